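# shared medium-size simulated cohort (study-condition control size, smaller
# case arm kept at the generator default)
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sim_cohort(seed = 2024)
    cache
  }
})

test_that("the ultra-rare filter applies a strict bound on both AF sources", {
  variants <- tibble::tibble(
    variant_id = paste0("v", 1:3), chrom = "chr_X", pos = 1:3,
    ref = "A", alt = "T")
  samples <- tibble::tibble(
    id = c("case_1", paste0("ctrl_", 1:5000)),
    group = c("case", rep("control", 5000)))
  # v1: 1 control carrier -> af 1e-4 exactly (strict bound removes it)
  carriers <- tibble::tibble(variant_id = "v1", sample_id = "ctrl_1",
                             dose = 1L)
  out <- ultra_rare_filter(variants, carriers, samples, threshold = 1e-4)
  expect_false("v1" %in% out$variant_id)
  expect_setequal(out$variant_id, c("v2", "v3"))
  # threshold 1 keeps everything
  expect_equal(nrow(ultra_rare_filter(variants, carriers, samples,
                                      threshold = 1)), 3)
  # reference AF can disqualify a variant the control cohort cannot see
  af <- tibble::tibble(chrom = "chr_X", pos = 2L, ref = "A", alt = "T",
                       af = 5e-4,
                       variant_id = "v2")
  expect_warning(
    out2 <- ultra_rare_filter(variants, carriers, samples, af, 1e-4),
    "missing from the AF reference")
  expect_setequal(out2$variant_id, "v3")
})

test_that("filter monotonicity gives the nested sensitivity chain", {
  sim <- sim_fixture()
  q1 <- ultra_rare_filter(sim$variants, sim$carriers, sim$samples,
                          sim$af_reference, 5e-5)
  q2 <- ultra_rare_filter(sim$variants, sim$carriers, sim$samples,
                          sim$af_reference, 1e-4)
  q3 <- ultra_rare_filter(sim$variants, sim$carriers, sim$samples,
                          sim$af_reference, 2e-4)
  expect_true(all(q1$variant_id %in% q2$variant_id))
  expect_true(all(q2$variant_id %in% q3$variant_id))
})

test_that("carrier collapse counts individuals once and partitions LOF", {
  samples <- tibble::tibble(id = c("s1", "s2", "c1", "c2"),
                            group = c("case", "case", "control", "control"))
  variants <- tibble::tibble(variant_id = c("e1", "e2", "t1"),
                             chrom = "g", pos = 1:3, ref = "A", alt = "T")
  ann <- tibble::tibble(
    variant_id = c("e1", "e2", "t1"), gene = "G1",
    consequence = c("stop_gain", "frameshift", "stop_gain"),
    nmd_class = c("escape", "escape", "triggering"))
  # s1 carries two escape variants -> counts once; s2 carries one escape and
  # one triggering variant -> LOF_all still counts it once
  carriers <- tibble::tibble(
    variant_id = c("e1", "e2", "e1", "t1"),
    sample_id = c("s1", "s1", "s2", "s2"), dose = 1L)
  cc <- collapse_carriers(variants, ann, carriers, samples)
  expect_equal(cc$a[cc$category == "NMD_escape"], 2L)
  expect_equal(cc$a[cc$category == "NMD_triggering"], 1L)
  expect_equal(cc$a[cc$category == "LOF_all"], 2L)   # union, not sum
  expect_equal(cc$b[cc$category == "LOF_all"], 0L)
  expect_equal(cc$d[cc$category == "LOF_all"], 2L)
  # collapsing is order-independent
  shuffled <- carriers[c(4, 2, 3, 1), ]
  expect_equal(collapse_carriers(variants, ann, shuffled, samples), cc)
  # qualifying variant without annotation is an error
  expect_error(
    collapse_carriers(dplyr::bind_rows(
      variants, tibble::tibble(variant_id = "x", chrom = "g", pos = 9,
                               ref = "A", alt = "G")),
      ann, carriers, samples),
    "without annotation")
  # unknown carrier id is an error
  expect_error(
    collapse_carriers(variants, ann,
                      dplyr::bind_rows(carriers,
                                       tibble::tibble(variant_id = "e1",
                                                      sample_id = "ghost",
                                                      dose = 1L)),
                      samples),
    "absent from the sample sheet")
})

test_that("collapsed counts reproduce the generator's truth ledger exactly", {
  sim <- sim_fixture()
  ann <- annotate_variants(sim$variants, sim$txs)
  qual <- ultra_rare_filter(sim$variants, sim$carriers, sim$samples,
                            sim$af_reference, 1e-4)
  # every planted site is ultra-rare by construction
  expect_equal(nrow(qual), nrow(sim$variants))
  cc <- collapse_carriers(qual, ann, sim$carriers, sim$samples)
  obs <- dplyr::select(cc, "gene", "category", a_obs = "a", c_obs = "c")
  cmp <- dplyr::left_join(sim$truth, obs, by = c("gene", "category"))
  cmp$a_obs[is.na(cmp$a_obs)] <- 0L
  cmp$c_obs[is.na(cmp$c_obs)] <- 0L
  expect_equal(cmp$a_obs, cmp$case_carriers)
  expect_equal(cmp$c_obs, cmp$control_carriers)
})

test_that("VCF round trip preserves variants and carriers", {
  sim <- sim_cohort(n_case = 150, n_control = 1500, seed = 5)
  paths <- write_cohort_files(sim, withr::local_tempdir())
  vc <- read_cohort_vcf(paths$vcf)
  expect_setequal(vc$variants$variant_id, sim$variants$variant_id)
  key <- function(x) sort(paste(x$variant_id, x$sample_id, x$dose))
  expect_identical(key(vc$carriers), key(sim$carriers))
  sheet <- read_sample_sheet(paths$samples)
  expect_equal(sheet, sim$samples)
  af <- read_af_table(paths$af)
  expect_equal(nrow(af), nrow(sim$af_reference))
  # multi-allelic records are rejected
  bad <- readLines(paths$vcf)
  i <- grep("^[^#]", bad)[1]
  f <- strsplit(bad[i], "\t")[[1]]
  f[5] <- paste0(f[5], ",G")
  bad[i] <- paste(f, collapse = "\t")
  bp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(bad, bp)
  expect_error(read_cohort_vcf(bp), "multi-allelic")
})
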