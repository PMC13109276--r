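pm <- proinsulin_map()
tx_ins <- toy_transcripts()[["INS"]]
wt <- pm$reference_seq

test_that("the proinsulin map validates against its reference sequence", {
  expect_equal(pm$length, 110)
  expect_equal(substring(wt, pm$cysteines, pm$cysteines),
               rep("C", 6))
  expect_error(proinsulin_map(cysteines = c(31, 43, 95, 96, 100, 108)),
               "not cysteines")
})

test_that("cysteine inventories match the published truncation biology", {
  panel <- ins_variant_panel()
  ann <- annotate_variants(panel, list(INS = tx_ins))
  profs <- setNames(purrr::map(ann$mutant_protein, cysteine_inventory),
                    panel$name)
  # p.Gln78*: A chain entirely lost, both B-chain cysteines unpaired
  g78 <- profs[["p.Gln78*"]]
  expect_equal(g78$retained_cys[[1]], c(31, 43))
  expect_false(g78$a_chain_intact)
  expect_equal(g78$unpaired_b_cys, 2L)
  # p.Tyr103*: keeps the first three A-chain cysteines, loses only 109
  y103 <- profs[["p.Tyr103*"]]
  expect_equal(y103$retained_cys[[1]], c(31, 43, 95, 96, 100))
  expect_equal(y103$unpaired_b_cys, 1L)
  # frameshift tails: fsTer58 introduces exactly two novel cysteines
  expect_length(profs[["p.Glu83ValfsTer58"]]$novel_cys[[1]], 2)
  expect_length(profs[["p.Leu82GlyfsTer52"]]$novel_cys[[1]], 0)
  # wild type: everything retained, nothing unpaired
  wtp <- cysteine_inventory(wt)
  expect_equal(wtp$retained_cys[[1]], pm$cysteines)
  expect_equal(wtp$unpaired_b_cys, 0L)
  expect_equal(wtp$pattern, "indeterminate")
})

test_that("severity classification follows A-chain cysteine topology", {
  profile_of <- function(aa) cysteine_inventory(aa, pm)
  # every stop-gain with PTC <= 89 (A chain lost): mody-like, and for
  # PTC > 43 both B-chain cysteines are unpaired
  for (ptc in c(44, 60, 78, 89)) {
    pr <- profile_of(substr(wt, 1, ptc - 1))
    expect_false(pr$a_chain_intact)
    expect_equal(pr$unpaired_b_cys, 2L)
    expect_equal(pr$pattern, "mody_like")
  }
  # truncations into the late A chain: neonatal-like
  for (ptc in c(103, 108)) {
    expect_equal(profile_of(substr(wt, 1, ptc - 1))$pattern, "neonatal_like")
  }
  # novel tail cysteines never flip the class
  trunc81 <- substr(wt, 1, 81)
  with_tail <- paste0(trunc81, "GRCPACRS")        # tail with 2 cysteines
  pr <- profile_of(with_tail)
  expect_equal(pr$pattern, "mody_like")
  expect_length(pr$novel_cys[[1]], 2)
  # extension past the reference without any frameshift is an error
  expect_error(cysteine_inventory(paste0(wt, "AAA")), "longer than reference")
})

test_that("the bundled panel profiles to the published MODY/neonatal split", {
  prof <- ins_panel_profile()
  mody <- c("p.Gln78*", "p.Leu82GlyfsTer52", "p.Cys95*", "p.Glu83ValfsTer58")
  expect_true(all(prof$pattern[prof$name %in% mody] == "mody_like"))
  expect_true(all(prof$pattern[prof$name %in% c("p.Tyr103*", "p.Tyr108*")] ==
                    "neonatal_like"))
  expect_true(all(prof$nmd_class == "escape"))
})

test_that("SG distances are Euclidean with CB fallback and cutoff flag", {
  coords <- tibble::tibble(
    resno = c(31, 43, 96, 96),
    elety = c("SG", "SG", "CB", "N"),
    x = c(0, 3, 0, 9), y = c(0, 4, 4.8, 9), z = c(0, 0, 0, 9))
  d <- sg_distances(coords, c(31, 43), cutoff = 5.5)
  expect_equal(d$distance, 5)                      # 3-4-5 triangle
  expect_true(d$pairable)
  # identical coordinates give distance zero
  d0 <- sg_distances(tibble::tibble(resno = c(1, 2), elety = c("SG", "SG"),
                                    x = c(1, 1), y = c(2, 2), z = c(3, 3)),
                     c(1, 2))
  expect_equal(d0$distance, 0)
  # wild-type-like 4.8 A separation is pairable at the default cutoff
  d48 <- sg_distances(tibble::tibble(resno = c(31, 96), elety = c("SG", "SG"),
                                     x = c(0, 4.8), y = 0, z = 0), c(31, 96))
  expect_true(d48$pairable)
  # CB fallback is used and flagged when SG is absent
  d2 <- sg_distances(coords, c(31, 96))
  expect_equal(d2$atom_j, "CB")
  expect_equal(d2$distance, 4.8)
  # a residue with neither atom is skipped with a warning
  expect_warning(d3 <- sg_distances(coords, c(31, 43, 50)), "skipped")
  expect_equal(nrow(d3), 1)
})

test_that("PDB files are read for distance measurement", {
  # synthetic two-cysteine PDB, SG atoms 4.8 A apart
  pdb_lines <- c(
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 1, " SG", " ", "CYS", "A", 31, " ", 0, 0, 0, 1, 0, "S"),
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", 2, " SG", " ", "CYS", "A", 96, " ", 4.8, 0, 0, 1, 0, "S"),
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, path)
  d <- sg_distances(path, c(31, 96))
  expect_equal(d$distance, 4.8, tolerance = 1e-6)
  expect_true(d$pairable)
})
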