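test_that("two-sided Fisher p equals the exhaustive-enumeration oracle", {
  # every table with margins <= 12, plus random tables with margins <= 30
  for (m1 in c(1, 3, 7, 12)) {
    for (m2 in c(1, 4, 12)) {
      for (s in 0:(m1 + m2)) {
        for (a in max(0, s - m2):min(s, m1)) {
          tab <- c(a, m1 - a, s - a, m2 - (s - a))
          expect_equal(fisher_two_sided(tab[1], tab[2], tab[3], tab[4]),
                       oracle_fisher_enum(tab[1], tab[2], tab[3], tab[4]),
                       tolerance = 1e-12)
        }
      }
    }
  }
  set.seed(42)
  for (i in 1:200) {
    t <- random_table(30)
    p <- fisher_two_sided(t["a"], t["b"], t["c"], t["d"])
    expect_equal(p, oracle_fisher_enum(t["a"], t["b"], t["c"], t["d"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # independent cross-check against the standard implementation
    ft <- stats::fisher.test(matrix(c(t["a"], t["c"], t["b"], t["d"]), 2))
    expect_equal(p, ft$p.value, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # zero margin
  expect_equal(fisher_two_sided(0, 10, 0, 20), 1)
})

test_that("conditional-MLE odds ratio matches a brute-force likelihood scan", {
  set.seed(7)
  n_done <- 0
  while (n_done < 40) {
    t <- random_table(25)
    or <- conditional_mle_or(t["a"], t["b"], t["c"], t["d"])
    if (!is.finite(or) || or == 0) next
    expect_equal(log(or), log(oracle_cmle_scan(t["a"], t["b"], t["c"], t["d"])),
                 tolerance = 1e-6, ignore_attr = TRUE)
    n_done <- n_done + 1
  }
})

test_that("conditional-MLE boundary conventions and symmetry hold", {
  expect_equal(conditional_mle_or(0, 100, 5, 95), 0)
  expect_identical(conditional_mle_or(3, 97, 0, 100), Inf)
  expect_true(is.na(conditional_mle_or(0, 100, 0, 100)))
  # perfectly balanced table
  expect_equal(conditional_mle_or(4, 50, 4, 50), 1, tolerance = 1e-8)
  # cMLE approaches the sample OR as cells grow
  gap <- function(f) {
    abs(log(conditional_mle_or(8 * f, 100 * f, 2 * f, 100 * f)) - log(4))
  }
  expect_true(gap(50) < gap(5))
  expect_lt(gap(50), 0.01)
})

test_that("exact CIs invert the conditional tail tests", {
  set.seed(11)
  for (i in 1:25) {
    t <- random_table(25)
    if (t["a"] + t["c"] == 0) next
    ci95 <- exact_ci(t["a"], t["b"], t["c"], t["d"], level = 0.95)
    ci99 <- exact_ci(t["a"], t["b"], t["c"], t["d"], level = 0.99)
    # widening with the level
    expect_lte(ci99[1], ci95[1])
    expect_gte(ci99[2], ci95[2])
    # central convention: CI excludes 1 <=> doubled one-sided tail p < 0.05
    m1 <- t["a"] + t["b"]; m2 <- t["c"] + t["d"]; s <- t["a"] + t["c"]
    h <- modyburden:::nchg(m1, m2, s, 1)
    p_central <- min(1, 2 * min(sum(h$p[h$x <= t["a"]]),
                                sum(h$p[h$x >= t["a"]])))
    excl <- ci95[1] > 1 || ci95[2] < 1
    expect_equal(excl, p_central < 0.05, ignore_attr = TRUE)
  }
  # zero-cell one-sided bounds
  expect_equal(exact_ci(0, 100, 3, 97)[1], 0)
  expect_identical(exact_ci(5, 95, 0, 100)[2], Inf)
})

test_that("the Bonferroni threshold is plain division", {
  expect_identical(bonferroni_threshold(0.05, 10, 2), 0.0025)
  expect_identical(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_identical(bonferroni_threshold(0.10, 4, 5), 0.005)
})

test_that("odds-ratio homogeneity test behaves under the null and edge cases", {
  # identical tables: observed split is the modal one
  expect_gt(or_homogeneity(c(10, 90, 10, 90), c(10, 90, 10, 90)), 0.9)
  # zero carrier cell in both tables is undefined
  expect_warning(p <- or_homogeneity(c(0, 10, 3, 7), c(0, 10, 2, 8)),
                 "undefined")
  expect_true(is.na(p))
  # Wald fallback gives a probability
  pw <- or_homogeneity(c(8, 92, 4, 96), c(3, 97, 6, 94), method = "wald")
  expect_true(pw > 0 && pw <= 1)
  # type-I error at alpha 0.05 under a shared odds ratio (exact test is
  # conservative, so the rejection rate must not exceed the nominal level)
  set.seed(99)
  reps <- 1000
  rej <- 0
  for (i in 1:reps) {
    a1 <- rbinom(1, 40, 0.3); c1 <- rbinom(1, 40, 0.15)
    a2 <- rbinom(1, 40, 0.3); c2 <- rbinom(1, 40, 0.15)
    p <- suppressWarnings(
      or_homogeneity(c(a1, 40 - a1, c1, 40 - c1),
                     c(a2, 40 - a2, c2, 40 - c2)))
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("burden_test assembles results with broom verbs and a forest plot", {
  counts <- tibble::tibble(
    gene = c("INS", "NEUROD1", "ABCC8"),
    category = c("NMD_escape", "LOF_all", "NMD_escape"),
    a = c(3, 8, 0), b = c(2568, 2563, 2571),
    c = c(1, 23, 6), d = c(155500, 155478, 155495))
  res <- burden_test(counts, alpha = 0.05, n_tests = 20)
  expect_s3_class(res, "burden_result")
  expect_equal(attr(res, "threshold"), 0.0025)
  td <- tidy(res)
  expect_equal(nrow(td), 3)
  expect_true(all(c("or_cmle", "or_sample", "ci_lo", "ci_hi", "p_fisher",
                    "significant") %in% names(td)))
  # INS escape enriched, ABCC8 escape empty in cases
  expect_true(td$significant[td$gene == "INS"])
  expect_equal(td$or_cmle[td$gene == "ABCC8"], 0)
  expect_equal(td$p_fisher[td$gene == "ABCC8"], 1)
  gl <- glance(res)
  expect_equal(gl$n_significant, 2)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
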