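# Exact inference on 2x2 carrier tables.
#
# The carrier table for a gene x variant-category cell is
#     a = case carriers,    b = case non-carriers,
#     c = control carriers, d = control non-carriers.
# Conditional on both margins, the case-carrier count follows Fisher's
# noncentral hypergeometric distribution with odds-ratio parameter psi.
# The package reports the conditional MLE of psi (the estimator associated
# with Fisher's exact test), a central exact confidence interval obtained by
# inverting the one-sided conditional tail tests, and the two-sided Fisher
# p-value under probability-mass ordering. All three are implemented here
# directly on the conditional likelihood; stats::fisher.test is used only as
# an independent cross-check in the test suite.

# noncentral hypergeometric probabilities over the conditional support.
# margins: m1 = a+b (cases), m2 = c+d (controls), s = a+c (carriers).
#' @keywords internal
nchg <- function(m1, m2, s, psi) {
  lo <- max(0L, s - m2)
  hi <- min(s, m1)
  x <- lo:hi
  if (psi == 0) {
    p <- as.numeric(x == lo)
    return(list(x = x, p = p, lo = lo, hi = hi))
  }
  lw <- lchoose(m1, x) + lchoose(m2, s - x) + x * log(psi)
  w <- exp(lw - max(lw))
  list(x = x, p = w / sum(w), lo = lo, hi = hi)
}

#' @keywords internal
check_table <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("table cells must be nonnegative integers")
  }
  invisible(TRUE)
}

#' Two-sided Fisher exact p-value for a 2x2 carrier table
#'
#' Probability-mass ordering: the p-value is the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one. A zero margin gives p = 1.
#'
#' @param a,b,c,d Table cells: case carriers, case non-carriers, control
#'   carriers, control non-carriers.
#' @return The two-sided p-value.
#' @examples
#' fisher_two_sided(3, 2568, 1, 155500)
#' @export
fisher_two_sided <- function(a, b, c, d) {
  check_table(a, b, c, d)
  m1 <- a + b; m2 <- c + d; s <- a + c
  if (m1 == 0 || m2 == 0 || s == 0 || (b + d) == 0) return(1)
  h <- nchg(m1, m2, s, 1)
  p_obs <- h$p[h$x == a]
  # tolerance guards against ties broken by floating-point noise
  sum(h$p[h$p <= p_obs * (1 + 1e-7)])
}

#' Conditional maximum-likelihood odds ratio
#'
#' Maximises the noncentral hypergeometric conditional likelihood in the
#' odds-ratio parameter (the estimator associated with Fisher's exact test);
#' equivalently solves `E_psi[X] = a`. Boundary conventions: `a` at the
#' support minimum gives 0, at the support maximum gives `Inf`; a table with
#' `a = 0` and `c = 0` is undefined (`NA`).
#'
#' @inheritParams fisher_two_sided
#' @return The conditional MLE of the odds ratio (may be 0, `Inf`, or `NA`).
#' @examples
#' conditional_mle_or(8, 2563, 23, 155478)   # ~21
#' @export
conditional_mle_or <- function(a, b, c, d) {
  check_table(a, b, c, d)
  if (a == 0 && c == 0) return(NA_real_)
  m1 <- a + b; m2 <- c + d; s <- a + c
  lo <- max(0L, s - m2); hi <- min(s, m1)
  if (a == lo && a == hi) return(NA_real_)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  f <- function(lp) {
    h <- nchg(m1, m2, s, exp(lp))
    sum(h$x * h$p) - a
  }
  r <- uniroot(f, lower = -1, upper = 1, extendInt = "upX",
               tol = 1e-10, maxiter = 2000)
  exp(r$root)
}

#' Central exact confidence interval for the odds ratio
#'
#' Inverts the one-sided conditional tail tests at `(1 - level)/2` each side:
#' the upper bound solves `P(X <= a | psi) = (1 - level)/2`, the lower bound
#' `P(X >= a | psi) = (1 - level)/2`. Tables with `a` at a support boundary
#' give one-sided intervals (lower 0 or upper `Inf`).
#'
#' @inheritParams fisher_two_sided
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' exact_ci(1, 2570, 1, 155500)
#' @export
exact_ci <- function(a, b, c, d, level = 0.95) {
  check_table(a, b, c, d)
  if (a == 0 && c == 0) return(c(NA_real_, NA_real_))
  m1 <- a + b; m2 <- c + d; s <- a + c
  lo <- max(0L, s - m2); hi <- min(s, m1)
  alpha <- (1 - level) / 2
  tail_le <- function(lp) {   # P(X <= a | psi)
    h <- nchg(m1, m2, s, exp(lp))
    sum(h$p[h$x <= a])
  }
  tail_ge <- function(lp) {   # P(X >= a | psi)
    h <- nchg(m1, m2, s, exp(lp))
    sum(h$p[h$x >= a])
  }
  upper <- if (a == hi) Inf else {
    exp(uniroot(function(lp) tail_le(lp) - alpha, lower = -1, upper = 1,
                extendInt = "downX", tol = 1e-10, maxiter = 2000)$root)
  }
  lower <- if (a == lo) 0 else {
    exp(uniroot(function(lp) tail_ge(lp) - alpha, lower = -1, upper = 1,
                extendInt = "upX", tol = 1e-10, maxiter = 2000)$root)
  }
  c(lower, upper)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_genes Number of genes tested (default 10).
#' @param n_categories Number of variant categories per gene tested against
#'   the threshold (default 2: LOF and synonymous).
#' @return `alpha / (n_genes * n_categories)`.
#' @examples
#' bonferroni_threshold()   # 0.0025
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_genes = 10,
                                 n_categories = 2) {
  stopifnot(alpha > 0, n_genes >= 1, n_categories >= 1)
  alpha / (n_genes * n_categories)
}

#' Test homogeneity of two odds ratios (interaction test)
#'
#' Default is Zelen's exact conditional test: conditioning on all margins and
#' on the total number of case carriers removes the common odds ratio under
#' the null, leaving a product-hypergeometric distribution; the p-value sums
#' the probabilities of all splits at most as probable as the observed one.
#' The asymptotic fallback is a Wald test on the difference of log sample
#' odds ratios with a 0.5 continuity correction applied to zero cells.
#'
#' @param t1,t2 Numeric vectors `c(a, b, c, d)` for the two tables (shared
#'   control-universe definition).
#' @param method `"exact"` (Zelen) or `"wald"`.
#' @return The interaction p-value (`NA` with a warning when a carrier cell
#'   is zero in both tables, where neither method is informative).
#' @examples
#' or_homogeneity(c(74, 3789, 7, 155494), c(12, 3851, 5, 155496))
#' @export
or_homogeneity <- function(t1, t2, method = c("exact", "wald")) {
  method <- match.arg(method)
  check_table(t1[1], t1[2], t1[3], t1[4])
  check_table(t2[1], t2[2], t2[3], t2[4])
  if ((t1[1] == 0 && t2[1] == 0) || (t1[3] == 0 && t2[3] == 0)) {
    warn("a carrier cell is zero in both tables; homogeneity is undefined")
    return(NA_real_)
  }
  if (method == "wald") {
    cc <- function(t) if (any(t == 0)) t + 0.5 else t
    t1 <- cc(t1); t2 <- cc(t2)
    l1 <- log(t1[1] * t1[4] / (t1[2] * t1[3]))
    l2 <- log(t2[1] * t2[4] / (t2[2] * t2[3]))
    se <- sqrt(sum(1 / t1) + sum(1 / t2))
    return(2 * stats::pnorm(-abs(l1 - l2) / se))
  }
  # Zelen: split s = a1 + a2 over the two tables
  m11 <- t1[1] + t1[2]; s1 <- t1[1] + t1[3]
  m12 <- t2[1] + t2[2]; s2 <- t2[1] + t2[3]
  s <- t1[1] + t2[1]
  a1_lo <- max(0L, s - min(s2, m12), s - s2)
  a1_hi <- min(s, s1, m11)
  a1 <- a1_lo:a1_hi
  lw <- vapply(a1, function(x) {
    x2 <- s - x
    if (x > s1 || x2 > s2 || x2 < 0) return(-Inf)
    stats::dhyper(x, m11, t1[3] + t1[4], s1, log = TRUE) +
      stats::dhyper(x2, m12, t2[3] + t2[4], s2, log = TRUE)
  }, 0)
  keep <- is.finite(lw)
  a1 <- a1[keep]; lw <- lw[keep]
  w <- exp(lw - max(lw)); p <- w / sum(w)
  p_obs <- p[a1 == t1[1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# ---- table-level burden testing --------------------------------------------

#' Exact burden inference on a table of carrier counts
#'
#' Runs the full exact machinery on each row of a carrier-count table:
#' two-sided Fisher p, conditional-MLE odds ratio, sample odds ratio, central
#' exact CI, and a significance flag at the Bonferroni-corrected threshold.
#'
#' @param counts Data frame with columns `a`, `b`, `c`, `d` (see
#'   [fisher_two_sided()]) and any identifying columns (e.g. `gene`,
#'   `category`), which are carried through.
#' @param alpha Family-wise error rate before correction.
#' @param n_tests Number of tests the Bonferroni correction divides `alpha`
#'   by (default 20 = 10 genes x 2 categories).
#' @param level Confidence level for the exact CI.
#' @return A `burden_result` tibble: input columns plus `or_cmle`,
#'   `or_sample`, `ci_lo`, `ci_hi`, `p_fisher`, `significant`. The corrected
#'   threshold is stored in the `threshold` attribute.
#' @examples
#' counts <- tibble::tibble(gene = "INS", category = "NMD_escape",
#'                          a = 3, b = 2568, c = 1, d = 155500)
#' burden_test(counts)
#' @export
burden_test <- function(counts, alpha = 0.05, n_tests = 20, level = 0.95) {
  counts <- as_tibble(counts)
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  thr <- alpha / n_tests
  res <- purrr::pmap(counts[, c("a", "b", "c", "d")], function(a, b, c, d) {
    ci <- exact_ci(a, b, c, d, level = level)
    p <- fisher_two_sided(a, b, c, d)
    or_s <- if (b == 0 || c == 0) {
      if (a == 0 && c == 0) NA_real_ else Inf
    } else a * d / (b * c)
    tibble(or_cmle = conditional_mle_or(a, b, c, d), or_sample = or_s,
           ci_lo = ci[1], ci_hi = ci[2], p_fisher = p,
           significant = !is.na(p) && p < thr)
  })
  out <- dplyr::bind_cols(counts, bind_rows(res))
  structure(out, threshold = thr, level = level,
            class = c("burden_result", class(out)))
}

#' @export
tidy.burden_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.burden_result <- function(x, ...) {
  tibble(n_tables = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         threshold = attr(x, "threshold"),
         level = attr(x, "level"))
}

#' Forest plot of burden results
#'
#' Odds ratios (conditional MLE) with exact CIs on a log axis, faceted by
#' variant category when present. Infinite estimates/bounds are clipped to
#' the plotted range with an open arrowhead-style marker omitted.
#'
#' @param object A [burden_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_result <- function(object, ...) {
  df <- as_tibble(object)
  if (!"gene" %in% names(df)) df$gene <- as.character(seq_len(nrow(df)))
  finite_max <- max(c(df$ci_hi[is.finite(df$ci_hi)],
                      df$or_cmle[is.finite(df$or_cmle)], 10), na.rm = TRUE)
  clip <- finite_max * 2
  df <- mutate(df,
    or_plot = pmin(pmax(.data$or_cmle, 1e-3), clip),
    lo_plot = pmin(pmax(.data$ci_lo, 1e-3), clip),
    hi_plot = pmin(.data$ci_hi, clip))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$or_plot, y = .data$gene)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo_plot, xmax = .data$hi_plot), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "significant") +
    ggplot2::labs(x = "odds ratio (conditional MLE, exact 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if ("category" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' Write burden results as a forest-plot-ready TSV
#'
#' @param result A [burden_test()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_burden_tsv <- function(result, path) {
  readr::write_tsv(as_tibble(result), path)
  invisible(path)
}
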