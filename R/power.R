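# Simulation-based power for the carrier burden design.
#
# "MAF < 1 in 10,000" is interpreted as the collapsed qualifying-carrier
# frequency p0 = 1e-4 in controls - the quantity the 2x2 carrier test sees.
# Case carriers are Binomial(n_case, p1) with odds(p1) = OR * odds(p0);
# control carriers Binomial(n_control, p0). Power is the fraction of
# replicates with two-sided Fisher p below alpha.

#' @keywords internal
implied_p1 <- function(or, p0) {
  odds1 <- or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  if (p1 >= 1) abort("implied case carrier frequency >= 1")
  p1
}

# Fisher p over unique (a, c) pairs with caching - the simulated counts are
# heavily tied, so only a few hundred distinct tables are ever evaluated.
#' @keywords internal
sim_power_once <- function(a, c, n_case, n_control, alpha) {
  # significance is strict (p < alpha) as in the burden analysis; alpha >= 1
  # disables the test entirely (every replicate counts)
  if (alpha >= 1) return(1)
  key <- paste(a, c, sep = ",")
  uk <- !duplicated(key)
  pu <- purrr::map2_dbl(a[uk], c[uk], function(ai, ci) {
    fisher_two_sided(ai, n_case - ai, ci, n_control - ci)
  })
  hit <- setNames(pu < alpha, key[uk])
  mean(hit[key])
}

#' Estimate power of the carrier burden test at a given odds ratio
#'
#' @param or_true True odds ratio(s); vectorised (replicates are shared
#'   across values via common random numbers, so the estimated power curve is
#'   monotone in the odds ratio).
#' @param n_case,n_control Cohort sizes.
#' @param carrier_freq Collapsed qualifying-carrier frequency in controls.
#' @param alpha Significance threshold for the two-sided Fisher test
#'   (default 0.0025, the Bonferroni-corrected threshold).
#' @param reps Number of simulation replicates (>= 20,000 recommended for
#'   reported results; Monte-Carlo error ~ 0.003 near power 0.8).
#' @param seed Optional integer seed; identical inputs reproduce the estimate
#'   bit-for-bit.
#' @return Tibble: `or_true`, `power`, `mc_se` (binomial Monte-Carlo standard
#'   error), `reps`.
#' @examples
#' power_at(20, n_case = 2571, n_control = 155501, reps = 2000, seed = 1)
#' @export
power_at <- function(or_true, n_case, n_control, carrier_freq = 1e-4,
                     alpha = 0.0025, reps = 20000, seed = NULL) {
  stopifnot(reps >= 1, carrier_freq > 0, carrier_freq < 1, all(or_true > 0))
  with_seed_if(seed, {
    u_case <- runif(reps)
    u_ctrl <- runif(reps)
    ctrl <- qbinom(u_ctrl, n_control, carrier_freq)
    pw <- vapply(or_true, function(or) {
      cases <- qbinom(u_case, n_case, implied_p1(or, carrier_freq))
      sim_power_once(cases, ctrl, n_case, n_control, alpha)
    }, 0)
    tibble(or_true = or_true, power = pw,
           mc_se = sqrt(pw * (1 - pw) / reps), reps = reps)
  })
}

#' Minimal detectable odds ratio at a target power
#'
#' Bisection over the odds ratio until the estimated power crosses the
#' target. Common random numbers across candidate odds ratios make the
#' empirical power curve monotone, so the bisection is well behaved despite
#' Monte-Carlo noise; the result is reported to one decimal place.
#'
#' @inheritParams power_at
#' @param target_power Power to reach (default 0.80).
#' @param or_max Upper bracket for the search (expanded automatically if
#'   needed).
#' @return A one-row tibble: `min_or` (1 d.p.), `power_at_min` (estimated
#'   power at the returned odds ratio), `mc_se`, `reps`.
#' @examples
#' min_detectable_or(n_case = 300, n_control = 3000, carrier_freq = 0.01,
#'                   alpha = 0.05, reps = 2000, seed = 1)
#' @export
min_detectable_or <- function(n_case, n_control, carrier_freq = 1e-4,
                              alpha = 0.0025, target_power = 0.80,
                              reps = 20000, seed = NULL, or_max = 64) {
  stopifnot(target_power > 0, target_power < 1)
  with_seed_if(seed, {
    u_case <- runif(reps)
    u_ctrl <- runif(reps)
    ctrl <- qbinom(u_ctrl, n_control, carrier_freq)
    pw <- function(or) {
      cases <- qbinom(u_case, n_case, implied_p1(or, carrier_freq))
      sim_power_once(cases, ctrl, n_case, n_control, alpha)
    }
    lo <- 1
    hi <- or_max
    while (pw(hi) < target_power) {
      lo <- hi
      hi <- hi * 2
      if (hi > 1e6) abort("no attainable odds ratio reaches the target power")
    }
    if (pw(lo) >= target_power) {
      hi <- lo
    } else {
      for (i in 1:30) {
        mid <- (lo + hi) / 2
        if (pw(mid) >= target_power) hi <- mid else lo <- mid
        if (hi - lo < 0.01) break
      }
    }
    # smallest value on the 0.1 grid that reaches the target with these draws
    cand <- round(hi, 1)
    if (cand >= 1 + 0.1 && pw(cand - 0.1) >= target_power) cand <- cand - 0.1
    if (pw(cand) < target_power) cand <- cand + 0.1
    p_hat <- pw(cand)
    tibble(min_or = cand, power_at_min = p_hat,
           mc_se = sqrt(p_hat * (1 - p_hat) / reps), reps = reps)
  })
}

#' Power curve over a grid of odds ratios
#'
#' Convenience wrapper returning a tibble ready for plotting, plus
#' [plot_power_curve()] for a standard display.
#'
#' @inheritParams power_at
#' @param or_grid Odds ratios to evaluate.
#' @return Tibble as [power_at()].
#' @export
power_curve <- function(or_grid, n_case, n_control, carrier_freq = 1e-4,
                        alpha = 0.0025, reps = 20000, seed = NULL) {
  power_at(or_grid, n_case, n_control, carrier_freq, alpha, reps, seed)
}

#' @rdname power_curve
#' @param curve Output of [power_curve()].
#' @param target_power Horizontal reference line.
#' @export
plot_power_curve <- function(curve, target_power = 0.80) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$or_true, y = .data$power)) +
    ggplot2::geom_hline(yintercept = target_power, linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$power - 2 * .data$mc_se, 0),
                   ymax = pmin(.data$power + 2 * .data$mc_se, 1)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "true odds ratio", y = "power") +
    ggplot2::theme_minimal()
}
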