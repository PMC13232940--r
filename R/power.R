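# Noncentral chi-square power and sensitivity analysis (Cohen's w).

#' Power of a chi-square test at effect size w
#'
#' Power of an asymptotic chi-square test (such as a G2 goodness-of-fit or
#' delta-G2 test) against an alternative of effect size `w` (Cohen's w):
#' the upper-tail probability, beyond the central `1 - alpha` critical
#' value, of the noncentral chi-square distribution with noncentrality
#' `lambda = n_obs * w^2`.
#'
#' `n_obs` is the total number of responses entering the test — participants
#' times responses per participant when each participant contributes several
#' lineup responses — not the number of participants. This convention is what
#' makes the packaged sensitivity analyses come out at the published values
#' and is a known point of confusion across power tools.
#'
#' @param w Effect size Cohen's w (>= 0).
#' @param n_obs Total number of observations (responses) entering the test.
#' @param df Degrees of freedom of the test (>= 1).
#' @param alpha Type-I error probability.
#' @return The power; equals `alpha` at `w = 0`.
#' @examples
#' power_chisq(w = 0.07, n_obs = 766 * 4, df = 1, alpha = 0.05)
#' @export
power_chisq <- function(w, n_obs, df, alpha = 0.05) {
  stopifnot(w >= 0, n_obs > 0, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df = df)
  stats::pchisq(crit, df = df, ncp = n_obs * w^2, lower.tail = FALSE)
}

#' Smallest detectable effect size (sensitivity analysis)
#'
#' Solves `power_chisq(w, n_obs, df, alpha) = power` for `w` on
#' `[1e-6, 1]`: the smallest effect size Cohen's w detectable with the
#' requested power at the given alpha, degrees of freedom and total
#' observation count.
#'
#' @inheritParams power_chisq
#' @param power Target power `1 - beta`.
#' @return The critical effect size `w`, solved to about `1e-10`.
#' @examples
#' sensitivity_w(n_obs = 766 * 4, df = 1, alpha = 0.05, power = 0.95)
#' @export
sensitivity_w <- function(n_obs, df, alpha = 0.05, power = 0.95) {
  stopifnot(alpha > 0, alpha < power, power < 1)
  f <- function(w) power_chisq(w, n_obs, df, alpha) - power
  if (f(1) < 0)
    stop("no detectable effect size w <= 1 at these settings; ",
         "increase n_obs or relax power/alpha")
  stats::uniroot(f, c(1e-6, 1), tol = 1e-10)$root
}
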