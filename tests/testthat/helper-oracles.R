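# Independent oracles and small fixture builders used across the suite.

# frequency dataset for a single condition; either tree may be NULL
single_condition_data <- function(cp = NULL, ca = NULL, condition = "only") {
  rows <- list()
  if (!is.null(cp))
    rows$cp <- data.frame(condition = condition, lineup_type = "culprit_present",
                          response = c("suspect", "filler", "rejection"),
                          count = cp)
  if (!is.null(ca))
    rows$ca <- data.frame(condition = condition, lineup_type = "culprit_absent",
                          response = c("suspect", "filler", "rejection"),
                          count = ca)
  frequency_data(do.call(rbind, rows))
}

# brute-force grid-search oracle for a culprit-present tree with b and dA
# fixed: maximizes the multinomial log-likelihood over (dP, g) on a coarse
# grid, then on a refined grid around the coarse optimum. Independent of the
# package's optimizer: probabilities are expanded directly from the branch
# products.
grid_search_cp <- function(counts, b = 0, cc = 0.16667,
                           n_coarse = 100L, n_fine = 100L) {
  ll <- function(dP, g) {
    ps <- dP + (1 - dP) * b + (1 - dP) * (1 - b) * g * cc
    pf <- (1 - dP) * (1 - b) * g * (1 - cc)
    pr <- (1 - dP) * (1 - b) * (1 - g)
    counts[1] * log(pmax(ps, 1e-300)) + counts[2] * log(pmax(pf, 1e-300)) +
      counts[3] * log(pmax(pr, 1e-300))
  }
  search <- function(dP_range, g_range, n) {
    dP <- seq(dP_range[1], dP_range[2], length.out = n)
    g <- seq(g_range[1], g_range[2], length.out = n)
    val <- outer(dP, g, ll)
    best <- arrayInd(which.max(val), dim(val))
    list(dP = dP[best[1]], g = g[best[2]], ll = max(val),
         step = c(diff(dP_range), diff(g_range)) / (n - 1))
  }
  coarse <- search(c(0, 1), c(0, 1), n_coarse)
  fine <- search(pmax(0, pmin(1, coarse$dP + c(-1, 1) * 2 * coarse$step[1])),
                 pmax(0, pmin(1, coarse$g + c(-1, 1) * 2 * coarse$step[2])),
                 n_fine)
  fine
}

# noncentral chi-square survival function by the Poisson-mixture series:
# P(X > q) = sum_j Pois(j; lambda/2) * P(ChiSq(df + 2j) > q).
# Uses only the central chi-square distribution, independently of the
# noncentral code path exercised by power_chisq().
ncx2_sf_series <- function(q, df, lambda, rel_tol = 1e-12, max_terms = 10000L) {
  total <- 0
  for (j in 0:max_terms) {
    term <- stats::dpois(j, lambda / 2) *
      stats::pchisq(q, df + 2 * j, lower.tail = FALSE)
    total <- total + term
    if (j > lambda / 2 && term < rel_tol * max(total, 1e-300)) break
  }
  total
}
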