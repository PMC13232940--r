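# Likelihood-ratio (delta G2) tests of nested parameter hypotheses.

#' Test equality of a parameter across conditions
#'
#' Fits the general model and a restricted model in which `parameter` is
#' additionally equated across the given condition groups, and compares them
#' by the likelihood-ratio statistic `delta G2 = G2_restricted - G2_general`,
#' referred to the chi-square distribution with `delta df` degrees of
#' freedom. A significantly worse restricted fit indicates that the latent
#' process differs across the equated conditions.
#'
#' The restricted model is fitted from the usual multi-start grid plus one
#' extra start: the general solution projected onto the constraint (shared
#' slots averaged). This protects the test against a spuriously positive
#' `delta G2` caused by optimization failure. A `delta G2` below `-1e-6`
#' raises an error (it would mean the nested fit beat the general one);
#' smaller negative rounding noise is clipped to zero.
#'
#' @inheritParams fit_mpt
#' @param parameter One of `dP`, `dA`, `b`, `g`.
#' @param groups `"all"`, a character vector of conditions to equate, or a
#'   list of such vectors.
#' @param general_fit Optionally, a precomputed [fit_mpt()] of `model` on
#'   `data` (reused instead of refitting).
#' @param ... Passed on to [fit_mpt()] (e.g. `n_starts`, `se = FALSE`).
#' @return An object of class `"mpt_test"`: `delta_G2`, `delta_df`,
#'   `p_value`, `parameter`, `groups`, and both fits (`general`,
#'   `restricted`).
#' @examples
#' m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
#' test_equality(m, exp1_frequencies(), "dP")
#' @export
test_equality <- function(model, data, parameter, groups = "all",
                          general_fit = NULL, ...) {
  restricted_model <- add_equality(model, parameter, groups)
  if (restricted_model$n_free >= model$n_free)
    stop("the added equality does not restrict the model; ",
         "nothing to test")
  if (is.null(general_fit)) {
    general_fit <- fit_mpt(model, data, ...)
  } else {
    stopifnot(inherits(general_fit, "mpt_fit"))
    if (!identical(general_fit$model$index, model$index))
      stop("'general_fit' was not fitted with the supplied model")
  }

  seed_start <- collapse_params(general_fit$estimates, restricted_model)
  restricted_fit <- fit_mpt(restricted_model, data,
                            extra_starts = list(seed_start), ...)

  delta_G2 <- restricted_fit$G2 - general_fit$G2
  if (delta_G2 < -1e-6)
    stop("restricted model fit better than the general model (delta G2 = ",
         format(delta_G2), "); optimization quality is suspect")
  delta_G2 <- max(delta_G2, 0)
  delta_df <- restricted_fit$df - general_fit$df

  structure(list(parameter = parameter, groups = groups,
                 delta_G2 = delta_G2, delta_df = delta_df,
                 p_value = gof_p_value(delta_G2, delta_df),
                 general = general_fit, restricted = restricted_fit),
            class = "mpt_test")
}

#' Test one condition's parameter against an already-pooled group
#'
#' One-degree-of-freedom test of whether `parameter` in `focal` equals its
#' common value in `rest`, for a general model in which the `rest`
#' conditions already share a single free parameter (e.g. after a
#' preliminary homogeneity test justified pooling them). This is the
#' grouped-contrast layout of a focused directional hypothesis: the focal
#' condition against everything else.
#'
#' @inheritParams test_equality
#' @param focal A single condition label.
#' @param rest Character vector of the remaining conditions, which must
#'   already share one free parameter for `parameter` in `model`.
#' @return An `"mpt_test"` (see [test_equality()]).
#' @export
test_grouped_vs_rest <- function(model, data, parameter, focal, rest, ...) {
  stopifnot(length(focal) == 1L, length(rest) >= 1L)
  idx <- model$index[parameter, rest]
  if (length(unique(idx)) != 1L || any(idx == 0L))
    stop("the 'rest' conditions must already share one free parameter for '",
         parameter, "' in the general model")
  test_equality(model, data, parameter, groups = list(c(focal, rest)), ...)
}

#' @export
print.mpt_test <- function(x, ...) {
  grp <- if (identical(x$groups, "all")) "all conditions"
    else if (is.list(x$groups))
      paste(vapply(x$groups, paste, "", collapse = ","), collapse = "; ")
    else paste(x$groups, collapse = ",")
  cat("Equality test for '", x$parameter, "' (", grp, ")\n", sep = "")
  cat(sprintf("  delta G2(%d) = %.2f, p = %.3f\n",
              x$delta_df, x$delta_G2, x$p_value))
  invisible(x)
}
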