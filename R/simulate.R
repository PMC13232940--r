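# Generative side of the 2-HT lineup model: multinomial simulation and
# parameter-recovery studies.

#' Simulate pooled lineup response frequencies
#'
#' Draws multinomial response counts from the 2-HT trees under known true
#' parameters. For each condition, `n_participants * lineups_present`
#' culprit-present responses and `n_participants * lineups_absent`
#' culprit-absent responses are drawn as independent multinomial trials from
#' the model's category probabilities — exactly the independence assumption
#' the pooled analysis makes; within-participant clustering is deliberately
#' not modeled, matching how the pooled frequencies are analyzed.
#'
#' @param truth True parameters: a condition x parameter matrix (columns
#'   `dP`, `dA`, `b`, `g`, rownames the condition labels) or a named list of
#'   named vectors.
#' @param design A data.frame with columns `condition`, `n_participants`,
#'   `lineups_present`, `lineups_absent` (lineups per participant; a
#'   four-lineup session has `lineups_present + lineups_absent = 4`).
#' @param guess_split Guessing-split constant (1 / lineup size).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   dataset.
#' @return An `"mpt_freq"` dataset of pooled counts.
#' @examples
#' d <- exp1_design()
#' simulate_responses(d$truth, d$design, seed = 7)
#' @export
simulate_responses <- function(truth, design, guess_split = 0.16667,
                               seed = NULL) {
  if (is.list(truth) && !is.matrix(truth))
    truth <- do.call(rbind, lapply(truth, function(v) unlist(v)[PARAM_NAMES]))
  truth <- as.matrix(truth)[, PARAM_NAMES, drop = FALSE]
  need <- c("condition", "n_participants", "lineups_present", "lineups_absent")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (any(design$n_participants <= 0))
    stop("'n_participants' must be positive")
  if (any(design$lineups_present < 0 | design$lineups_absent < 0) ||
      any(design$lineups_present + design$lineups_absent <= 0))
    stop("each condition needs a non-negative lineup count and at least one lineup")
  missing_cond <- setdiff(design$condition, rownames(truth))
  if (length(missing_cond))
    stop("no true parameters for condition(s): ",
         paste(missing_cond, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    pars <- truth[cond, ]
    n_trees <- c(culprit_present = design$n_participants[i] * design$lineups_present[i],
                 culprit_absent = design$n_participants[i] * design$lineups_absent[i])
    for (tree in TREE_KINDS) {
      if (n_trees[[tree]] == 0) next
      p <- .category_probs(pars[["dP"]], pars[["dA"]], pars[["b"]], pars[["g"]],
                           tree, guess_split)
      cnt <- as.integer(stats::rmultinom(1L, n_trees[[tree]], p))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, lineup_type = tree,
        response = RESPONSE_CATEGORIES, count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  frequency_data(do.call(rbind, rows))
}

#' The first packaged experiment's design and plausible true parameters
#'
#' Returns the study conditions of the two-format experiment — 382 and 384
#' participants viewing two culprit-present and two culprit-absent lineups
#' each — together with true parameter values at the fitted estimates
#' (dP = .30/.28, dA = .05, b = .06, g = .44/.42), the standard
#' configuration for recovery and calibration studies at realistic sample
#' sizes.
#'
#' @return A list with elements `design` (data.frame) and `truth` (matrix).
#' @export
exp1_design <- function() {
  design <- data.frame(
    condition = c("combined", "separate"),
    n_participants = c(382L, 384L),
    lineups_present = 2L, lineups_absent = 2L,
    stringsAsFactors = FALSE)
  truth <- rbind(combined = c(dP = 0.30, dA = 0.05, b = 0.06, g = 0.44),
                 separate = c(dP = 0.28, dA = 0.05, b = 0.06, g = 0.42))
  list(design = design, truth = truth)
}

#' Parameter-recovery study
#'
#' Simulates `n_replicates` datasets from known true parameters, refits the
#' model to each, and summarizes estimator quality per free parameter: mean
#' estimate, bias, RMSE, empirical SE, mean model-based SE, and coverage of
#' the nominal Wald confidence interval. The decomposition
#' `RMSE^2 = bias^2 + variance` holds exactly (population variance).
#'
#' A master seed spawns one sub-seed per replicate, so the study is
#' reproducible and individual replicates can be regenerated in isolation.
#' Replicate-level fit failures are recorded as a failure rate, not fatal.
#' If the truth violates the model's equality constraints the study is one
#' of deliberate misspecification and is flagged as such in the report.
#'
#' @inheritParams simulate_responses
#' @param model The [mpt_model()] fitted to each replicate.
#' @param n_replicates Number of simulated datasets.
#' @param seed Master seed.
#' @param conf_level Nominal confidence level for the coverage column.
#' @param n_starts Optimizer starts per replicate fit. These recovery
#'   problems are well conditioned, so fewer starts than [fit_mpt()]'s
#'   default keep large studies fast; the truth-collapsed vector is always
#'   added as an extra start.
#' @return A `"recovery_report"`: a data.frame with one row per free
#'   parameter and attributes `n_replicates`, `n_failed`, `seed`,
#'   `misspecified`.
#' @export
recovery_study <- function(truth, design, model, n_replicates = 200L,
                           seed = 1L, guess_split = NULL,
                           conf_level = 0.95, n_starts = 3L) {
  stopifnot(inherits(model, "mpt_model"), n_replicates >= 1L)
  if (is.null(guess_split)) guess_split <- model$guess_split
  if (is.list(truth) && !is.matrix(truth))
    truth <- do.call(rbind, lapply(truth, function(v) unlist(v)[PARAM_NAMES]))
  truth <- as.matrix(truth)[model$conditions, PARAM_NAMES, drop = FALSE]

  theta_true <- collapse_params(truth, model)
  expanded <- expand_params(theta_true, model)
  misspecified <- max(abs(expanded[, PARAM_NAMES] - truth)) > 1e-12
  if (misspecified)
    warning("true parameters violate the model's constraints; ",
            "this is a misspecification study")

  sub_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_replicates))
  est <- matrix(NA_real_, n_replicates, model$n_free)
  ses <- matrix(NA_real_, n_replicates, model$n_free)
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    dat <- simulate_responses(truth, design, guess_split, seed = sub_seeds[r])
    fit <- tryCatch(
      suppressWarnings(fit_mpt(model, dat, n_starts = n_starts,
                               start_seed = sub_seeds[r],
                               extra_starts = list(theta_true))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
    est[r, ] <- fit$theta
    ses[r, ] <- fit$theta_se
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop("every replicate fit failed")

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  summarize <- function(j) {
    e <- est[ok, j]
    mean_est <- mean(e)
    bias <- mean_est - theta_true[j]
    varp <- mean((e - mean_est)^2)       # population variance: RMSE identity
    rmse <- sqrt(bias^2 + varp)
    s <- ses[ok, j]
    cover <- mean(abs(e - theta_true[j]) <= z * s, na.rm = TRUE)
    c(truth = theta_true[j], mean_estimate = mean_est, bias = bias,
      rmse = rmse,
      empirical_se = if (sum(ok) > 1L) sqrt(varp) else NA_real_,
      mean_model_se = mean(s, na.rm = TRUE),
      coverage = if (sum(ok) > 1L) cover else NA_real_)
  }
  tab <- as.data.frame(t(vapply(seq_len(model$n_free), summarize,
                                numeric(7))))
  tab <- cbind(parameter = model$free_labels, tab)
  rownames(tab) <- NULL
  structure(tab, n_replicates = n_replicates, n_failed = failed,
            seed = seed, misspecified = misspecified,
            conf_level = conf_level,
            class = c("recovery_report", "data.frame"))
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat("Parameter recovery over ", attr(x, "n_replicates"), " replicates (",
      attr(x, "n_failed"), " failed; master seed ", attr(x, "seed"), ")\n",
      sep = "")
  if (isTRUE(attr(x, "misspecified")))
    cat("  NOTE: deliberate model misspecification\n")
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], round, digits)
  print(df, ...)
  invisible(x)
}
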