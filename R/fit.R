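# Constrained maximum-likelihood estimation, G2 goodness of fit,
# degrees of freedom, and observed-information standard errors.

OPT_LOWER <- 1e-8
OPT_UPPER <- 1 - 1e-8

#' Multinomial log-likelihood of a constrained 2-HT model
#'
#' Sum over trees of `sum(n * log(p))`, omitting the multinomial coefficient.
#' Cells with zero counts contribute zero; a zero probability facing a
#' positive count yields `-Inf`.
#'
#' @param model An [mpt_model()].
#' @param theta Free-parameter vector of length `model$n_free`.
#' @param data An `"mpt_freq"` dataset (see [frequency_data()]).
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(model, theta, data) {
  fl <- freq_list(data, model$conditions)
  .loglik(model, theta, fl)
}

.loglik <- function(model, theta, fl) {
  pm <- expand_params(theta, model)
  ll <- 0
  for (k in seq_along(fl)) {
    for (tree in TREE_KINDS) {
      n <- fl[[k]][[tree]]
      if (is.null(n)) next
      p <- .category_probs(pm[k, "dP"], pm[k, "dA"], pm[k, "b"], pm[k, "g"],
                           tree, model$guess_split)
      pos <- n > 0
      if (!any(pos)) next
      ll <- ll + sum(n[pos] * log(p[pos]))
    }
  }
  ll
}

# negative log-likelihood with a floor on probabilities so the optimizer
# can traverse the boundary without producing NaN
.nll <- function(theta, model, fl) {
  pm <- expand_params(theta, model)
  ll <- 0
  for (k in seq_along(fl)) {
    for (tree in TREE_KINDS) {
      n <- fl[[k]][[tree]]
      if (is.null(n)) next
      p <- .category_probs(pm[k, "dP"], pm[k, "dA"], pm[k, "b"], pm[k, "g"],
                           tree, model$guess_split)
      pos <- n > 0
      if (!any(pos)) next
      ll <- ll + sum(n[pos] * log(pmax(p[pos], 1e-300)))
    }
  }
  -ll
}

# exact gradient of .nll: d(-ll)/d(theta). The tree probabilities are
# multilinear in the parameters, so the per-slot derivatives are closed-form;
# they are chained onto the free vector through the model's index map.
.nll_grad <- function(theta, model, fl) {
  pm <- expand_params(theta, model)
  cc <- model$guess_split
  grad <- numeric(model$n_free)
  for (k in seq_along(fl)) {
    dP <- pm[k, "dP"]; dA <- pm[k, "dA"]; b <- pm[k, "b"]; g <- pm[k, "g"]
    for (tree in TREE_KINDS) {
      n <- fl[[k]][[tree]]
      if (is.null(n)) next
      d <- if (tree == "culprit_present") dP else dA
      nd <- 1 - d
      p <- c(d * (tree == "culprit_present") + nd * b + nd * (1 - b) * g * cc,
             nd * (1 - b) * g * (1 - cc),
             nd * (1 - b) * (1 - g))
      if (tree == "culprit_absent") p[3L] <- p[3L] + d
      w <- n / pmax(p, 1e-300)           # dll/dp weights
      # derivative of (p_s, p_f, p_r) wrt the tree's detection parameter
      dp_d <- if (tree == "culprit_present")
        c(1 - b - (1 - b) * g * cc, -(1 - b) * g * (1 - cc),
          -(1 - b) * (1 - g))
      else
        c(-(b + (1 - b) * g * cc), -(1 - b) * g * (1 - cc),
          1 - (1 - b) * (1 - g))
      dp_b <- c(nd * (1 - g * cc), -nd * g * (1 - cc), -nd * (1 - g))
      dp_g <- c(nd * (1 - b) * cc, nd * (1 - b) * (1 - cc), -nd * (1 - b))
      det_name <- if (tree == "culprit_present") "dP" else "dA"
      for (pr in list(list(det_name, dp_d), list("b", dp_b), list("g", dp_g))) {
        j <- model$index[pr[[1L]], k]
        if (j > 0L) grad[j] <- grad[j] - sum(w * pr[[2L]])
      }
    }
  }
  grad
}

#' Degrees of freedom of a constrained model on a dataset
#'
#' The goodness-of-fit degrees of freedom: number of observed response cells,
#' minus one sum-to-one constraint per observed tree, minus the number of
#' free parameters.
#'
#' @inheritParams log_likelihood
#' @return Integer degrees of freedom (>= 0).
#' @export
mpt_df <- function(model, data) {
  fl <- freq_list(data, model$conditions)
  trees <- sum(vapply(fl, function(cond)
    sum(!vapply(cond, is.null, logical(1))), numeric(1)))
  df <- as.integer(3L * trees - trees - model$n_free)
  if (df < 0L)
    stop("model is overparameterized for these data: ", model$n_free,
         " free parameters but only ", 2L * trees,
         " identifiable category probabilities")
  df
}

#' Upper-tail chi-square p-value for a G-squared statistic
#'
#' @param G2 Goodness-of-fit statistic (>= 0).
#' @param df Degrees of freedom. For `df = 0` (a saturated model) the
#'   p-value is defined as 1.
#' @return The p-value.
#' @export
gof_p_value <- function(G2, df) {
  stopifnot(G2 >= -1e-12, df >= 0)
  if (df == 0L) return(1)
  stats::pchisq(max(G2, 0), df = df, lower.tail = FALSE)
}

#' Fit a constrained 2-HT model by maximum likelihood
#'
#' Maximizes the pooled multinomial likelihood over the unit box by bounded
#' quasi-Newton (`L-BFGS-B`) from multiple deterministic starts: one at 0.5
#' everywhere, the rest drawn uniformly under `start_seed`, plus any
#' caller-supplied starts. The best solution is kept; start-to-start
#' agreement of the maximized log-likelihood is recorded so optimization
#' trouble is visible rather than silent.
#'
#' `G2 = 2 * sum(n * log(n / (N * p_hat)))` over positive-count cells; zero
#' cells contribute zero. Standard errors come from the observed information
#' (see [standard_errors()]); estimates within `1e-6` of the unit bounds are
#' flagged as boundary estimates whose standard errors are approximate.
#'
#' @inheritParams log_likelihood
#' @param n_starts Number of optimizer starts (>= 1); default 10.
#' @param start_seed Seed for the uniform random starts; the global RNG
#'   state is left untouched.
#' @param extra_starts Optional list of additional start vectors.
#' @param se Compute standard errors (default `TRUE`); skipping them speeds
#'   up large simulation studies where only point estimates are needed.
#' @return An object of class `"mpt_fit"` with elements `estimates`
#'   (condition x parameter matrix), `se`, `theta`, `theta_se`,
#'   `log_likelihood`, `G2`, `df`, `p_value`, `converged`, `boundary`,
#'   `n_starts_used`, `start_loglik_spread`, `fitted` (per-tree fitted
#'   category probabilities) and the `model`.
#' @examples
#' fit <- fit_mpt(mpt_model(c("combined", "separate"),
#'                          equal = list(b = "all", dA = "all")),
#'                exp1_frequencies())
#' fit$G2
#' @export
fit_mpt <- function(model, data, n_starts = 10L, start_seed = 1L,
                    extra_starts = NULL, se = TRUE) {
  stopifnot(inherits(model, "mpt_model"), n_starts >= 1L)
  fl <- freq_list(data, model$conditions)
  totals <- vapply(fl, function(cond)
    sum(unlist(cond)), numeric(1))
  if (any(totals <= 0))
    stop("every condition needs a positive response total; offending: ",
         paste(names(totals)[totals <= 0], collapse = ", "))

  k <- model$n_free
  starts <- list(rep(0.5, k))
  if (n_starts > 1L) {
    u <- with_local_seed(start_seed, stats::runif((n_starts - 1L) * k))
    starts <- c(starts, asplit(matrix(u, n_starts - 1L, k), 1L))
  }
  starts <- c(starts, lapply(extra_starts, pmin, OPT_UPPER))
  starts <- lapply(starts, pmax, OPT_LOWER)

  best <- NULL
  values <- numeric(0)
  codes <- integer(0)
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, .nll, gr = .nll_grad, model = model, fl = fl,
                   method = "L-BFGS-B",
                   lower = OPT_LOWER, upper = OPT_UPPER,
                   control = list(factr = 1e1, maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    values <- c(values, opt$value)
    codes <- c(codes, opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimization failed from every start")
  # converged if any start that reached the best value reported clean
  # convergence (a lone line-search abort on a dominated start is harmless)
  converged <- is.finite(best$value) &&
    any(codes == 0L & values <= best$value + 1e-8)
  if (!converged)
    warning("optimizer did not report convergence (code ", best$convergence,
            "); treat estimates with caution")

  theta <- best$par
  estimates <- expand_params(theta, model)
  boundary <- (model$index > 0L) &
    (t(estimates) < 1e-6 | t(estimates) > 1 - 1e-6)

  # G2 and fitted probabilities
  G2 <- 0
  fitted <- list()
  for (k_i in seq_along(fl)) {
    cond <- names(fl)[k_i]
    for (tree in TREE_KINDS) {
      n <- fl[[k_i]][[tree]]
      if (is.null(n)) next
      p <- .category_probs(estimates[k_i, "dP"], estimates[k_i, "dA"],
                           estimates[k_i, "b"], estimates[k_i, "g"],
                           tree, model$guess_split)
      fitted[[paste(cond, tree, sep = ".")]] <- p
      N <- sum(n)
      pos <- n > 0
      G2 <- G2 + 2 * sum(n[pos] * log(n[pos] / (N * p[pos])))
    }
  }
  G2 <- max(G2, 0)
  df <- mpt_df(model, data)

  theta_se <- rep(NA_real_, model$n_free)
  se_mat <- matrix(NA_real_, nrow(estimates), ncol(estimates),
                   dimnames = dimnames(estimates))
  if (se) {
    theta_se <- .theta_se(model, fl, theta)
    free <- model$index > 0L
    se_mat[t(free)] <- theta_se[t(model$index)[t(free)]]
  }

  structure(list(model = model, estimates = estimates, se = se_mat,
                 theta = stats::setNames(theta, model$free_labels),
                 theta_se = stats::setNames(theta_se, model$free_labels),
                 log_likelihood = -best$value,
                 G2 = G2, df = df, p_value = gof_p_value(G2, df),
                 converged = converged,
                 boundary = t(boundary),
                 n_starts_used = length(values),
                 start_loglik_spread = if (length(values) > 1L)
                   diff(range(-values)) else 0,
                 fitted = fitted),
            class = "mpt_fit")
}

# draw from a temporary RNG stream without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Observed-information standard errors
#'
#' Square roots of the diagonal of the inverse observed information, i.e. the
#' numerical Hessian of the negative log-likelihood at the maximum, by
#' central differences with step `1e-5`. Estimates within `1e-6` of the unit
#' bounds are nudged inward before differentiation; their standard errors
#' are approximate. A singular information matrix yields `NA` standard
#' errors with a warning rather than a failed fit.
#'
#' @inheritParams log_likelihood
#' @param theta The maximum-likelihood free-parameter vector.
#' @return Condition x parameter matrix of standard errors (`NA` where a
#'   parameter is fixed or the information matrix is singular).
#' @export
standard_errors <- function(model, data, theta) {
  fl <- freq_list(data, model$conditions)
  theta_se <- .theta_se(model, fl, theta)
  estimates <- expand_params(theta, model)
  out <- matrix(NA_real_, nrow(estimates), ncol(estimates),
                dimnames = dimnames(estimates))
  free <- model$index > 0L
  out[t(free)] <- theta_se[t(model$index)[t(free)]]
  out
}

.theta_se <- function(model, fl, theta, h = 1e-5) {
  k <- length(theta)
  x <- pmin(pmax(theta, 2e-5), 1 - 2e-5)  # nudge off the bounds
  f <- function(t) .nll(t, model, fl)
  f0 <- f(x)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) + f(x - ei) - 2 * f0) / h^2
    for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    warning("observed information matrix is singular or indefinite; ",
            "standard errors unavailable")
    return(rep(NA_real_, k))
  }
  sqrt(diag(cov))
}

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat("2-HT model fit (", x$n_starts_used, " starts",
      if (!x$converged) ", NOT CONVERGED", ")\n", sep = "")
  cat(sprintf("  G2(%d) = %.*f, p = %.3f, logLik = %.*f\n",
              x$df, digits, x$G2, x$p_value, digits, x$log_likelihood))
  tab <- round(x$estimates, digits)
  print(tab)
  if (any(x$boundary, na.rm = TRUE))
    cat("  note: boundary estimate(s) flagged; their SEs are approximate\n")
  invisible(x)
}

#' @export
coef.mpt_fit <- function(object, ...) object$estimates

#' @export
logLik.mpt_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$model$n_free, class = "logLik")
}
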