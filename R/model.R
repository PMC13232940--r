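# Core 2-HT lineup model: category probabilities and constrained
# multi-condition model structure.

# Canonical parameter order; free-parameter indices are assigned in this
# order so that fits are reproducible run-to-run.
PARAM_NAMES <- c("dP", "dA", "b", "g")

TREE_KINDS <- c("culprit_present", "culprit_absent")

RESPONSE_CATEGORIES <- c("suspect", "filler", "rejection")

#' Category probabilities of the 2-HT eyewitness identification model
#'
#' Computes the probabilities of the three observable lineup responses
#' (suspect selection, filler selection, lineup rejection) from the latent
#' process parameters of the two-high-threshold eyewitness identification
#' model, for a culprit-present or a culprit-absent lineup.
#'
#' For a culprit-present lineup the culprit's presence is detected with
#' probability `dP`, producing a culprit identification. Otherwise biased
#' suspect selection occurs with probability `b`; failing that, guessing-based
#' selection occurs with probability `g` and lands on the suspect with the
#' random-sampling probability `guess_split` (1 / lineup size). For a
#' culprit-absent lineup, detection of the culprit's absence (probability
#' `dA`) produces a rejection; the non-detection branches mirror the
#' culprit-present tree with the innocent suspect in the culprit's place.
#'
#' @param params Named numeric vector (or list) with elements `dP`, `dA`,
#'   `b`, `g`, each a probability in `[0, 1]`.
#' @param tree `"culprit_present"` or `"culprit_absent"`.
#' @param guess_split Probability that a guessing-based selection picks the
#'   suspect rather than a filler; `1 / lineup size`. Must lie strictly
#'   inside `(0, 1)`. Defaults to 0.16667, the six-member-lineup value.
#' @return Named numeric vector `c(suspect, filler, rejection)` summing to 1.
#' @examples
#' category_probs(c(dP = 0.3, dA = 0.1, b = 0.06, g = 0.44), "culprit_present")
#' @export
category_probs <- function(params, tree = c("culprit_present", "culprit_absent"),
                           guess_split = 0.16667) {
  tree <- match.arg(tree)
  params <- unlist(params)[PARAM_NAMES]
  for (nm in PARAM_NAMES) {
    v <- params[[nm]]
    if (is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a probability in [0, 1], got ", v)
  }
  check_guess_split(guess_split)
  .category_probs(params[["dP"]], params[["dA"]], params[["b"]], params[["g"]],
                  tree, guess_split)
}

# unchecked kernel, used in likelihood loops
.category_probs <- function(dP, dA, b, g, tree, cc) {
  if (tree == "culprit_present") {
    nd <- 1 - dP
    c(suspect = dP + nd * b + nd * (1 - b) * g * cc,
      filler = nd * (1 - b) * g * (1 - cc),
      rejection = nd * (1 - b) * (1 - g))
  } else {
    nd <- 1 - dA
    c(suspect = nd * b + nd * (1 - b) * g * cc,
      filler = nd * (1 - b) * g * (1 - cc),
      rejection = dA + nd * (1 - b) * (1 - g))
  }
}

check_guess_split <- function(cc) {
  if (!is.numeric(cc) || length(cc) != 1L || is.na(cc) || cc <= 0 || cc >= 1)
    stop("'guess_split' must lie strictly inside (0, 1); a lineup with ",
         "guess_split 0 or 1 has no suspect/filler distinction")
  invisible(cc)
}

#' Build a constrained multi-condition 2-HT model
#'
#' Replicates the 2-HT lineup trees over experimental conditions and encodes
#' equality constraints (shared free parameters across conditions) and fixed
#' constants. Free-parameter indices are assigned deterministically: parameters
#' in the order `dP`, `dA`, `b`, `g`, conditions in declaration order.
#'
#' @param conditions Character vector of unique condition labels.
#' @param equal Named list mapping a parameter name (`dP`, `dA`, `b`, `g`) to
#'   equality groups: either the string `"all"` (one shared parameter across
#'   every condition), a character vector of conditions forming one group, or
#'   a list of such vectors for several disjoint groups.
#' @param fixed Named list mapping a parameter name to either a single numeric
#'   constant (fixed in every condition) or a named numeric vector
#'   (condition -> constant). A fixed value inside an equality group
#'   propagates to the whole group.
#' @param guess_split Guessing-split constant `1 / lineup size`; stored as the
#'   literal 0.16667 by default for six-member lineups.
#' @return An object of class `"mpt_model"`: the condition labels, constraint
#'   structure, number of free parameters `n_free`, and labels for the free
#'   parameter vector.
#' @examples
#' # two lineup-presentation formats, b and dA shared: 6 free parameters
#' m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
#' m$n_free
#' @export
mpt_model <- function(conditions, equal = list(), fixed = list(),
                      guess_split = 0.16667) {
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("'conditions' must be a non-empty vector of unique labels")
  check_guess_split(guess_split)
  K <- length(conditions)

  bad <- setdiff(names(equal), PARAM_NAMES)
  if (length(bad))
    stop("equality constraints may only name ", paste(PARAM_NAMES, collapse = ", "),
         "; unknown: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(fixed), PARAM_NAMES)
  if (length(bad))
    stop("fixed values may only name ", paste(PARAM_NAMES, collapse = ", "),
         "; unknown: ", paste(bad, collapse = ", "))

  # group id per (parameter, condition); start fully unconstrained
  group <- matrix(seq_len(4L * K), nrow = 4L, ncol = K,
                  dimnames = list(PARAM_NAMES, conditions))
  equal <- lapply(equal, canonical_groups, conditions = conditions)
  for (p in names(equal)) {
    for (grp in equal[[p]]) {
      ids <- group[p, grp]
      group[p, ][group[p, ] %in% ids] <- min(ids)
    }
  }

  # fixed constants, propagated across each equality group
  fixed_mat <- matrix(NA_real_, 4L, K, dimnames = list(PARAM_NAMES, conditions))
  for (p in names(fixed)) {
    v <- fixed[[p]]
    if (is.null(names(v))) {
      if (length(v) != 1L)
        stop("unnamed fixed value for '", p, "' must be a single constant")
      fixed_mat[p, ] <- v
    } else {
      unknown <- setdiff(names(v), conditions)
      if (length(unknown))
        stop("fixed value for '", p, "' names unknown condition(s): ",
             paste(unknown, collapse = ", "))
      fixed_mat[p, names(v)] <- v
    }
  }
  if (any(fixed_mat < 0 | fixed_mat > 1, na.rm = TRUE))
    stop("fixed parameter values must lie in [0, 1]")
  for (p in PARAM_NAMES) for (k in seq_len(K)) {
    if (!is.na(fixed_mat[p, k])) {
      members <- group[p, ] == group[p, k]
      vals <- fixed_mat[p, members]
      if (length(unique(vals[!is.na(vals)])) > 1L)
        stop("conflicting fixed values for '", p, "' within one equality group")
      fixed_mat[p, members] <- vals[!is.na(vals)][1L]
    }
  }

  # deterministic free-index assignment
  index <- matrix(0L, 4L, K, dimnames = list(PARAM_NAMES, conditions))
  labels <- character(0)
  next_idx <- 0L
  for (p in PARAM_NAMES) for (k in seq_len(K)) {
    if (!is.na(fixed_mat[p, k]) || index[p, k] != 0L) next
    next_idx <- next_idx + 1L
    members <- group[p, ] == group[p, k]
    index[p, members] <- next_idx
    labels[next_idx] <- if (all(members)) p else
      paste0(p, "[", paste(conditions[members], collapse = ","), "]")
  }

  structure(list(conditions = conditions, guess_split = guess_split,
                 equal = equal, fixed = fixed,
                 index = index, fixed_values = fixed_mat,
                 n_free = next_idx, free_labels = labels),
            class = "mpt_model")
}

canonical_groups <- function(spec, conditions) {
  if (identical(spec, "all")) spec <- list(conditions)
  if (is.character(spec)) spec <- list(spec)
  if (!is.list(spec))
    stop("an equality constraint must be \"all\", a character vector, ",
         "or a list of character vectors")
  spec <- lapply(spec, as.character)
  for (grp in spec) {
    unknown <- setdiff(grp, conditions)
    if (length(unknown))
      stop("equality group names unknown condition(s): ",
           paste(unknown, collapse = ", "))
    if (length(grp) < 2L)
      stop("an equality group needs at least two conditions")
  }
  spec
}

#' Add an equality constraint to an existing model
#'
#' Returns a new, more restricted model in which `parameter` is additionally
#' equated across the given condition groups. The result is nested in the
#' input model, which is what makes delta-G-squared likelihood-ratio tests
#' well defined.
#'
#' @param model An [mpt_model()].
#' @param parameter One of `dP`, `dA`, `b`, `g`.
#' @param groups `"all"`, a character vector of conditions (one group), or a
#'   list of character vectors.
#' @return A new `"mpt_model"` with the constraint merged in.
#' @export
add_equality <- function(model, parameter, groups = "all") {
  stopifnot(inherits(model, "mpt_model"))
  if (!parameter %in% PARAM_NAMES)
    stop("unknown parameter '", parameter, "'")
  equal <- model$equal
  new_groups <- canonical_groups(groups, model$conditions)
  equal[[parameter]] <- c(if (parameter %in% names(equal)) equal[[parameter]],
                          new_groups)
  mpt_model(model$conditions, equal = equal, fixed = model$fixed,
            guess_split = model$guess_split)
}

#' Expand a free-parameter vector into per-condition parameters
#'
#' Maps the free-parameter vector of a constrained model onto the full
#' `condition x parameter` table, filling shared slots from their common
#' index and fixed slots from their constants.
#'
#' @param theta Numeric vector of length `model$n_free`.
#' @param model An [mpt_model()].
#' @return Numeric matrix, one row per condition, columns `dP`, `dA`, `b`, `g`.
#' @export
expand_params <- function(theta, model) {
  stopifnot(inherits(model, "mpt_model"))
  if (length(theta) != model$n_free)
    stop("'theta' has length ", length(theta), " but the model has ",
         model$n_free, " free parameters")
  out <- t(model$fixed_values)
  free <- model$index > 0L
  out[t(free)] <- theta[t(model$index)[t(free)]]
  out
}

# Inverse of expand_params for a consistent per-condition assignment:
# collapse a condition x parameter matrix onto the model's free vector.
# Inconsistent slots (unequal values sharing an index) are averaged, which
# is the natural seed when projecting a general solution onto a restriction.
collapse_params <- function(par_matrix, model) {
  theta <- numeric(model$n_free)
  for (j in seq_len(model$n_free)) {
    slots <- which(model$index == j, arr.ind = TRUE)
    theta[j] <- mean(par_matrix[cbind(slots[, 2L], slots[, 1L])])
  }
  theta
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("2-HT lineup identification model\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  cat("  guessing split c = ", format(x$guess_split), "\n", sep = "")
  cat("  free parameters (", x$n_free, "): ",
      paste(x$free_labels, collapse = ", "), "\n", sep = "")
  fx <- which(!is.na(x$fixed_values), arr.ind = TRUE)
  if (nrow(fx))
    cat("  fixed: ",
        paste0(rownames(x$fixed_values)[fx[, 1L]], "[",
               colnames(x$fixed_values)[fx[, 2L]], "] = ",
               x$fixed_values[fx], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a model in EQN format
#'
#' Writes the instantiated trees as an EQN file (the de-facto interchange
#' format of MPT software): a header line with the number of branch lines,
#' then one line per branch with tree name, response category, and the branch
#' probability product. Shared parameters carry the same symbol across
#' conditions; the guessing split appears as its numeric constant.
#'
#' @param model An [mpt_model()].
#' @param path Output file path.
#' @return Invisibly, the lines written.
#' @export
write_eqn <- function(model, path) {
  stopifnot(inherits(model, "mpt_model"))
  sym <- function(p, k) {
    if (!is.na(model$fixed_values[p, k]))
      return(format(model$fixed_values[p, k]))
    lbl <- model$free_labels[model$index[p, k]]
    gsub("[^A-Za-z0-9_]", "_", lbl)
  }
  cc <- format(model$guess_split)
  lines <- character(0)
  for (k in seq_along(model$conditions)) {
    cond <- model$conditions[k]
    dP <- sym("dP", k); dA <- sym("dA", k); b <- sym("b", k); g <- sym("g", k)
    cp <- paste0(cond, ".culprit_present")
    ca <- paste0(cond, ".culprit_absent")
    lines <- c(lines,
      paste(cp, "suspect", dP),
      paste(cp, "suspect", paste0("(1-", dP, ")*", b)),
      paste(cp, "suspect", paste0("(1-", dP, ")*(1-", b, ")*", g, "*", cc)),
      paste(cp, "filler", paste0("(1-", dP, ")*(1-", b, ")*", g, "*(1-", cc, ")")),
      paste(cp, "rejection", paste0("(1-", dP, ")*(1-", b, ")*(1-", g, ")")),
      paste(ca, "rejection", dA),
      paste(ca, "suspect", paste0("(1-", dA, ")*", b)),
      paste(ca, "suspect", paste0("(1-", dA, ")*(1-", b, ")*", g, "*", cc)),
      paste(ca, "filler", paste0("(1-", dA, ")*(1-", b, ")*", g, "*(1-", cc, ")")),
      paste(ca, "rejection", paste0("(1-", dA, ")*(1-", b, ")*(1-", g, ")")))
  }
  out <- c(as.character(length(lines)), lines)
  writeLines(out, path)
  invisible(out)
}

#' Read a model configuration file
#'
#' Builds an [mpt_model()] from a YAML or JSON configuration with fields
#' `conditions` (list of labels), optional `equal` (parameter -> "all" or
#' groups of conditions), optional `fixed` (parameter -> constant or
#' condition -> constant mapping) and optional `guess_split` (default
#' 0.16667). Example configurations for both packaged experiments ship in
#' `system.file("extdata", package = "lineup2ht")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `"mpt_model"`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$conditions))
    stop("model configuration must list 'conditions'")
  equal <- cfg$equal %||% list()
  fixed <- lapply(cfg$fixed %||% list(), function(v) {
    if (is.list(v)) unlist(v) else v
  })
  mpt_model(unlist(cfg$conditions), equal = equal, fixed = fixed,
            guess_split = cfg$guess_split %||% 0.16667)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
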