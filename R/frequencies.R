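# Response-frequency containers and CSV I/O.

#' Construct a response-frequency dataset
#'
#' Validates and normalizes observed lineup response counts. The expected
#' layout is long: one row per `(condition, lineup_type, response)` cell with
#' a non-negative integer `count`. Response categories absent from an observed
#' tree are filled with zero counts; a condition must contribute at least one
#' tree.
#'
#' @param x A data.frame with columns `condition`, `lineup_type`
#'   (`"culprit_present"` or `"culprit_absent"`), `response` (`"suspect"`,
#'   `"filler"`, `"rejection"`) and `count`.
#' @return An object of class `"mpt_freq"` (a normalized data.frame).
#' @export
frequency_data <- function(x) {
  need <- c("condition", "lineup_type", "response", "count")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("frequency data lacks column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$condition <- as.character(x$condition)
  x$lineup_type <- as.character(x$lineup_type)
  x$response <- as.character(x$response)

  bad <- which(!x$lineup_type %in% TREE_KINDS)
  if (length(bad))
    stop("unknown lineup_type ", paste(unique(x$lineup_type[bad]), collapse = ", "),
         " (row ", paste(bad, collapse = ", "), "); expected ",
         paste(TREE_KINDS, collapse = " or "))
  bad <- which(!x$response %in% RESPONSE_CATEGORIES)
  if (length(bad))
    stop("unknown response ", paste(unique(x$response[bad]), collapse = ", "),
         " (row ", paste(bad, collapse = ", "), "); expected ",
         paste(RESPONSE_CATEGORIES, collapse = ", "))
  cnt <- suppressWarnings(as.numeric(x$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad))
    stop("'count' must be a non-negative integer; offending row(s): ",
         paste(bad, collapse = ", "))
  x$count <- as.integer(round(cnt))

  key <- paste(x$condition, x$lineup_type, x$response)
  if (anyDuplicated(key))
    stop("duplicate (condition, lineup_type, response) cell(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  # fill unobserved categories of observed trees with zeros, in canonical order
  conditions <- unique(x$condition)
  rows <- list()
  for (cond in conditions) for (tree in TREE_KINDS) {
    sub <- x[x$condition == cond & x$lineup_type == tree, ]
    if (!nrow(sub)) next
    cnts <- stats::setNames(integer(3L), RESPONSE_CATEGORIES)
    cnts[sub$response] <- sub$count
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, lineup_type = tree,
      response = RESPONSE_CATEGORIES, count = as.integer(cnts),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, conditions = conditions, class = c("mpt_freq", "data.frame"))
}

#' Read response frequencies from CSV
#'
#' Reads a UTF-8 CSV with header `condition,lineup_type,response,count` and
#' validates it via [frequency_data()].
#'
#' @param path CSV file path.
#' @return An `"mpt_freq"` object.
#' @export
read_frequencies <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  frequency_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write response frequencies to CSV
#'
#' @param data An `"mpt_freq"` object (or coercible data.frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_frequencies <- function(data, path) {
  data <- frequency_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: counts as a per-condition list of per-tree 3-vectors
# (suspect, filler, rejection), in the model's condition order
freq_list <- function(data, conditions = attr(data, "conditions")) {
  data <- frequency_data(data)
  present <- attr(data, "conditions")
  unknown <- setdiff(conditions, present)
  if (length(unknown))
    stop("data has no counts for condition(s): ", paste(unknown, collapse = ", "))
  extra <- setdiff(present, conditions)
  if (length(extra))
    stop("data contains condition(s) absent from the model: ",
         paste(extra, collapse = ", "))
  out <- lapply(conditions, function(cond) {
    trees <- lapply(TREE_KINDS, function(tree) {
      sub <- data[data$condition == cond & data$lineup_type == tree, ]
      if (!nrow(sub)) return(NULL)
      stats::setNames(sub$count[match(RESPONSE_CATEGORIES, sub$response)],
                      RESPONSE_CATEGORIES)
    })
    names(trees) <- TREE_KINDS
    trees
  })
  names(out) <- conditions
  out
}

#' @export
print.mpt_freq <- function(x, ...) {
  cat("Lineup response frequencies (", length(attr(x, "conditions")),
      " condition(s), ", sum(x$count), " responses)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Observed response frequencies of the two packaged experiments
#'
#' `exp1_frequencies()` returns the two-condition dataset (combined vs.
#' separate lineup-presentation format; 766 participants, two culprit-present
#' and two culprit-absent lineups each). `exp2_frequencies()` returns the
#' four-condition dataset crossing presentation format with the number of
#' culprit-present lineups (three vs. one; 781 participants). Both are the
#' published pooled response-frequency tables shipped as package fixtures.
#'
#' @return An `"mpt_freq"` object.
#' @export
exp1_frequencies <- function() {
  read_frequencies(system.file("extdata", "exp1_frequencies.csv",
                               package = "lineup2ht", mustWork = TRUE))
}

#' @rdname exp1_frequencies
#' @export
exp2_frequencies <- function() {
  read_frequencies(system.file("extdata", "exp2_frequencies.csv",
                               package = "lineup2ht", mustWork = TRUE))
}
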