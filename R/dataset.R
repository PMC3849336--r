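#' Case-control dataset
#'
#' The universal input of the package: a real-valued feature matrix
#' (samples x features) with a binary disease outcome (0 = control,
#' 1 = case) and distinct feature names.
#'
#' @param features numeric matrix or data frame, samples in rows.
#' @param outcome binary vector (0/1) of length `nrow(features)`; both
#'   classes must be present.
#' @param feature_names character vector of distinct, non-empty names;
#'   defaults to the column names of `features`.
#' @return an object of class `case_control_dataset` with elements
#'   `features` (matrix), `outcome` (integer vector) and `feature_names`.
#' @examples
#' d <- case_control_dataset(matrix(rnorm(60), 30, 2),
#'                           rep(c(0, 1), 15), c("a", "b"))
#' d
#' @export
case_control_dataset <- function(features, outcome,
                                 feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%02d", seq_len(ncol(features)))
  }
  feature_names <- as.character(feature_names)

  if (ncol(features) < 2L) {
    synet_error("synet_input_error", "need at least 2 features")
  }
  if (nrow(features) < 20L) {
    synet_error("synet_input_error",
                "need at least 20 samples (cross-validation folds degenerate below this)")
  }
  if (anyNA(features) || any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    synet_error("synet_input_error",
                sprintf("missing or non-finite feature value at row %d, column %d",
                        bad[1L], bad[2L]))
  }
  if (length(outcome) != nrow(features)) {
    synet_error("synet_input_error", "outcome length does not match sample count")
  }
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    bad <- outcome[!(outcome %in% c(0, 1))][1L]
    synet_error("synet_input_error",
                sprintf("outcome must contain only 0 and 1 (found '%s')",
                        as.character(bad)))
  }
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L) {
    synet_error("synet_input_error", "both outcome classes must be present")
  }
  if (length(feature_names) != ncol(features) ||
      anyDuplicated(feature_names) || any(!nzchar(feature_names))) {
    synet_error("synet_input_error",
                "feature_names must be distinct non-empty strings, one per column")
  }
  colnames(features) <- feature_names
  rownames(features) <- NULL

  structure(list(features = features, outcome = outcome,
                 feature_names = feature_names),
            class = "case_control_dataset")
}

# Internal: row subset without re-validating the minimum-n invariant
# (CV folds of an already validated dataset).
#' @noRd
dataset_rows <- function(dataset, idx) {
  structure(list(features = dataset$features[idx, , drop = FALSE],
                 outcome = dataset$outcome[idx],
                 feature_names = dataset$feature_names),
            class = "case_control_dataset")
}

#' @export
print.case_control_dataset <- function(x, ...) {
  cat(sprintf("case_control_dataset: %d samples x %d features (%d cases, %d controls)\n",
              nrow(x$features), ncol(x$features),
              sum(x$outcome == 1L), sum(x$outcome == 0L)))
  invisible(x)
}

#' @export
dim.case_control_dataset <- function(x) dim(x$features)
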