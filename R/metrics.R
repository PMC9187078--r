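# Classification bookkeeping: confusion matrices, per-class and overall
# accuracies, dataset-composition reports, and the packaged reference tables
# of the published validation run.

#' Build a 6x6 confusion matrix
#'
#' @param true_labels,predicted Integer class labels 0..5, equal length.
#' @return 6x6 integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted classes, dimnames are the class names.
#' @export
confusion_matrix <- function(true_labels, predicted) {
  if (length(true_labels) != length(predicted)) {
    stop(sprintf("length mismatch: %d true labels vs %d predictions",
                 length(true_labels), length(predicted)), call. = FALSE)
  }
  true_labels <- assert_label(true_labels)
  predicted <- assert_label(predicted)
  counts <- table(factor(true_labels, levels = 0:5),
                  factor(predicted, levels = 0:5))
  m <- matrix(as.integer(counts), 6, 6,
              dimnames = list(true = CLASS_NAMES, predicted = CLASS_NAMES))
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 6, ncol(m) == 6, all(m >= 0))
  dimnames(m) <- list(true = CLASS_NAMES, predicted = CLASS_NAMES)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class accuracy from a confusion matrix
#'
#' accuracy_k = counts\[k, k\] / rowsum_k, rounded half-up to 3 decimals
#' (the reporting precision of the reference tables). Classes with an empty
#' row are flagged as `NA` rather than reported as 0.
#'
#' @param cm A `confusion_matrix` (or any 6x6 count matrix).
#' @param digits Decimals to report (default 3); `NA` for unrounded.
#' @return Named numeric vector of length 6.
#' @export
per_class_accuracy <- function(cm, digits = 3) {
  cm <- as_confusion_matrix(cm)
  rs <- rowSums(cm)
  acc <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  if (!is.na(digits)) acc <- round_half_up(acc, digits)
  stats::setNames(acc, CLASS_NAMES)
}

#' Overall accuracy from a confusion matrix
#'
#' trace/total, rounded half-up to 3 decimals by default.
#'
#' @inheritParams per_class_accuracy
#' @return Numeric scalar.
#' @export
overall_accuracy <- function(cm, digits = 3) {
  cm <- as_confusion_matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  acc <- sum(diag(cm)) / total
  if (!is.na(digits)) acc <- round_half_up(acc, digits)
  acc
}

#' Dataset-composition report
#'
#' Tabulates per-class image counts across dataset splits and derives split
#' totals, the grand total, and each class's share of the grand total as a
#' percentage (half-up, 1 decimal).
#'
#' @param splits Named list of per-class count vectors (each length 6, in
#'   class order 0..5), or a data.frame with a `class` column and one count
#'   column per split.
#' @return List with `table` (classes x splits counts plus a `total`
#'   column), `split_totals`, `grand_total` and `share_pct` (per-class
#'   percent of grand total, 1 decimal).
#' @export
composition_report <- function(splits) {
  if (is.data.frame(splits)) {
    stopifnot("class" %in% names(splits), nrow(splits) == 6)
    counts <- as.matrix(splits[, setdiff(names(splits), "class"), drop = FALSE])
  } else {
    stopifnot(length(splits) >= 1)
    counts <- do.call(cbind, splits)
  }
  stopifnot(nrow(counts) == 6, all(counts >= 0))
  rownames(counts) <- CLASS_NAMES
  class_totals <- rowSums(counts)
  grand <- sum(counts)
  list(
    table = cbind(as.data.frame(counts), total = class_totals),
    split_totals = colSums(counts),
    grand_total = grand,
    share_pct = round_half_up(100 * class_totals / grand, 1)
  )
}

#' Write / read a confusion matrix as CSV
#'
#' 6x6 counts with a leading `true_class` name column and predicted class
#' names as headers.
#'
#' @param cm A `confusion_matrix`.
#' @param path CSV path.
#' @return For the reader, a `confusion_matrix`; for the writer, `path`
#'   invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  cm <- as_confusion_matrix(cm)
  df <- cbind(data.frame(true_class = CLASS_NAMES), as.data.frame(unclass(cm)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_confusion_matrix(df[, -1])
}

#' Packaged reference tables
#'
#' The package ships, as plain-CSV fixtures, the published validation
#' confusion matrix of the capsule-endoscopy severity classifier and the
#' per-class composition of its training/validation datasets.
#' `reference_confusion()` returns the 6x6 validation confusion matrix;
#' `reference_composition()` returns the per-class training/validation
#' counts.
#'
#' @return See above.
#' @export
reference_confusion <- function() {
  read_confusion_csv(system.file("extdata", "validation_confusion.csv",
                                 package = "ccemap", mustWork = TRUE))
}

#' @rdname reference_confusion
#' @export
reference_composition <- function() {
  utils::read.csv(system.file("extdata", "dataset_composition.csv",
                              package = "ccemap", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
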