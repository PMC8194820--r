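#' Confusion counts
#'
#' Container for the four cells of a binary confusion table.
#'
#' @param tp,fn,fp,tn Non-negative integer counts, totalling > 0.
#' @return A `confusion_counts` object.
#' @export
#' @examples
#' confusion_counts(1897, 32, 37, 884)
confusion_counts <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("confusion counts must total > 0", call. = FALSE)
  structure(as.list(cells), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  FP %d  TN %d (n = %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn + x$fp + x$tn))
  invisible(x)
}

#' Binarized confusion counts from multiclass labels
#'
#' Collapses five-class truth/prediction label vectors to an
#' infected-vs-healthy binary table: classes in `positive` count as
#' positive (infected). The default positive set is the four disease
#' classes.
#'
#' @param truth,predicted Equal-length character vectors of class labels.
#' @param positive Character vector of positive class names.
#' @param labels Allowed labels (default the five symptom classes).
#' @return A [confusion_counts()] object; the four cells sum to the number
#'   of samples.
#' @export
binary_confusion <- function(truth, predicted,
                             positive = setdiff(symptom_classes(), "healthy"),
                             labels = symptom_classes()) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("no samples to evaluate", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tpos <- truth %in% positive
  ppos <- predicted %in% positive
  confusion_counts(
    tp = sum(tpos & ppos), fn = sum(tpos & !ppos),
    fp = sum(!tpos & ppos), tn = sum(!tpos & !ppos)
  )
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Sensitivity (true positive rate), percent
#'
#' `100 * TP / (TP + FN)`. Undefined (NA, with a warning) when no positive
#' samples exist.
#'
#' @param counts A [confusion_counts()].
#' @return Percent in `[0, 100]` (unrounded).
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    warning("sensitivity undefined: no positive samples", call. = FALSE)
    return(NA_real_)
  }
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Specificity (true negative rate), percent
#'
#' `100 * TN / (TN + FP)`. Undefined (NA, with a warning) when no negative
#' samples exist.
#'
#' @param counts A [confusion_counts()].
#' @return Percent in `[0, 100]` (unrounded).
#' @export
specificity <- function(counts) {
  if (counts$tn + counts$fp == 0) {
    warning("specificity undefined: no negative samples", call. = FALSE)
    return(NA_real_)
  }
  100 * counts$tn / (counts$tn + counts$fp)
}

#' Accuracy, percent
#'
#' `100 * (TP + TN) / (TP + FN + FP + TN)`, the exact ratio of the printed
#' counts (no re-rounding of intermediate figures).
#'
#' @param counts A [confusion_counts()].
#' @return Percent in `[0, 100]` (unrounded).
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$fn + counts$fp + counts$tn
  100 * (counts$tp + counts$tn) / total
}

#' Metric report for a confusion table
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return One-row tibble: the four counts, total, and sensitivity,
#'   specificity, accuracy in percent, rounded half-up to 2 decimals
#'   (raw ratios are available from [sensitivity()] etc.).
#' @method glance confusion_counts
#' @export
glance.confusion_counts <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
    total = x$tp + x$fn + x$fp + x$tn,
    sensitivity = round_half_up(sensitivity(x)),
    specificity = round_half_up(specificity(x)),
    accuracy = round_half_up(accuracy(x))
  )
}

#' @rdname glance.confusion_counts
#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fn", "fp", "tn"),
                 count = c(x$tp, x$fn, x$fp, x$tn))
}

#' Published G-4 chili benchmark: dataset ledger
#'
#' Per-class image counts of the G-4 (Guntur-4) chili leaf field dataset
#' this pipeline models: 7,850 photographs over the five symptom classes,
#' of which 5,000 were used for training and 2,850 for testing.
#'
#' @return A tibble with `class` and `images` columns.
#' @export
g4_image_counts <- function() {
  tibble::tibble(
    class = symptom_classes(),
    images = c(1554L, 1568L, 1570L, 1577L, 1581L)
  )
}

#' Published G-4 chili benchmark: confusion counts
#'
#' The reported binary (infected vs healthy) confusion counts on the 2,850
#' test images, for the moment-correlation technique and the SVM baseline
#' it was compared against.
#'
#' @return A tibble with `technique`, `tp`, `fn`, `fp`, `tn`.
#' @export
g4_confusion_counts <- function() {
  tibble::tibble(
    technique = c("svm", "proposed"),
    tp = c(1083L, 1897L), fn = c(342L, 32L),
    fp = c(399L, 37L), tn = c(1026L, 884L)
  )
}
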