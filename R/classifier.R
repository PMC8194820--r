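#' Mean of a symptom vector
#'
#' @param u Numeric vector (non-empty).
#' @return The arithmetic mean.
#' @export
vector_mean <- function(u) {
  if (length(u) == 0) stop("cannot average an empty vector", call. = FALSE)
  sum(u) / length(u)
}

#' Difference vector
#'
#' Subtracts the vector's mean from each element; the result sums to zero.
#'
#' @param u Numeric vector (non-empty).
#' @return `u - mean(u)`.
#' @export
difference_vector <- function(u) {
  u - vector_mean(u)
}

#' Coefficient of correlation between two symptom vectors
#'
#' Scores the similarity of two feature vectors: 1 means identical shape,
#' 0 uncorrelated, -1 anti-correlated. The default `"pearson"` mode is the
#' standard Pearson r: the dot product of the mean-centered vectors divided
#' by the product of their centered norms. The `"literal"` mode instead
#' normalizes the centered difference vectors by the *raw* vector norms
#' `|u|`, `|v|` (a variant whose score does not reach 1 for identical
#' vectors unless they are already mean-free); it is retained as the
#' literal raw-norm variant and must be requested explicitly.
#'
#' @param u,v Numeric vectors of equal length >= 2.
#' @param mode `"pearson"` (default) or `"literal"`.
#' @return The correlation score, or `NA` when the denominator vanishes
#'   (a constant vector in pearson mode, a zero vector in literal mode).
#' @export
#' @examples
#' coc(c(1, 2, 3), c(2, 4, 6))  #  1
#' coc(c(1, 2, 3), c(3, 2, 1))  # -1
coc <- function(u, v, mode = c("pearson", "literal")) {
  mode <- match.arg(mode)
  if (length(u) != length(v)) {
    stop("vectors must have equal length (", length(u), " vs ", length(v), ")",
         call. = FALSE)
  }
  if (length(u) < 2) stop("vectors must have length at least 2", call. = FALSE)
  du <- difference_vector(u)
  dv <- difference_vector(v)
  den <- if (mode == "pearson") {
    sqrt(sum(du^2)) * sqrt(sum(dv^2))
  } else {
    sqrt(sum(u^2)) * sqrt(sum(v^2))
  }
  if (den == 0) return(NA_real_)
  sum(du * dv) / den
}

feature_columns <- function(dataset) {
  cols <- grep("^m_[0-9]+$", names(dataset), value = TRUE)
  if (length(cols) == 0) {
    stop("dataset has no feature columns m_1, m_2, ...", call. = FALSE)
  }
  cols[order(as.integer(sub("^m_", "", cols)))]
}

#' Classify a symptom vector against a trained feature dataset
#'
#' Scores the test vector against every record (or, with
#' `matching = "template"`, against each class's mean vector) by
#' [coc()] and returns the label attaining the maximal score. Records with
#' an undefined score (constant vectors in pearson mode) are excluded
#' rather than treated as zero. Ties go to the first occurrence in dataset
#' order.
#'
#' @param test Numeric feature vector.
#' @param dataset A feature tibble with columns `label`, optionally `path`,
#'   and `m_1 ...` (see [extract_features()] / [read_feature_dataset()]).
#' @param mode Correlation mode, see [coc()].
#' @param matching `"record"` (1-NN over all records, default) or
#'   `"template"` (per-class mean vectors).
#' @return An object of class `coc_match`: `label`, `r`, `scores` (a tibble
#'   of all defined scores), `mode`, `matching`, `rule`.
#' @export
classify_vector <- function(test, dataset, mode = c("pearson", "literal"),
                            matching = c("record", "template")) {
  mode <- match.arg(mode)
  matching <- match.arg(matching)
  if (nrow(dataset) == 0) stop("the feature dataset is empty", call. = FALSE)
  cols <- feature_columns(dataset)
  if (length(test) != length(cols)) {
    stop("feature length mismatch: test vector has ", length(test),
         " values but the dataset has ", length(cols), call. = FALSE)
  }
  M <- as.matrix(dataset[cols])
  labels <- dataset$label
  if (matching == "template") {
    keep <- !duplicated(labels)
    M <- rowsum(M, labels) / as.vector(table(labels)[sort(unique(labels))])
    M <- M[match(unique(labels), rownames(M)), , drop = FALSE]
    labels <- unique(labels)
  }
  r <- vapply(seq_len(nrow(M)), function(i) coc(test, M[i, ], mode = mode),
              numeric(1))
  scores <- tibble::tibble(label = labels, r = r)
  if ("path" %in% names(dataset) && matching == "record") {
    scores$path <- dataset$path
  }
  defined <- scores[!is.na(scores$r), , drop = FALSE]
  if (nrow(defined) == 0) {
    stop("all correlation scores are undefined (constant vectors); ",
         "cannot classify", call. = FALSE)
  }
  best <- which.max(defined$r)
  structure(
    list(label = defined$label[best], r = defined$r[best], scores = scores,
         mode = mode, matching = matching, rule = "max_coc"),
    class = "coc_match"
  )
}

#' @export
print.coc_match <- function(x, ...) {
  cat(sprintf("<coc_match> %s (r = %s, %s mode, %s matching, rule = %s)\n",
              x$label, if (is.na(x$r)) "NA" else sprintf("%.4f", x$r),
              x$mode, x$matching, x$rule))
  top <- dplyr::slice_max(x$scores, .data$r, n = 5, with_ties = FALSE)
  print(top)
  invisible(x)
}

#' All per-record correlation scores of a match
#'
#' @param x A `coc_match`.
#' @param ... Unused.
#' @return Tibble of `label`, `r` (and `path` when available), sorted by
#'   decreasing score.
#' @method tidy coc_match
#' @export
tidy.coc_match <- function(x, ...) {
  dplyr::arrange(x$scores, dplyr::desc(.data$r))
}

#' One-line summary of a match
#'
#' @param x A `coc_match`.
#' @param ... Unused.
#' @return One-row tibble: label, r, mode, matching, rule, n_scores.
#' @method glance coc_match
#' @export
glance.coc_match <- function(x, ...) {
  tibble::tibble(label = x$label, r = x$r, mode = x$mode,
                 matching = x$matching, rule = x$rule,
                 n_scores = nrow(x$scores))
}
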