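#' Segment a leaf image by fuzzy c-means
#'
#' Clusters pixels in HSV (default) or normalized RGB space, de-fuzzifies to
#' a crisp label image, and selects the region-of-interest (symptom)
#' cluster. Because fuzzy c-means uses Euclidean distances, the HSV triples
#' are embedded on the saturation-weighted hue disc,
#' `(S cos 2*pi*H, S sin 2*pi*H, V)`: hue is an angle, so this removes both
#' the wrap-around discontinuity at red and the arbitrary hue assigned to
#' achromatic pixels, while keeping exactly the hue/saturation/value
#' information.
#'
#' ROI selection: the background cluster is the one owning the largest
#' share of image-border pixels; among the remaining clusters the ROI is
#' the one whose centroid hue lies farthest (circularly) from the
#' healthy-green reference hue 1/3, provided that distance exceeds
#' `green_tol` -- clusters that are themselves green are leaf tissue, and
#' if no candidate is meaningfully non-green the image is flagged
#' symptomless with an empty ROI. A single-color image is degenerate: it
#' gets a single-cluster mask, an undefined ROI, and a warning.
#'
#' @param img A preprocessed RGB [leaf_image].
#' @param k Number of clusters. The default 5 covers the colorimetric
#'   populations a Gaussian-filtered flat-color leaf image actually
#'   contains: background, leaf tissue, symptom, and the two-sided
#'   smoothing transition ring between leaf and background.
#' @param m,epsilon,max_iter,seed Fuzzy c-means controls, see [fcm()].
#' @param feature_space `"hsv"` (default; hue-disc embedding as above) or
#'   `"rgb"` (channels scaled to `[0, 1]`).
#' @param green_tol Minimal circular hue distance from green for a cluster
#'   to count as a symptom (default 0.06, about 22 degrees).
#' @return An object of class `leaf_segmentation`: `labels` (H x W integer
#'   matrix, 0-based), `roi_cluster` (integer, or `NA` if degenerate or
#'   symptomless), `background_cluster`, `degenerate`, `no_symptom`,
#'   `feature_space`, and `fit` (the [fcm()] result).
#' @export
segment_leaf <- function(img, k = 5, m = 2, epsilon = 1e-5, max_iter = 100,
                         seed = 1, feature_space = c("hsv", "rgb"),
                         green_tol = 0.06) {
  assert_rgb(img, "segment_leaf()")
  feature_space <- match.arg(feature_space)
  d <- dim(img)
  flat_rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                    as.vector(img[, , 3]))
  if (all(flat_rgb[, 1] == flat_rgb[1, 1]) &&
      all(flat_rgb[, 2] == flat_rgb[1, 2]) &&
      all(flat_rgb[, 3] == flat_rgb[1, 3])) {
    warning("degenerate single-color image: no structure to segment",
            call. = FALSE)
    return(structure(
      list(labels = matrix(0L, d[1], d[2]), roi_cluster = NA_integer_,
           background_cluster = NA_integer_, degenerate = TRUE,
           no_symptom = NA, feature_space = feature_space, fit = NULL),
      class = "leaf_segmentation"
    ))
  }
  X <- if (feature_space == "hsv") {
    h <- rgb_to_hsv(img)
    ang <- 2 * pi * as.vector(h[, , 1])
    s <- as.vector(h[, , 2])
    cbind(s * cos(ang), s * sin(ang), as.vector(h[, , 3]))
  } else {
    flat_rgb / 255
  }
  fit <- fcm(X, k = k, m = m, epsilon = epsilon, max_iter = max_iter,
             seed = seed)
  labels <- matrix(fcm_defuzzify(fit$memberships), d[1], d[2])
  border <- c(labels[1, ], labels[d[1], ], labels[, 1], labels[, d[2]])
  border_share <- vapply(seq_len(k) - 1L, function(j) sum(border == j),
                         numeric(1))
  bg <- which.max(border_share) - 1L
  hue <- if (feature_space == "hsv") {
    (atan2(fit$centroids[, 2], fit$centroids[, 1]) / (2 * pi)) %% 1
  } else {
    grDevices::rgb2hsv(t(fit$centroids * 255), maxColorValue = 255)[1, ] %% 1
  }
  dist_green <- pmin(abs(hue - 1 / 3), 1 - abs(hue - 1 / 3))
  candidates <- setdiff(seq_len(k) - 1L, bg)
  candidates <- candidates[dist_green[candidates + 1L] > green_tol]
  no_symptom <- length(candidates) == 0
  roi <- if (no_symptom) NA_integer_ else {
    candidates[which.max(dist_green[candidates + 1L])]
  }
  structure(
    list(labels = labels, roi_cluster = roi, background_cluster = bg,
         degenerate = FALSE, no_symptom = no_symptom,
         feature_space = feature_space, fit = fit),
    class = "leaf_segmentation"
  )
}

#' Region-of-interest mask of a segmentation
#'
#' @param seg A `leaf_segmentation`.
#' @return Logical H x W matrix (all `FALSE` if the ROI is undefined).
#' @export
roi_mask <- function(seg) {
  if (is.na(seg$roi_cluster)) {
    matrix(FALSE, nrow(seg$labels), ncol(seg$labels))
  } else {
    seg$labels == seg$roi_cluster
  }
}

#' Jaccard index of two binary masks
#'
#' Intersection over union; 1 if both masks are empty.
#'
#' @param a,b Logical matrices of equal shape.
#' @return A number in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' @export
print.leaf_segmentation <- function(x, ...) {
  if (x$degenerate) {
    cat("<leaf_segmentation> degenerate (single-color image), ROI undefined\n")
  } else {
    cat(sprintf(
      "<leaf_segmentation> k = %d (%s space), ROI cluster %d (%d px), background cluster %d\n",
      x$fit$k, x$feature_space, x$roi_cluster, sum(roi_mask(x)),
      x$background_cluster))
  }
  invisible(x)
}

#' Plot a segmentation label image
#'
#' @param object A `leaf_segmentation`.
#' @param ... Unused.
#' @return A ggplot object; the ROI cluster is labeled in the legend.
#' @method autoplot leaf_segmentation
#' @export
autoplot.leaf_segmentation <- function(object, ...) {
  d <- dim(object$labels)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    cluster = factor(as.vector(object$labels))
  )
  lab <- if (is.na(object$roi_cluster)) "cluster" else
    sprintf("cluster (ROI = %d)", object$roi_cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$cluster)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = lab) +
    ggplot2::theme_void()
}

#' Export a segmentation mask
#'
#' Writes the label image as a single-channel PNG (raw cluster labels) and
#' a JSON sidecar with k, the ROI cluster, iteration count and final
#' objective value.
#'
#' @param seg A `leaf_segmentation`.
#' @param path Output PNG path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_segmentation_mask <- function(seg, path) {
  png::writePNG(seg$labels / 255, target = path)
  meta <- list(
    k = if (seg$degenerate) 1L else seg$fit$k,
    roi_cluster = seg$roi_cluster,
    background_cluster = seg$background_cluster,
    degenerate = seg$degenerate,
    iterations = if (seg$degenerate) 0L else seg$fit$iterations,
    objective = if (seg$degenerate) NA else
      utils::tail(seg$fit$objective_trace, 1)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
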