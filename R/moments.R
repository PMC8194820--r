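#' The lesion condition
#'
#' A pixel counts toward a symptom region when its green channel is low but
#' the pixel is not pure red/blue-free: `g < 90 & r > 5 & b > 5` on the
#' 0--255 scale. This fires on dark necrotic tissue and is blind to pale or
#' yellow symptoms by construction.
#'
#' @param r,g,b Numeric vectors of channel values in `[0, 255]`.
#' @return Logical vector.
#' @export
#' @examples
#' lesion_condition(100, 50, 100)  # TRUE
#' lesion_condition(100, 200, 100) # FALSE: green too high
lesion_condition <- function(r, g, b) {
  g < 90 & r > 5 & b > 5
}

#' Lesion mask of an image
#'
#' Applies [lesion_condition()] pixel-wise.
#'
#' @param img An RGB [leaf_image].
#' @return Logical H x W matrix.
#' @export
lesion_mask <- function(img) {
  assert_rgb(img, "lesion_mask()")
  lesion_condition(img[, , 1], img[, , 2], img[, , 3])
}

#' Partition an image into horizontal bands
#'
#' Divides the image into `regions` equal-height horizontal bands; the last
#' band absorbs the remainder rows. Bands are disjoint and cover the image.
#'
#' @param img A [leaf_image] (or an integer height).
#' @param regions Number of bands (1 <= regions <= image height).
#' @return A tibble with one row per band: `region`, `row_start`,
#'   `row_end` (1-based, inclusive), `height`.
#' @export
#' @examples
#' partition_regions(256, 3)$height  # 85 85 86
partition_regions <- function(img, regions = 3) {
  h <- if (is.numeric(img) && length(img) == 1L) as.integer(img) else dim(img)[1]
  regions <- as.integer(regions)
  if (regions < 1) stop("regions must be at least 1", call. = FALSE)
  if (regions > h) {
    stop("cannot cut ", h, " rows into ", regions, " bands", call. = FALSE)
  }
  base <- h %/% regions
  starts <- (seq_len(regions) - 1L) * base + 1L
  ends <- c(starts[-1] - 1L, h)
  tibble::tibble(region = seq_len(regions), row_start = starts,
                 row_end = ends, height = ends - starts + 1L)
}

region_selector <- function(img, region) {
  d <- dim(img)[1:2]
  if (is.logical(region) && is.matrix(region)) {
    stopifnot(identical(dim(region), d))
    return(region)
  }
  sel <- matrix(FALSE, d[1], d[2])
  sel[region, ] <- TRUE  # integer row indices (1-based)
  sel
}

#' Area, coordinate sums and centroid of a region
#'
#' Counts the region pixels satisfying the lesion condition (`area`), sums
#' their 0-based row (`sumx`) and column (`sumy`) coordinates, and derives
#' the centroid `(sumx/area, sumy/area)`. Rows are the x axis (height),
#' columns the y axis (width). A region with no qualifying pixel has
#' `area = 0` and `NA` centroids, with `defined = FALSE`.
#'
#' @param img An RGB [leaf_image].
#' @param region Either a logical H x W matrix or a vector of 1-based row
#'   indices (a horizontal band).
#' @return A one-row tibble: `area`, `sumx`, `sumy`, `xcentroid`,
#'   `ycentroid`, `defined`.
#' @export
region_stats <- function(img, region) {
  sel <- region_selector(img, region)
  q <- lesion_mask(img) & sel
  idx <- which(q, arr.ind = TRUE)
  area <- nrow(idx)
  sumx <- sum(idx[, 1] - 1)
  sumy <- sum(idx[, 2] - 1)
  tibble::tibble(
    area = area, sumx = sumx, sumy = sumy,
    xcentroid = if (area > 0) sumx / area else NA_real_,
    ycentroid = if (area > 0) sumy / area else NA_real_,
    defined = area > 0
  )
}

#' Centroid of the whole image's qualifying pixels
#'
#' @param img An RGB [leaf_image].
#' @return A list with `xloc`, `yloc` (0-based; `NA` if no pixel qualifies)
#'   and `defined`.
#' @export
image_centroid <- function(img) {
  s <- region_stats(img, matrix(TRUE, dim(img)[1], dim(img)[2]))
  list(xloc = s$xcentroid, yloc = s$ycentroid, defined = s$defined)
}

moment_order <- function() {
  c("m00", "m01", "m02", "m10", "m11", "m12", "m20", "m21", "m22")
}

#' Geometric moments of a region
#'
#' Computes the nine moments `m_pq = sum (x - xloc)^p (y - yloc)^q` for
#' `p, q` in 0..2, summing over the region's qualifying (lesion-condition)
#' pixels only, with x the 0-based row and y the 0-based column. `m00` is
#' the region's qualifying area; first-order moments vanish when the
#' center is the region centroid; second-order moments measure spread. An
#' empty foreground yields all-zero moments.
#'
#' @param img An RGB [leaf_image].
#' @param region Logical H x W matrix or 1-based row indices.
#' @param xloc,yloc Moment center (0-based coordinates, finite).
#' @return Named numeric vector of length 9 in the fixed order
#'   `m00, m01, m02, m10, m11, m12, m20, m21, m22`.
#' @export
region_moments <- function(img, region, xloc, yloc) {
  if (!is.finite(xloc) || !is.finite(yloc)) {
    stop("moment center must be finite", call. = FALSE)
  }
  sel <- region_selector(img, region)
  q <- lesion_mask(img) & sel
  idx <- which(q, arr.ind = TRUE)
  out <- stats::setNames(numeric(9), moment_order())
  if (nrow(idx) == 0) return(out)
  x <- (idx[, 1] - 1) - xloc
  y <- (idx[, 2] - 1) - yloc
  i <- 0
  for (p in 0:2) {
    for (qq in 0:2) {
      i <- i + 1
      out[i] <- sum(x^p * y^qq)
    }
  }
  out
}

#' Build the symptom feature vector of an image
#'
#' Splits the image into `regions` horizontal bands and concatenates each
#' band's nine geometric moments over its qualifying (lesion-condition)
#' pixels, giving a vector of length `9 * regions` (27 by default). With
#' `center_mode = "region"` each band's moments are centered on that band's
#' own lesion centroid, making the vector invariant to translating the
#' lesion pattern within a band; `"image"` centers every band on the
#' whole-image lesion centroid. Bands (or images) with no qualifying pixel
#' contribute zero moments, with a warning of class
#' `chilimoments_empty_region`.
#'
#' @param img A preprocessed RGB [leaf_image].
#' @param mask Optional logical H x W matrix (e.g. a segmentation ROI) that
#'   further restricts the qualifying pixels; `NULL` (default) uses the
#'   lesion condition alone.
#' @param regions Number of horizontal bands (default 3).
#' @param center_mode `"region"` (default) or `"image"`.
#' @return Named numeric vector `m_1 ... m_(9*regions)` with attributes
#'   `region_count`, `center_mode` and `moment_labels`.
#' @export
build_feature_vector <- function(img, mask = NULL, regions = 3,
                                 center_mode = c("region", "image")) {
  center_mode <- match.arg(center_mode)
  work <- img
  if (!is.null(mask)) {
    # zero out non-mask pixels so they can never satisfy the lesion condition
    stopifnot(identical(dim(mask), dim(img)[1:2]))
    a <- unclass(img)
    for (ch in 1:3) {
      plane <- a[, , ch]
      plane[!mask] <- 0
      a[, , ch] <- plane
    }
    attributes(a) <- list(dim = dim(img))
    work <- leaf_image(a, "rgb")
  }
  bands <- partition_regions(work, regions)
  ic <- if (center_mode == "image") image_centroid(work) else NULL
  empty <- integer(0)
  vec <- numeric(0)
  labels <- character(0)
  for (i in seq_len(nrow(bands))) {
    rows <- bands$row_start[i]:bands$row_end[i]
    st <- region_stats(work, rows)
    if (!st$defined) {
      mom <- stats::setNames(numeric(9), moment_order())
      empty <- c(empty, i)
    } else if (center_mode == "region") {
      mom <- region_moments(work, rows, st$xcentroid, st$ycentroid)
    } else if (!ic$defined) {
      mom <- stats::setNames(numeric(9), moment_order())
      empty <- c(empty, i)
    } else {
      mom <- region_moments(work, rows, ic$xloc, ic$yloc)
    }
    vec <- c(vec, mom)
    labels <- c(labels, paste0("r", i, "_", names(mom)))
  }
  if (length(empty)) {
    rlang::warn(
      paste0("no qualifying lesion pixels in region(s) ",
             paste(empty, collapse = ", "), "; zero moments substituted"),
      class = "chilimoments_empty_region"
    )
  }
  names(vec) <- paste0("m_", seq_along(vec))
  attr(vec, "region_count") <- as.integer(regions)
  attr(vec, "center_mode") <- center_mode
  attr(vec, "moment_labels") <- labels
  vec
}
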