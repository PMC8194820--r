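#' Leaf image container
#'
#' A `leaf_image` is a numeric `H x W x 3` array with a `colorspace`
#' attribute. RGB images hold channel values on the 0--255 scale (reals are
#' allowed, e.g. after filtering); HSV images hold hue in `[0, 1)` and
#' saturation/value in `[0, 1]`. The first array index is the image row
#' (height, "x" in the moment formulas), the second the column (width, "y"),
#' both 0-based in all coordinate arithmetic.
#'
#' @param x A numeric `H x W x 3` array.
#' @param colorspace Either `"rgb"` or `"hsv"`.
#' @return A `leaf_image` object.
#' @export
#' @examples
#' img <- leaf_image(array(128, dim = c(4, 4, 3)))
#' dim(img)
leaf_image <- function(x, colorspace = c("rgb", "hsv")) {
  colorspace <- match.arg(colorspace)
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("a leaf_image must be a numeric H x W x 3 array", call. = FALSE)
  }
  if (!is.numeric(x)) stop("pixel values must be numeric", call. = FALSE)
  if (any(dim(x)[1:2] < 1L)) stop("image height and width must be positive", call. = FALSE)
  if (colorspace == "rgb") {
    if (min(x) < 0 || max(x) > 255) {
      stop("RGB channel values must lie in [0, 255]", call. = FALSE)
    }
  } else {
    if (min(x) < 0 || max(x) > 1) {
      stop("HSV channel values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(x, colorspace = colorspace, class = c("leaf_image", "array"))
}

img_colorspace <- function(img) attr(img, "colorspace") %||% "rgb"

assert_rgb <- function(img, what = "this operation") {
  if (img_colorspace(img) != "rgb") {
    stop(what, " requires an RGB image", call. = FALSE)
  }
  invisible(img)
}

#' @export
print.leaf_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<leaf_image> %d x %d pixels, %s, values [%.3g, %.3g]\n",
    d[1], d[2], img_colorspace(x), min(x), max(x)
  ))
  invisible(x)
}

#' Read a leaf image from a PNG file
#'
#' @param path Path to a PNG file.
#' @return An RGB [leaf_image] on the 0--255 scale (alpha, if present, is
#'   dropped; grayscale is replicated across channels).
#' @export
read_leaf_png <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  leaf_image(a * 255, colorspace = "rgb")
}

#' Write a leaf image to a PNG file
#'
#' @param img An RGB [leaf_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_leaf_png <- function(img, path) {
  assert_rgb(img, "write_leaf_png()")
  a <- unclass(img) / 255
  attributes(a) <- list(dim = dim(img))
  png::writePNG(pmin(pmax(a, 0), 1), target = path)
  invisible(path)
}

#' Plot a leaf image
#'
#' Renders the pixel grid with [ggplot2::geom_raster()].
#'
#' @param object A [leaf_image] (RGB).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leaf_image
#' @export
autoplot.leaf_image <- function(object, ...) {
  assert_rgb(object, "autoplot.leaf_image()")
  d <- dim(object)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(
      as.vector(object[, , 1]), as.vector(object[, , 2]),
      as.vector(object[, , 3]), maxColorValue = 255
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang %||% .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
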