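#' Resize an image
#'
#' Resamples to the exact target size (default bilinear; nearest-neighbor
#' for bit-exactness in tests). Channel count is preserved.
#'
#' @param img A [leaf_image].
#' @param height,width Target size in pixels (> 0).
#' @param method `"bilinear"` or `"nearest"`.
#' @return A [leaf_image] of exactly `height x width` pixels.
#' @export
resize_image <- function(img, height = 256, width = 256,
                         method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (height < 1 || width < 1) stop("target size must be positive", call. = FALSE)
  cs <- img_colorspace(img)
  if (method == "nearest" && all(dim(img)[1:2] == c(height, width))) {
    return(img)  # identity, bit-exact
  }
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  e <- EBImage::Image(a, colormode = "Color")
  out <- EBImage::resize(e, w = height, h = width,
                         filter = if (method == "bilinear") "bilinear" else "none")
  res <- EBImage::imageData(out)
  if (cs == "rgb") res <- pmin(pmax(res, 0), 255)
  leaf_image(res, cs)
}

gaussian_kernel_1d <- function(sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# Symmetric (reflect) padding indices for a length-n axis and pad width r.
reflect_index <- function(n, r) {
  c(r:1, 1:n, n:(n - r + 1))
}

conv1_reflect <- function(mat, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  r <- (length(k) - 1L) / 2L
  if (along == "rows") {
    padded <- mat[reflect_index(nrow(mat), r), , drop = FALSE]
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(nrow(mat)), , drop = FALSE]
    }
  } else {
    padded <- mat[, reflect_index(ncol(mat), r), drop = FALSE]
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[, (j - 1) + seq_len(ncol(mat)), drop = FALSE]
    }
  }
  out
}

#' Gaussian denoising
#'
#' Per-channel Gaussian smoothing by separable convolution with symmetric
#' (reflect) boundary padding, so no halo appears at the image border.
#' `sigma = 0` is the identity. The kernel is truncated at three standard
#' deviations and renormalized.
#'
#' @param img A [leaf_image].
#' @param sigma Gaussian standard deviation in pixels (>= 0; default 1).
#' @return A smoothed [leaf_image] of the same shape and colorspace.
#' @export
gaussian_denoise <- function(img, sigma = 1) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  out <- unclass(img)
  for (ch in 1:3) {
    out[, , ch] <- conv1_reflect(conv1_reflect(out[, , ch], k, "rows"), k, "cols")
  }
  cs <- img_colorspace(img)
  if (cs == "rgb") out <- pmin(pmax(out, 0), 255)
  leaf_image(out, cs)
}

#' Convert RGB to HSV
#'
#' Standard hexcone transform; hue is normalized to `[0, 1)` (a full turn of
#' the color circle is 1, red at 0, green at 1/3), saturation and value to
#' `[0, 1]`.
#'
#' @param img An RGB [leaf_image].
#' @return An HSV [leaf_image].
#' @export
rgb_to_hsv <- function(img) {
  assert_rgb(img, "rgb_to_hsv()")
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- matrix(hsv[1, ] %% 1, d[1], d[2])
  out[, , 2] <- matrix(hsv[2, ], d[1], d[2])
  out[, , 3] <- matrix(hsv[3, ], d[1], d[2])
  leaf_image(out, "hsv")
}

#' Convert HSV back to RGB
#'
#' Inverse of [rgb_to_hsv()]; recovers 8-bit RGB within one level per
#' channel.
#'
#' @param img An HSV [leaf_image].
#' @return An RGB [leaf_image].
#' @export
hsv_to_rgb <- function(img) {
  if (img_colorspace(img) != "hsv") {
    stop("hsv_to_rgb() requires an HSV image", call. = FALSE)
  }
  d <- dim(img)
  cols <- grDevices::hsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                         as.vector(img[, , 3]))
  rgb <- grDevices::col2rgb(cols)
  out <- array(0, dim = d)
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, ], d[1], d[2])
  leaf_image(out, "rgb")
}

#' Preprocess a leaf image
#'
#' The standard input conditioning: resize to a fixed square (default
#' 256 x 256), then Gaussian denoising. Downstream stages consume this
#' image; segmentation converts it to HSV internally.
#'
#' @param img An RGB [leaf_image].
#' @param size Target side length in pixels.
#' @param sigma Gaussian sigma in pixels (0 disables denoising).
#' @param interpolation Resize method, `"bilinear"` or `"nearest"`.
#' @return A preprocessed RGB [leaf_image] of `size x size` pixels.
#' @export
preprocess_image <- function(img, size = 256, sigma = 1,
                             interpolation = "bilinear") {
  assert_rgb(img, "preprocess_image()")
  gaussian_denoise(resize_image(img, size, size, method = interpolation), sigma)
}
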