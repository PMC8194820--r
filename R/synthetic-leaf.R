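#' The five symptom classes
#'
#' Class inventory for the G-4 chili leaf problem: four foliar diseases plus
#' healthy. Bacterial leaf spot shows small dark necrotic discs, powdery
#' mildew (whitefly) pale whitish patches, leaf curl a deformed leaf margin
#' with no color lesion, Fusarium wilt yellowed patches; healthy leaves bear
#' no symptom.
#'
#' @return Character vector of the five class names, in canonical order.
#' @export
symptom_classes <- function() {
  c("bacterial_leaf_spot", "powdery_mildew", "leaf_curl", "fusarium_wilt",
    "healthy")
}

#' Default symptom palette
#'
#' Flat colors used by the synthetic generator. The bacterial-spot color is
#' the only one satisfying the lesion condition (g < 90, r > 5, b > 5);
#' leaf tissue, background, powdery and wilt patches never do.
#'
#' @return Named list of RGB triples on the 0--255 scale.
#' @export
leaf_palette <- function() {
  list(
    leaf       = c(40, 140, 50),
    background = c(235, 235, 235),
    bacterial_leaf_spot = c(80, 50, 30),
    powdery_mildew      = c(250, 250, 250),
    fusarium_wilt       = c(200, 190, 20)
  )
}

default_symptom_count <- function(class) {
  switch(class,
    bacterial_leaf_spot = 3L, powdery_mildew = 2L, leaf_curl = 5L,
    fusarium_wilt = 3L, healthy = 0L
  )
}

default_symptom_radius <- function(class) {
  switch(class,
    bacterial_leaf_spot = 6, powdery_mildew = 12, leaf_curl = 12,
    fusarium_wilt = 10, healthy = 0
  )
}

#' Specify a synthetic leaf image
#'
#' A `leaf_spec` fixes everything the generator needs: symptom class, image
#' size, colors, symptom count and radius, and the random seed. For
#' `leaf_curl` the "symptoms" are boundary deformations: `symptom_count` is
#' the number of sinusoidal curl waves along the margin and `symptom_radius`
#' the deformation amplitude in pixels. `symptom_count` must be zero exactly
#' for the healthy class.
#'
#' @param class One of [symptom_classes()].
#' @param image_size Image side length in pixels (square image, >= 64).
#' @param leaf_color,background_color RGB triples (0--255).
#' @param symptom_count Number of symptom marks (curl waves for
#'   `leaf_curl`); defaults per class.
#' @param symptom_radius Symptom radius (curl amplitude) in pixels.
#' @param seed Integer seed; the same spec always renders the same pixels.
#' @return A `leaf_spec` object.
#' @export
#' @examples
#' sp <- leaf_spec("bacterial_leaf_spot", seed = 7)
#' img <- generate_leaf_image(sp)
leaf_spec <- function(class, image_size = 256, leaf_color = leaf_palette()$leaf,
                      background_color = leaf_palette()$background,
                      symptom_count = NULL, symptom_radius = NULL, seed = 1) {
  if (length(class) != 1L || !class %in% symptom_classes()) {
    stop("unknown symptom class: ", paste(class, collapse = ", "),
         "; must be one of ", paste(symptom_classes(), collapse = ", "),
         call. = FALSE)
  }
  if (image_size < 64) stop("image_size must be at least 64 pixels", call. = FALSE)
  symptom_count <- as.integer(symptom_count %||% default_symptom_count(class))
  symptom_radius <- symptom_radius %||% default_symptom_radius(class)
  if (class == "healthy" && symptom_count != 0L) {
    stop("healthy leaves must have symptom_count = 0", call. = FALSE)
  }
  if (class != "healthy" && symptom_count < 1L) {
    stop("diseased classes need symptom_count >= 1", call. = FALSE)
  }
  structure(
    list(class = class, image_size = as.integer(image_size),
         leaf_color = leaf_color, background_color = background_color,
         symptom_count = symptom_count, symptom_radius = symptom_radius,
         seed = as.integer(seed)),
    class = "leaf_spec"
  )
}

# Rasterize an elliptical (optionally curl-deformed) silhouette on the
# 0-based pixel grid. Returns a logical H x W mask.
leaf_silhouette <- function(n, a, b, curl_waves = 0, curl_amp = 0,
                            curl_phase = 0) {
  cx <- (n - 1) / 2
  rows <- matrix(0:(n - 1), nrow = n, ncol = n)
  cols <- t(rows)
  dx <- (rows - cx) / a
  dy <- (cols - cx) / b
  rho <- sqrt(dx^2 + dy^2)
  if (curl_waves > 0) {
    theta <- atan2(dy, dx)
    edge <- 1 + (curl_amp / ((a + b) / 2)) * sin(curl_waves * theta + curl_phase)
  } else {
    edge <- 1
  }
  rho <= edge
}

disc_mask <- function(n, center, radius) {
  rows <- matrix(0:(n - 1), nrow = n, ncol = n)
  cols <- t(rows)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# Sample disjoint disc centers fully inside the leaf mask (0-based coords).
place_discs <- function(leaf, count, radius, max_tries = 500) {
  n <- nrow(leaf)
  inside <- which(leaf)
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < count && tries < max_tries) {
    tries <- tries + 1
    idx <- inside[sample.int(length(inside), 1L)]
    cr <- (idx - 1) %% n       # 0-based row
    cc <- (idx - 1) %/% n      # 0-based col
    d <- disc_mask(n, c(cr, cc), radius)
    if (any(d & !leaf)) next
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) < 2 * radius + 2)) next
    centers <- rbind(centers, c(cr, cc))
  }
  if (nrow(centers) < count) {
    stop("could not place ", count, " disjoint symptoms of radius ", radius,
         " inside the leaf; reduce count or radius", call. = FALSE)
  }
  centers
}

#' Generate a synthetic chili leaf image
#'
#' Renders a green leaf (an ellipse with seeded eccentricity; curl-deformed
#' margin for `leaf_curl`) on a plain background, then draws hard-edged
#' class-specific symptoms: dark necrotic discs (bacterial leaf spot),
#' near-white patches (powdery mildew), yellow patches (Fusarium wilt), or
#' none (leaf curl, healthy). No anti-aliasing is applied, so pixel-count
#' oracles over the symptom marks are exact. The same spec always produces
#' bit-identical pixels.
#'
#' @param spec A [leaf_spec()].
#' @return An RGB [leaf_image] with attributes `leaf_mask` (logical H x W
#'   silhouette), `lesion_mask` (logical H x W ground-truth symptom pixels;
#'   all `FALSE` for leaf curl and healthy), `symptom_centers` (matrix of
#'   0-based disc centers) and `spec`.
#' @export
generate_leaf_image <- function(spec) {
  if (!inherits(spec, "leaf_spec")) spec <- do.call(leaf_spec, as.list(spec))
  n <- spec$image_size
  withr::with_seed(spec$seed, {
    a <- n * stats::runif(1, 0.33, 0.42)
    b <- n * stats::runif(1, 0.24, 0.32)
    if (spec$class == "leaf_curl") {
      leaf <- leaf_silhouette(n, a, b, curl_waves = spec$symptom_count,
                              curl_amp = spec$symptom_radius,
                              curl_phase = stats::runif(1, 0, 2 * pi))
    } else {
      leaf <- leaf_silhouette(n, a, b)
    }
    img <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background_color[ch], n, n)
      plane[leaf] <- spec$leaf_color[ch]
      img[, , ch] <- plane
    }
    lesion <- matrix(FALSE, n, n)
    centers <- matrix(numeric(0), ncol = 2)
    if (spec$class %in% c("bacterial_leaf_spot", "powdery_mildew", "fusarium_wilt")) {
      col <- leaf_palette()[[spec$class]]
      centers <- place_discs(leaf, spec$symptom_count, spec$symptom_radius)
      for (i in seq_len(nrow(centers))) {
        d <- disc_mask(n, centers[i, ], spec$symptom_radius)
        lesion <- lesion | d
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[d] <- col[ch]
          img[, , ch] <- plane
        }
      }
    }
    out <- leaf_image(img, "rgb")
    attr(out, "leaf_mask") <- leaf
    attr(out, "lesion_mask") <- lesion
    attr(out, "symptom_centers") <- centers
    attr(out, "spec") <- spec
    out
  })
}

#' Default jitter ranges for the synthetic dataset generator
#'
#' Per-class uniform ranges for symptom count and radius, giving each class
#' within-class variance in lesion number, size, and (through per-image
#' seeds) leaf shape and symptom position.
#'
#' @return Named list with `count` and `radius` range lists.
#' @export
leaf_jitter <- function() {
  list(
    count = list(bacterial_leaf_spot = c(2L, 5L), powdery_mildew = c(1L, 3L),
                 leaf_curl = c(3L, 6L), fusarium_wilt = c(2L, 4L),
                 healthy = c(0L, 0L)),
    radius = list(bacterial_leaf_spot = c(4, 9), powdery_mildew = c(9, 16),
                  leaf_curl = c(8, 14), fusarium_wilt = c(7, 13),
                  healthy = c(0, 0))
  )
}

#' Generate a labeled synthetic leaf dataset
#'
#' Produces `n_per_class` images for each requested class, with per-image
#' seeds derived deterministically from the master seed and per-image
#' symptom count/radius drawn from the jitter ranges. Two calls with the
#' same arguments return identical images and labels.
#'
#' @param n_per_class Images per class (>= 1).
#' @param seed Master seed.
#' @param classes Character vector of classes (default all five).
#' @param jitter Jitter ranges, see [leaf_jitter()].
#' @param image_size Image side length in pixels.
#' @return A tibble with one row per image: `class`, `seed`,
#'   `symptom_count`, `symptom_radius`, and list-columns `image`,
#'   `lesion_mask`, `leaf_mask`.
#' @export
#' @examples
#' ds <- generate_leaf_dataset(2, seed = 3)
#' dplyr::count(ds, class)
generate_leaf_dataset <- function(n_per_class, seed = 1,
                                  classes = symptom_classes(),
                                  jitter = leaf_jitter(), image_size = 256) {
  if (n_per_class < 1) stop("n_per_class must be at least 1", call. = FALSE)
  bad <- setdiff(classes, symptom_classes())
  if (length(bad)) stop("unknown symptom class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  plan <- withr::with_seed(seed, {
    purrr::map_dfr(classes, function(cl) {
      cnt_r <- jitter$count[[cl]]
      rad_r <- jitter$radius[[cl]]
      tibble::tibble(
        class = cl,
        seed = sample.int(.Machine$integer.max, n_per_class),
        symptom_count = if (cl == "healthy") 0L else
          sample(seq.int(cnt_r[1], cnt_r[2]), n_per_class, replace = TRUE),
        symptom_radius = if (cl == "healthy") 0 else
          stats::runif(n_per_class, rad_r[1], rad_r[2])
      )
    })
  })
  rendered <- purrr::pmap(plan, function(class, seed, symptom_count, symptom_radius) {
    sp <- leaf_spec(class, image_size = image_size,
                    symptom_count = if (class == "healthy") 0L else symptom_count,
                    symptom_radius = symptom_radius, seed = seed)
    generate_leaf_image(sp)
  })
  plan$image <- rendered
  plan$lesion_mask <- purrr::map(rendered, attr, "lesion_mask")
  plan$leaf_mask <- purrr::map(rendered, attr, "leaf_mask")
  plan
}

#' Write a synthetic dataset to disk
#'
#' Saves each image as PNG and a `manifest.csv` with columns `path`,
#' `class`, `seed`.
#'
#' @param dataset A tibble from [generate_leaf_dataset()].
#' @param dir Output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_leaf_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("%s_%04d.png", dataset$class, seq_len(nrow(dataset)))
  purrr::walk2(dataset$image, paths, function(img, p) {
    write_leaf_png(img, file.path(dir, p))
  })
  manifest <- tibble::tibble(path = paths, class = dataset$class,
                             seed = dataset$seed)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
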