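#' Pipeline configuration
#'
#' One object fixing every stage's parameters so a run is reproducible end
#' to end: preprocessing (target size, Gaussian sigma, interpolation),
#' fuzzy c-means (k, fuzzifier, stopping threshold, iteration cap, seed,
#' feature space), featurization (band count, moment center mode, whether
#' the segmentation ROI additionally masks the lesion pixels), similarity
#' (correlation mode, record vs template matching, the label assigned to
#' all-zero symptom vectors), and evaluation (the positive class set).
#'
#' @param preprocess,fcm,features,similarity,evaluation Named lists
#'   overriding individual defaults.
#' @return A validated `pipeline_config` object.
#' @export
#' @examples
#' cfg <- pipeline_config(fcm = list(k = 4))
#' cfg$fcm$k
pipeline_config <- function(preprocess = list(), fcm = list(),
                            features = list(), similarity = list(),
                            evaluation = list()) {
  cfg <- list(
    preprocess = utils::modifyList(
      list(size = 256L, sigma = 1, interpolation = "bilinear"), preprocess),
    fcm = utils::modifyList(
      list(k = 5L, m = 2, epsilon = 1e-5, max_iter = 100L, seed = 1L,
           feature_space = "hsv"), fcm),
    features = utils::modifyList(
      list(regions = 3L, center_mode = "region", use_mask = FALSE), features),
    similarity = utils::modifyList(
      list(mode = "pearson", matching = "record",
           no_symptom_label = "healthy"), similarity),
    evaluation = utils::modifyList(
      list(positive = setdiff(symptom_classes(), "healthy")), evaluation)
  )
  stopifnot(
    cfg$preprocess$size >= 64, cfg$preprocess$sigma >= 0,
    cfg$fcm$k >= 1, cfg$fcm$m > 1, cfg$fcm$epsilon > 0, cfg$fcm$max_iter >= 1,
    cfg$features$regions >= 1,
    cfg$features$center_mode %in% c("region", "image"),
    cfg$similarity$mode %in% c("pearson", "literal"),
    cfg$similarity$matching %in% c("record", "template")
  )
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Featurize one image through the configured pipeline
#'
#' Preprocesses the image and computes its moment feature vector. When
#' `config$features$use_mask` is `TRUE` the image is first segmented and
#' the ROI mask intersects the lesion condition; otherwise segmentation is
#' skipped in this path (the moment features depend only on the lesion
#' condition, so the crisp mask adds nothing under the default
#' configuration).
#'
#' @param img An RGB [leaf_image].
#' @param config A [pipeline_config()].
#' @return A feature vector, see [build_feature_vector()].
#' @export
featurize_image <- function(img, config = pipeline_config()) {
  pre <- preprocess_image(img, size = config$preprocess$size,
                          sigma = config$preprocess$sigma,
                          interpolation = config$preprocess$interpolation)
  mask <- NULL
  if (isTRUE(config$features$use_mask)) {
    seg <- segment_leaf(pre, k = config$fcm$k, m = config$fcm$m,
                        epsilon = config$fcm$epsilon,
                        max_iter = config$fcm$max_iter, seed = config$fcm$seed,
                        feature_space = config$fcm$feature_space)
    mask <- roi_mask(seg)
  }
  withCallingHandlers(
    build_feature_vector(pre, mask = mask, regions = config$features$regions,
                         center_mode = config$features$center_mode),
    chilimoments_empty_region = function(w) invokeRestart("muffleWarning")
  )
}

resolve_images <- function(images, quiet = FALSE) {
  # Accepts a tibble with an `image` list-column, or with `path`s to PNGs.
  if ("image" %in% names(images)) {
    images$.ok <- TRUE
    return(images)
  }
  if (!"path" %in% names(images)) {
    stop("images must carry an `image` list-column or a `path` column",
         call. = FALSE)
  }
  loaded <- purrr::map(images$path, function(p) {
    tryCatch(read_leaf_png(p), error = function(e) {
      if (!quiet) rlang::inform(paste0("skipping unreadable image: ", p))
      NULL
    })
  })
  images$image <- loaded
  images$.ok <- !purrr::map_lgl(loaded, is.null)
  images
}

#' Train: build the feature-vector dataset
#'
#' Featurizes every (readable) training image and returns the labeled
#' feature table, one record per image: infection name, source path,
#' moment vector. Unreadable images are skipped with a message and counted
#' in the `summary` attribute. Deterministic given the configuration.
#'
#' @param images A tibble with `class` (or `label`) and either an `image`
#'   list-column or a `path` column of PNG files.
#' @param config A [pipeline_config()].
#' @param path Optional CSV path; when given, the dataset is also written
#'   via [write_feature_dataset()].
#' @param quiet Suppress progress messages.
#' @return The feature tibble, with attribute `summary` (per-class counts
#'   and number skipped).
#' @export
run_train <- function(images, config = pipeline_config(), path = NULL,
                      quiet = FALSE) {
  images <- resolve_images(images, quiet = quiet)
  kept <- images[images$.ok, , drop = FALSE]
  ds <- extract_features(kept, config)
  smry <- list(
    n = nrow(ds), n_skipped = sum(!images$.ok),
    per_class = table(ds$label)
  )
  if (!quiet) {
    rlang::inform(sprintf("trained feature dataset: %d records (%d skipped)",
                          smry$n, smry$n_skipped))
  }
  if (!is.null(path)) {
    write_feature_dataset(ds, path, regions = config$features$regions,
                          center_mode = config$features$center_mode)
  }
  attr(ds, "summary") <- smry
  ds
}

#' Classify one leaf image against a trained dataset
#'
#' Runs the full chain preprocess -> (segment) -> featurize -> correlate.
#' An all-zero symptom vector means no pixel satisfied the lesion
#' condition, i.e. no detectable symptom: such images are assigned the
#' configured `no_symptom_label` directly (rule `"no_symptom"`), since
#' correlation against it is undefined.
#'
#' @param image An RGB [leaf_image] or a PNG path.
#' @param dataset A feature tibble ([run_train()]) or a CSV path.
#' @param config A [pipeline_config()].
#' @param quiet Suppress messages.
#' @return A `coc_match` (see [classify_vector()]); for the no-symptom rule
#'   `r` is `NA` and `rule` is `"no_symptom"`.
#' @export
run_classify <- function(image, dataset, config = pipeline_config(),
                         quiet = FALSE) {
  if (is.character(image)) image <- read_leaf_png(image)
  if (is.character(dataset)) dataset <- read_feature_dataset(dataset)
  cols <- feature_columns(dataset)
  expected <- 9L * config$features$regions
  if (length(cols) != expected) {
    stop("feature length mismatch: the configuration produces vectors of ",
         "length ", expected, " but the dataset has ", length(cols),
         call. = FALSE)
  }
  vec <- featurize_image(image, config)
  if (all(vec == 0)) {
    if (!quiet) {
      rlang::inform(paste0(
        "no pixel satisfied the lesion condition; applying the no-symptom ",
        "rule -> ", config$similarity$no_symptom_label))
    }
    return(structure(
      list(label = config$similarity$no_symptom_label, r = NA_real_,
           scores = tibble::tibble(label = character(), r = numeric()),
           mode = config$similarity$mode,
           matching = config$similarity$matching, rule = "no_symptom"),
      class = "coc_match"
    ))
  }
  classify_vector(vec, dataset, mode = config$similarity$mode,
                  matching = config$similarity$matching)
}

#' Evaluate predictions against truth
#'
#' Collapses the multiclass labels to infected-vs-healthy (per the
#' configured positive set) and reports the confusion counts and the three
#' headline metrics.
#'
#' @param predictions,truth Equal-length character vectors of class labels.
#' @param config A [pipeline_config()].
#' @return A list: `counts` (a [confusion_counts()]), `metrics` (the
#'   [glance.confusion_counts()] tibble), `multiclass_accuracy` (percent).
#' @export
run_evaluate <- function(predictions, truth, config = pipeline_config()) {
  counts <- binary_confusion(truth, predictions,
                             positive = config$evaluation$positive)
  list(counts = counts, metrics = glance(counts),
       multiclass_accuracy = 100 * mean(predictions == truth))
}

#' Run the full synthetic experiment
#'
#' Generates seeded train and test splits from the synthetic leaf
#' generator, builds the feature dataset, classifies every held-out image,
#' and evaluates. Identical seed and configuration give identical results.
#'
#' @param n_train,n_test Images per class in each split.
#' @param seed Master seed; train/test sub-seeds are derived from it.
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list: `features` (training table), `predictions` (tibble of
#'   `truth`, `predicted`, `r`, `rule`), `multiclass_accuracy` (percent),
#'   `per_class` (accuracy per true class), `counts`, `metrics`.
#' @export
run_demo <- function(n_train = 30, n_test = 10, seed = 1,
                     config = pipeline_config(), quiet = TRUE) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2))
  train <- generate_leaf_dataset(n_train, seed = seeds[1])
  test <- generate_leaf_dataset(n_test, seed = seeds[2])
  features <- run_train(train, config, quiet = quiet)
  matches <- purrr::map(test$image, function(img) {
    run_classify(img, features, config, quiet = TRUE)
  })
  predictions <- tibble::tibble(
    truth = test$class,
    predicted = purrr::map_chr(matches, "label"),
    r = purrr::map_dbl(matches, "r"),
    rule = purrr::map_chr(matches, "rule")
  )
  ev <- run_evaluate(predictions$predicted, predictions$truth, config)
  per_class <- dplyr::summarise(
    dplyr::group_by(predictions, .data$truth),
    accuracy = 100 * mean(.data$predicted == .data$truth), .groups = "drop")
  if (!quiet) {
    rlang::inform(sprintf("hold-out multiclass accuracy: %.1f%%",
                          ev$multiclass_accuracy))
  }
  list(features = features, predictions = predictions,
       multiclass_accuracy = ev$multiclass_accuracy, per_class = per_class,
       counts = ev$counts, metrics = ev$metrics)
}
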