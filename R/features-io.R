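#' Extract feature vectors from a set of images
#'
#' Runs the featurization path of the pipeline (preprocess, optional
#' segmentation, moment features) over a dataset tibble and returns a
#' feature table, one row per image.
#'
#' @param images A tibble with an `image` list-column of RGB [leaf_image]s
#'   and a `class` (or `label`) column; an optional `path` column is
#'   carried through.
#' @param config A [pipeline_config()].
#' @return A tibble with columns `label`, `path`, `m_1 ...`.
#' @export
extract_features <- function(images, config = pipeline_config()) {
  label <- images[[if ("label" %in% names(images)) "label" else "class"]]
  path <- if ("path" %in% names(images)) images$path else NA_character_
  vecs <- purrr::map(images$image, featurize_image, config = config)
  M <- do.call(rbind, vecs)
  out <- tibble::as_tibble(M)
  dplyr::bind_cols(tibble::tibble(label = label, path = path), out)
}

#' Write a feature dataset to CSV (with JSON header sidecar)
#'
#' The CSV holds one record per image: the infection name, the source file
#' path, and the moment vector (`label`, `path`, `m_1 ... m_N`). A JSON
#' sidecar `<path>.json` records the vector convention (region count,
#' center mode, moment order) so the loader can validate consistency.
#'
#' @param dataset A feature tibble (see [extract_features()]).
#' @param path Output CSV path.
#' @param regions,center_mode The featurization convention to record.
#' @return `path`, invisibly.
#' @export
write_feature_dataset <- function(dataset, path, regions = 3,
                                  center_mode = "region") {
  cols <- feature_columns(dataset)
  readr::write_csv(dataset[c("label", "path", cols)], path)
  jsonlite::write_json(
    list(regions = regions, center_mode = center_mode,
         vector_length = length(cols), moment_order = moment_order()),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a feature dataset written by [write_feature_dataset()]
#'
#' Validates that every record carries the same vector length and, when the
#' JSON sidecar is present, that it matches the recorded convention.
#'
#' @param path CSV path.
#' @return A feature tibble with attributes `regions` and `center_mode`
#'   when the sidecar is available.
#' @export
read_feature_dataset <- function(path) {
  ds <- readr::read_csv(path, show_col_types = FALSE)
  cols <- feature_columns(ds)
  if (any(!vapply(ds[cols], is.numeric, logical(1)))) {
    stop("non-numeric feature columns in ", path, call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$vector_length) && meta$vector_length != length(cols)) {
      stop("feature dataset ", path, " has ", length(cols),
           " feature columns but its header declares ", meta$vector_length,
           call. = FALSE)
    }
    attr(ds, "regions") <- meta$regions
    attr(ds, "center_mode") <- meta$center_mode
  }
  ds
}
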