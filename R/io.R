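# Readers, writers and run manifests tying the stages into a reproducible
# pipeline: PNG/TIFF rasters in, PNG/CSV/JSON artifacts out. JSON artifacts
# keep full precision; only the report CSV applies the printed-table
# rounding.

#' Read a lesion image
#'
#' Reads a PNG or TIFF raster and rescales intensities to `[0, 255]`. JPEG is
#' not supported.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix (grayscale file) or H x W x C array.
#' @export
read_lesion_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) {
    stop("unsupported image format \".", ext, "\" (PNG or TIFF expected)",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("input image not found: ", path, call. = FALSE)
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path)
  )
  img * 255
}

#' Write a lesion image (with optional ground-truth sidecar)
#'
#' Writes an 8-bit grayscale PNG; when the image carries generator ground
#' truth (a [generate_lesion_image()] result), a self-describing JSON sidecar
#' with the analytic truth record is written next to it.
#'
#' @param image numeric matrix in `[0, 255]`, or a `lesion_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_lesion_image <- function(image, path) {
  truth <- NULL
  if (inherits(image, "lesion_image")) {
    truth <- image$truth
    image <- image$image
  }
  png::writePNG(image / 255, path)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(tools::file_path_sans_ext(path),
                                       "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

response_table_columns <- c("reader_id", "image_id", "truth",
                            "decision_without", "decision_with")

#' Validate a paired response table
#'
#' Checks the paired-design invariants: required columns, labels in
#' `{melanoma, nevus}`, unique (reader, image) pairs, both decisions present
#' for every record, and at least one melanoma and one nevus per reader.
#'
#' @param table data frame of paired reader responses.
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_response_table <- function(table) {
  missing_cols <- setdiff(response_table_columns, names(table))
  if (length(missing_cols)) {
    stop("malformed response table: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  labels <- c("melanoma", "nevus")
  for (col in c("truth", "decision_without", "decision_with")) {
    bad <- setdiff(unique(table[[col]]), labels)
    if (length(bad)) {
      stop("malformed response table: unknown label(s) in ", col, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(is.na(table[[col]]))) {
      stop("malformed response table: missing values in ", col, call. = FALSE)
    }
  }
  if (anyDuplicated(table[c("reader_id", "image_id")])) {
    stop("malformed response table: duplicated (reader_id, image_id) pair",
         call. = FALSE)
  }
  per <- table(table$reader_id, factor(table$truth, levels = labels))
  if (any(per == 0)) {
    stop("malformed response table: every reader needs at least one melanoma ",
         "and one nevus", call. = FALSE)
  }
  invisible(table)
}

#' Read a paired response table from CSV
#'
#' @param path CSV path (UTF-8, header row) with columns `reader_id`,
#'   `image_id`, `truth`, `decision_without`, `decision_with`.
#' @return validated tibble.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("response table not found: ", path,
                               call. = FALSE)
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_response_table(tab)
  tab
}

#' Write a paired response table to CSV
#'
#' @param table validated response table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  validate_response_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a clock-sweep result as JSON
#'
#' Full-precision machine artifact: delta, mean brightness, the statistic and
#' the three hand angles (radians, clockwise from 12 o'clock), plus the
#' angular profile.
#'
#' @param result a [sweep_statistic()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(result, path) {
  stopifnot(inherits(result, "clock_sweep"))
  payload <- list(
    delta = result$delta,
    mean_brightness = result$mean_brightness,
    statistic = result$statistic,
    darkest_angle = result$darkest_angle,
    brightest_angle = result$brightest_angle,
    max_variation_angle = result$max_variation_angle,
    profile = list(angles = result$profile$angles,
                   values = result$profile$values)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run: the configuration
#' (including the seed), package and R versions, and MD5 checksums of the
#' input files. Deliberately timestamp-free so reruns are byte-identical.
#'
#' @param path output JSON path.
#' @param config named list of configuration values (should include `seed`).
#' @param inputs character vector of input file paths (checksummed).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), inputs = character()) {
  checksums <- tools::md5sum(inputs)
  names(checksums) <- basename(inputs)
  manifest <- list(
    config = config,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("clocksweep")),
    inputs = as.list(checksums)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
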