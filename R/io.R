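# CSV and TIFF I/O with fixed column schemas. CSV dialect: UTF-8,
# comma-separated, header row, "." decimal.

schema_trajectory <- c("time_s", "angle_rad", "stim_direction", "stim_speed",
                       "spatial_frequency", "fish_id", "group", "trial_id")
schema_trace <- c("time_ms", "voltage_uv", "onset_ms", "intensity",
                  "eye_id", "fish_id", "group", "condition")
schema_ct <- c("sample_id", "group", "gene", "replicate", "ct")
schema_landmarks <- c("cornea_apex", "anterior_lens", "posterior_lens", "rpe")

#' Read or write pipeline tables
#'
#' Thin schema-checked wrappers over [readr::read_csv()] /
#' [readr::write_csv()] for the pipeline's table kinds. Writers emit
#' exactly the columns present; readers verify the required schema and
#' fail loudly on missing columns.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @param kind One of `"trajectory"`, `"trace"`, `"ct"`, `"landmarks"`, or
#'   `"any"` (no schema check).
#' @return `read_zfeye_csv()` returns a tibble; `write_zfeye_csv()` returns
#'   `path` invisibly.
#' @export
read_zfeye_csv <- function(path, kind = c("any", "trajectory", "trace", "ct",
                                          "landmarks")) {
  kind <- match.arg(kind)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  schema <- switch(kind,
    any = NULL, trajectory = schema_trajectory, trace = schema_trace,
    ct = schema_ct, landmarks = schema_landmarks
  )
  if (!is.null(schema)) assert_columns(out, schema, sprintf("'%s'", path))
  out
}

#' @rdname read_zfeye_csv
#' @export
write_zfeye_csv <- function(x, path, kind = c("any", "trajectory", "trace",
                                              "ct", "landmarks")) {
  kind <- match.arg(kind)
  schema <- switch(kind,
    any = NULL, trajectory = schema_trajectory, trace = schema_trace,
    ct = schema_ct, landmarks = schema_landmarks
  )
  if (!is.null(schema)) assert_columns(x, schema, "`x`")
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read or write a grayscale image as TIFF
#'
#' Images are plain numeric matrices inside the package; on disk they are
#' single-channel TIFFs. Intensities are rescaled to `[0, 1]` on write
#' (TIFF stores normalized grayscale); the scale used is returned so
#' calibrated intensities can be recovered.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @param bits_per_sample 8 or 16.
#' @return `write_zfeye_tiff()` invisibly returns the scaling factor
#'   applied; `read_zfeye_tiff()` returns a matrix in `[0, 1]`.
#' @export
write_zfeye_tiff <- function(image, path, bits_per_sample = 16) {
  if (!is.matrix(image)) {
    abort("`image` must be a matrix", class = "zfeye_invalid_input")
  }
  lo <- min(image); hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = bits_per_sample)
  invisible(c(offset = lo, scale = if (hi > lo) hi - lo else 1))
}

#' @rdname write_zfeye_tiff
#' @export
read_zfeye_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
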