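# Inner-retinal layer intensity profiles: extraction from straightened
# sections, IPL-thickness renormalization, max-normalization, per-layer
# summed intensity.

new_layer_profile <- function(intensity, ipl_bounds = NULL,
                              roi_height_px = NA_integer_,
                              normalized = FALSE, meta = list()) {
  structure(
    tibble::tibble(position_px = seq_along(intensity),
                   intensity = as.numeric(intensity)),
    ipl_bounds = ipl_bounds,
    roi_height_px = roi_height_px,
    normalized = normalized,
    meta = meta,
    class = c("layer_profile", class(tibble::tibble()))
  )
}

#' @export
print.layer_profile <- function(x, ...) {
  b <- attr(x, "ipl_bounds")
  cat(sprintf(
    "Layer intensity profile: %d px%s%s\n",
    nrow(x),
    if (!is.null(b)) sprintf(", IPL %d-%d px", b[1], b[2]) else "",
    if (isTRUE(attr(x, "normalized"))) ", max-normalized" else ""
  ))
  NextMethod()
}

#' Extract an intensity profile from a straightened section
#'
#' Columnwise mean intensity over a vertically centered band of
#' `roi_height_px` rows — the ROI-box "plot profile" of a straightened
#' inner-retina image with the amacrine cell layer on the left and the
#' ganglion cell layer on the right.
#'
#' @param image Grayscale matrix (rows x columns).
#' @param roi_height_px ROI band height in rows (default 150).
#' @param ipl_bounds Optional integer pair: first and last IPL column
#'   (1-based, inclusive), carried on the profile for IPL renormalization.
#' @return A `layer_profile`: a tibble (`position_px`, `intensity`) with
#'   IPL bounds, ROI height and normalization state in attributes.
#' @export
extract_profile <- function(image, roi_height_px = 150, ipl_bounds = NULL) {
  if (!is.matrix(image) || ncol(image) < 2) {
    abort("`image` must be a matrix at least 2 px wide",
          class = "zfeye_invalid_input")
  }
  if (nrow(image) < roi_height_px) {
    abort("image is shorter than the requested ROI height",
          class = "zfeye_invalid_input")
  }
  top <- floor((nrow(image) - roi_height_px) / 2)
  rows <- seq(top + 1, top + roi_height_px)
  new_layer_profile(
    colMeans(image[rows, , drop = FALSE]),
    ipl_bounds = if (!is.null(ipl_bounds)) as.integer(ipl_bounds),
    roi_height_px = as.integer(roi_height_px)
  )
}

#' Rescale a profile so its IPL matches the control-group IPL thickness
#'
#' Stretches (or shrinks) the whole profile along the pixel axis by
#' `control_mean_ipl_px / ipl_width` with linear interpolation, emulating
#' the image-width resize used to normalize IPL thickness to the control
#' group's average before layer windows are applied. IPL bounds are updated
#' to the new scale. Resampling happens before max-normalization in this
#' pipeline (the order is recorded in the profile metadata).
#'
#' @param profile A `layer_profile` with known IPL bounds.
#' @param control_mean_ipl_px Target IPL thickness, px (>= 1).
#' @return A rescaled `layer_profile`.
#' @export
resample_to_control_ipl <- function(profile, control_mean_ipl_px) {
  b <- attr(profile, "ipl_bounds")
  if (is.null(b)) {
    abort("profile has no IPL bounds; cannot renormalize IPL thickness",
          class = "zfeye_invalid_input")
  }
  ipl_width <- b[2] - b[1] + 1
  if (ipl_width <= 0) {
    abort("zero IPL width", class = "zfeye_invalid_input")
  }
  if (control_mean_ipl_px < 1) {
    abort("`control_mean_ipl_px` must be >= 1", class = "zfeye_invalid_input")
  }
  factor <- control_mean_ipl_px / ipl_width
  n_old <- nrow(profile)
  n_new <- max(2L, round(n_old * factor))
  # positions of the stretched profile: old pixel x sits at 1 + (x-1)*factor
  x_stretched <- 1 + (seq_len(n_old) - 1) * factor
  y_new <- approx(x_stretched, profile$intensity, xout = seq_len(n_new),
                  rule = 2)$y
  new_layer_profile(
    y_new,
    ipl_bounds = as.integer(round(1 + (b - 1) * factor)),
    roi_height_px = attr(profile, "roi_height_px"),
    normalized = isTRUE(attr(profile, "normalized")),
    meta = c(attr(profile, "meta"),
             list(ipl_resample_factor = factor,
                  order = "resample-then-normalize"))
  )
}

#' Normalize a profile to its highest value
#'
#' Divides every intensity by the profile maximum so the brightest pixel
#' equals 1 exactly. Idempotent; an all-zero profile is an error rather
#' than a silent NaN.
#'
#' @param profile A `layer_profile`.
#' @return The normalized `layer_profile`.
#' @export
normalize_profile <- function(profile) {
  m <- max(profile$intensity)
  if (m <= 0) {
    abort("profile maximum is not positive; cannot normalize",
          class = "zfeye_degenerate_profile")
  }
  out <- new_layer_profile(
    profile$intensity / m,
    ipl_bounds = attr(profile, "ipl_bounds"),
    roi_height_px = attr(profile, "roi_height_px"),
    normalized = TRUE,
    meta = attr(profile, "meta")
  )
  out
}

layer_windows <- function(scheme, n, windows = NULL) {
  if (scheme == "custom") {
    if (is.null(windows)) {
      abort("custom scheme needs explicit `windows`",
            class = "zfeye_invalid_input")
    }
    return(windows)
  }
  w <- switch(scheme,
    "2day" = list(ACL = c(1L, 90L), IPL = c(91L, 300L), GCL = c(301L, 390L)),
    "4week" = list(ACL = c(1L, 90L), IPL = c(91L, 330L), GCL = c(331L, 455L))
  )
  expected <- w$GCL[2]
  if (n != expected) {
    abort(sprintf(
      "profile length %d does not match the %s scheme (expects %d px)",
      n, scheme, expected
    ), class = "zfeye_invalid_input")
  }
  w
}

#' Per-layer summed normalized intensity
#'
#' Sums the max-normalized profile over the inclusive 1-based pixel
#' windows of each inner-retinal layer. The `"2day"` scheme uses ACL
#' 1-90, IPL 91-300, GCL 301-390 (a 390-px ROI); the `"4week"` scheme uses
#' ACL 1-90, IPL 91-330, GCL 331-455 (455 px). The windows partition the
#' profile: the three sums always add up to the total summed intensity.
#'
#' @param profile A normalized `layer_profile` (see [normalize_profile()]).
#' @param scheme `"2day"`, `"4week"` or `"custom"`.
#' @param windows For `scheme = "custom"`: named list of inclusive 1-based
#'   `(start, end)` pairs partitioning the profile.
#' @return One-row tibble: `acl_sum`, `ipl_sum`, `gcl_sum` (or one column
#'   per custom window), `total`, `scheme`.
#' @export
layer_sums <- function(profile, scheme = c("2day", "4week", "custom"),
                       windows = NULL) {
  scheme <- match.arg(scheme)
  if (!isTRUE(attr(profile, "normalized"))) {
    abort("profile must be max-normalized before summing (see normalize_profile())",
          class = "zfeye_invalid_input")
  }
  n <- nrow(profile)
  w <- layer_windows(scheme, n, windows)
  covered <- sort(as.integer(unlist(lapply(w, function(b) seq(b[1], b[2])))))
  if (!identical(covered, seq_len(n))) {
    abort("windows must partition the profile exactly",
          class = "zfeye_invalid_input")
  }
  sums <- vapply(w, function(b) sum(profile$intensity[b[1]:b[2]]),
                 numeric(1))
  names(sums) <- paste0(tolower(names(w)), "_sum")
  dplyr::bind_cols(
    tibble::as_tibble(as.list(sums)),
    tibble::tibble(total = sum(profile$intensity), scheme = scheme)
  )
}
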