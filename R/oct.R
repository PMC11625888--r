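# Ocular biometry from OCT axial landmarks and Matthiessen's ratio
# (retina-to-lens radius), plus landmark detection on synthetic B-scans.

#' Ocular biometry from axial OCT landmarks
#'
#' From the axial positions (micrometers along the central optical axis)
#' of the corneal apex, the anterior and posterior lens surfaces and the
#' RPE:
#' axial length = RPE - cornea apex; lens radius = half the anterior-to-
#' posterior lens distance; retinal radius = axial length - lens radius
#' (the lens-center-to-RPE distance under the fish-eye assumption that the
#' cornea sits against the lens); R/L ratio = retinal radius / lens radius
#' (Matthiessen's ratio, the standard relative-refraction proxy in aquatic
#' eyes).
#'
#' @param landmarks Tibble with numeric columns `cornea_apex`,
#'   `anterior_lens`, `posterior_lens`, `rpe` (micrometers) and any id
#'   columns (`eye_id`, `fish_id`, `group`, ...), one row per eye.
#' @return The input with `axial_length_um`, `lens_radius_um`,
#'   `retinal_radius_um` and `rl_ratio` columns added.
#' @examples
#' compute_biometry(tibble::tibble(
#'   cornea_apex = 0, anterior_lens = 50, posterior_lens = 550, rpe = 900
#' ))
#' @export
compute_biometry <- function(landmarks) {
  assert_columns(landmarks,
                 c("cornea_apex", "anterior_lens", "posterior_lens", "rpe"),
                 "`landmarks`")
  with(landmarks, {
    if (any(!(cornea_apex < anterior_lens & anterior_lens <= posterior_lens &
              posterior_lens < rpe))) {
      abort("landmarks must be ordered cornea < anterior lens <= posterior lens < RPE",
            class = "zfeye_invalid_input")
    }
  })
  out <- landmarks |>
    dplyr::mutate(
      axial_length_um = .data$rpe - .data$cornea_apex,
      lens_radius_um = (.data$posterior_lens - .data$anterior_lens) / 2,
      retinal_radius_um = .data$axial_length_um - .data$lens_radius_um
    )
  if (any(out$lens_radius_um == 0)) {
    abort("zero lens radius: R/L ratio undefined (degenerate lens)",
          class = "zfeye_degenerate_lens")
  }
  dplyr::mutate(out, rl_ratio = .data$retinal_radius_um / .data$lens_radius_um)
}

# Peak prominence: height above the higher of the two lowest valleys
# separating the peak from higher terrain (standard topographic definition).
peak_prominence <- function(profile, peaks) {
  vapply(peaks, function(p) {
    h <- profile[p]
    left <- profile[seq_len(p - 1)]
    right <- profile[seq(p + 1, length(profile))]
    higher_l <- which(left >= h)
    higher_r <- which(right >= h)
    base_l <- if (length(higher_l)) {
      min(left[seq(max(higher_l), p - 1)])
    } else {
      min(left)
    }
    base_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r))])
    } else {
      min(right)
    }
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Detect axial landmarks on a B-scan image
#'
#' Averages the image over a central band of columns, locates local maxima
#' of the resulting axial intensity profile, ranks them by topographic
#' prominence, keeps the four strongest and re-sorts them by depth: cornea
#' apex, anterior lens, posterior lens, RPE. Each landmark is refined to
#' sub-pixel precision by a parabolic fit through the peak sample and its
#' two neighbours. Output is in pixel rows; calibrated biometry needs an
#' explicit pixels-per-micrometer conversion.
#'
#' @param image Grayscale matrix (rows = depth).
#' @param band_frac Fraction of central columns averaged (default 0.5).
#' @param prominence_min Minimum prominence for a credible landmark, as a
#'   fraction of the profile's dynamic range (default 0.2).
#' @return Tibble with columns `landmark`
#'   (`cornea_apex`/`anterior_lens`/`posterior_lens`/`rpe`), `row_px`
#'   (sub-pixel), `prominence`.
#' @export
detect_axis_landmarks <- function(image, band_frac = 0.5,
                                  prominence_min = 0.2) {
  if (!is.matrix(image) || length(image) == 0) {
    abort("`image` must be a non-empty matrix", class = "zfeye_invalid_input")
  }
  nc <- ncol(image)
  band <- seq(max(1, floor(nc * (1 - band_frac) / 2) + 1),
              min(nc, ceiling(nc * (1 + band_frac) / 2)))
  profile <- rowMeans(image[, band, drop = FALSE])
  rng <- diff(range(profile))
  if (rng == 0) {
    abort("flat intensity profile: no landmarks found",
          class = "zfeye_landmarks_not_found")
  }
  pk <- pracma::findpeaks(profile)
  if (is.null(pk)) {
    abort("no peaks in the axial profile", class = "zfeye_landmarks_not_found")
  }
  rows <- pk[, 2]
  prom <- peak_prominence(profile, rows)
  keep <- prom >= prominence_min * rng
  if (sum(keep) < 4) {
    abort("fewer than 4 sufficiently prominent peaks: landmarks not found",
          class = "zfeye_landmarks_not_found")
  }
  rows <- rows[keep]
  prom <- prom[keep]
  top <- order(prom, decreasing = TRUE)[1:4]
  ord <- order(rows[top])
  sel <- top[ord]

  refine <- vapply(rows[sel], function(r) {
    if (r <= 1 || r >= length(profile)) return(as.numeric(r))
    y1 <- profile[r - 1]; y2 <- profile[r]; y3 <- profile[r + 1]
    den <- y1 - 2 * y2 + y3
    if (den == 0) return(as.numeric(r))
    r - 0.5 * (y3 - y1) / den
  }, numeric(1))

  tibble::tibble(
    landmark = c("cornea_apex", "anterior_lens", "posterior_lens", "rpe"),
    row_px = refine,
    prominence = prom[sel]
  )
}

#' Relative refraction shift between groups of R/L ratios
#'
#' Mean difference in Matthiessen's ratio (case minus control). A positive
#' shift means a relatively longer eye for its lens — relative axial
#' myopia; a negative shift is a relative hyperopic shift; differences
#' within `tolerance` are called emmetropic. Descriptive only: no
#' inferential statistics.
#'
#' @param case_ratios,control_ratios Numeric vectors of R/L ratios.
#' @param tolerance Half-width of the emmetropic band (default 1e-6).
#' @return One-row tibble: `mean_case`, `mean_control`, `shift`, `label`.
#' @export
relative_refraction <- function(case_ratios, control_ratios,
                                tolerance = 1e-6) {
  if (length(case_ratios) == 0 || length(control_ratios) == 0) {
    abort("both groups need at least one R/L ratio",
          class = "zfeye_insufficient_data")
  }
  shift <- mean(case_ratios) - mean(control_ratios)
  label <- if (abs(shift) <= tolerance) {
    "emmetropic"
  } else if (shift > 0) {
    "relative myopia"
  } else {
    "relative hyperopia"
  }
  tibble::tibble(
    mean_case = mean(case_ratios),
    mean_control = mean(control_ratios),
    shift = shift,
    label = label
  )
}
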