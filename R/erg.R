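# Electroretinogram feature extraction: a-wave (corneal-negative trough)
# and b-wave (subsequent positive peak) amplitudes and implicit times, plus
# group mean +/- SEM traces and tidy intensity-response tables.

erg_id_cols <- c("eye_id", "fish_id", "group", "condition", "intensity")

#' Extract a-/b-wave features from ERG traces
#'
#' Per trace: the baseline is the mean voltage over `baseline_window` ms
#' immediately before stimulus onset; the a-trough is the minimum inside
#' `a_window` (ms post-onset; earliest sample on ties); the b-peak is the
#' maximum strictly after the a-trough up to `b_window_end` ms post-onset
#' (earliest on ties). Amplitudes follow the clinical conventions:
#' a-amplitude from baseline down to the trough, b-amplitude from the
#' trough up to the peak. Implicit times are measured from stimulus onset
#' to the trough/peak. A trough that does not descend below
#' `baseline - detection_floor` is flagged `a-wave-absent` (amplitude 0,
#' time `NA`) and the b-peak is then measured from baseline over the whole
#' post-onset search window; a trace with neither feature is flagged
#' `no-response`.
#'
#' @param traces Tibble of one or more traces with columns `time_ms`,
#'   `voltage_uv`, `onset_ms` plus any of the id columns `eye_id`,
#'   `fish_id`, `group`, `condition`, `intensity`.
#' @param a_window Search window for the a-trough, ms post-onset
#'   (default `c(3, 100)`).
#' @param b_window_end End of the b-peak search, ms post-onset (default
#'   300).
#' @param baseline_window Pre-onset baseline duration, ms (default 50).
#' @param detection_floor Minimum excursion (uV) below baseline for a real
#'   a-wave (and above the reference for a b-wave); default 3x the SD of
#'   the baseline-window samples, which separates "no wave" from noise
#'   minima on flat traces.
#' @param smooth_width Optional centered moving-average width (samples,
#'   odd) applied before extremum detection; 0 (default) disables
#'   filtering. Recorded in the output.
#' @return Tibble, one row per trace: ids, `baseline_uv`, `a_amplitude_uv`,
#'   `b_amplitude_uv`, `a_implicit_time_ms`, `b_implicit_time_ms`, `flags`
#'   (comma-separated quality labels, `"ok"` if none), `smooth_width`.
#' @export
erg_features <- function(traces,
                         a_window = c(3, 100),
                         b_window_end = 300,
                         baseline_window = 50,
                         detection_floor = NULL,
                         smooth_width = 0) {
  assert_columns(traces, c("time_ms", "voltage_uv", "onset_ms"), "`traces`")
  if (a_window[1] < 0 || a_window[2] <= a_window[1]) {
    abort("`a_window` must be an increasing window at or after onset",
          class = "zfeye_invalid_window")
  }
  ids <- intersect(erg_id_cols, names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_modify(~ erg_features_one(.x, a_window, b_window_end,
                                           baseline_window, detection_floor,
                                           smooth_width)) |>
    dplyr::ungroup()
}

erg_features_one <- function(trace, a_window, b_window_end, baseline_window,
                             detection_floor, smooth_width) {
  t <- trace$time_ms
  v <- trace$voltage_uv
  onset <- trace$onset_ms[1]
  if (smooth_width > 1) {
    w <- as.integer(smooth_width)
    if (w %% 2 == 0) w <- w + 1L
    v <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- as.numeric(v)
    # keep edges unsmoothed rather than NA
    v[is.na(v)] <- trace$voltage_uv[is.na(v)]
  }
  base_idx <- which(t >= onset - baseline_window & t < onset)
  if (length(base_idx) == 0) {
    abort("no samples in the baseline window before stimulus onset",
          class = "zfeye_invalid_window")
  }
  baseline <- mean(v[base_idx])
  floor_uv <- if (is.null(detection_floor)) {
    3 * sd(v[base_idx])
  } else {
    detection_floor
  }
  if (!is.finite(floor_uv)) floor_uv <- 0

  a_idx <- which(t >= onset + a_window[1] & t <= onset + a_window[2])
  if (length(a_idx) == 0) {
    abort("a-wave search window contains no samples",
          class = "zfeye_invalid_window")
  }
  i_trough <- a_idx[which.min(v[a_idx])]
  a_present <- (baseline - v[i_trough]) > floor_uv
  flags <- character()

  if (a_present) {
    a_amp <- baseline - v[i_trough]
    a_time <- t[i_trough] - onset
    b_idx <- which(t > t[i_trough] & t <= onset + b_window_end)
    b_ref <- v[i_trough]
  } else {
    a_amp <- 0
    a_time <- NA_real_
    flags <- c(flags, "a-wave-absent")
    b_idx <- which(t >= onset + a_window[1] & t <= onset + b_window_end)
    b_ref <- baseline
  }
  if (length(b_idx) == 0) {
    abort("b-wave search window contains no samples",
          class = "zfeye_invalid_window")
  }
  i_peak <- b_idx[which.max(v[b_idx])]
  b_present <- (v[i_peak] - b_ref) > floor_uv
  if (b_present) {
    b_amp <- v[i_peak] - b_ref
    b_time <- t[i_peak] - onset
  } else {
    b_amp <- 0
    b_time <- NA_real_
  }
  if (!a_present && !b_present) flags <- c(flags, "no-response")

  tibble::tibble(
    baseline_uv = baseline,
    a_amplitude_uv = a_amp,
    b_amplitude_uv = b_amp,
    a_implicit_time_ms = a_time,
    b_implicit_time_ms = b_time,
    flags = if (length(flags)) paste(flags, collapse = ",") else "ok",
    smooth_width = smooth_width
  )
}

#' Group-average ERG trace with pointwise SEM
#'
#' Averages traces pointwise within groups defined by `by` (default:
#' whichever of `group`, `condition`, `intensity` are present). All traces
#' in a cell must share the same time grid and onset; there is no
#' resampling. SEM is `sd / sqrt(n)` (sample SD, n - 1 denominator); a
#' single-trace cell gets `NA` SEM and a flag rather than 0.
#'
#' @param traces Tibble of traces (as in [erg_features()]).
#' @param by Character vector of grouping columns.
#' @return Tibble: grouping columns, `time_ms`, `mean_uv`, `sem_uv`,
#'   `n_traces`, `flags`.
#' @export
erg_group_average <- function(traces, by = NULL) {
  assert_columns(traces, c("time_ms", "voltage_uv", "onset_ms"), "`traces`")
  if (is.null(by)) by <- intersect(c("group", "condition", "intensity"),
                                   names(traces))
  trace_ids <- intersect(c("eye_id", "fish_id"), names(traces))
  if (length(trace_ids) == 0) {
    abort("traces need an `eye_id` or `fish_id` column to be distinguished",
          class = "zfeye_invalid_input")
  }
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      wide <- d |>
        dplyr::group_by(dplyr::across(dplyr::all_of(trace_ids)))
      grids <- dplyr::group_split(wide)
      ref <- grids[[1]]$time_ms
      same <- vapply(grids, function(g) {
        length(g$time_ms) == length(ref) && all(g$time_ms == ref) &&
          all(g$onset_ms == grids[[1]]$onset_ms[1])
      }, logical(1))
      if (!all(same)) {
        abort("traces in a group must share the same time grid and onset (no resampling)",
              class = "zfeye_invalid_input")
      }
      m <- vapply(grids, function(g) g$voltage_uv, numeric(length(ref)))
      n <- length(grids)
      tibble::tibble(
        time_ms = ref,
        mean_uv = rowMeans(m),
        sem_uv = if (n > 1) apply(m, 1, sd) / sqrt(n) else NA_real_,
        n_traces = n,
        flags = if (n > 1) "ok" else "single-trace"
      )
    }) |>
    dplyr::ungroup()
}

#' Tidy intensity-response table of ERG features
#'
#' Reshapes extracted features into one row per eye x intensity x feature,
#' ready for external factorial statistics. When an eye has repeated
#' flashes at an intensity (e.g. three repeats at low intensities), the
#' repeats are averaged per eye before tabulation and the repeat count is
#' recorded. Intensity values are carried through exactly as provided.
#'
#' @param features Tibble from [erg_features()]; must contain `eye_id` and
#'   `intensity`. An optional `repeat_id`/`trial_id` column distinguishes
#'   repeats; without one, duplicated (eye, intensity) rows are an error.
#' @return Tibble with id columns, `intensity`, `feature`, `value`,
#'   `n_repeats`.
#' @export
intensity_response_table <- function(features) {
  assert_columns(features, c("eye_id", "intensity"), "`features`")
  feat_cols <- c("a_amplitude_uv", "b_amplitude_uv",
                 "a_implicit_time_ms", "b_implicit_time_ms")
  assert_columns(features, feat_cols, "`features`")
  rep_col <- intersect(c("repeat_id", "trial_id"), names(features))
  keys <- c("eye_id", "intensity")
  if (length(rep_col) == 0 &&
      anyDuplicated(features[keys]) > 0) {
    abort("duplicate (eye_id, intensity) rows without a repeat column",
          class = "zfeye_invalid_input")
  }
  if (length(rep_col) > 0 &&
      anyDuplicated(features[c(keys, rep_col[1])]) > 0) {
    abort("duplicate (eye_id, intensity, repeat) keys",
          class = "zfeye_invalid_input")
  }
  carry <- intersect(c("fish_id", "group", "condition"), names(features))
  features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(carry, keys)))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(feat_cols), ~ mean(.x)),
      n_repeats = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(feat_cols),
                        names_to = "feature", values_to = "value")
}
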