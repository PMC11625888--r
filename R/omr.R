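# Optomotor index (OMI): net signed angular displacement per trial, trial
# averaging, and normalization to a reference group x frequency.

#' Compute the optomotor index for each trial
#'
#' The OMI of a trial is the net angular displacement of the fish over the
#' trial, signed so that movement in the direction of the rotating grating
#' is positive: the tracked wrapped angle is first unwrapped (adjacent
#' jumps larger than pi are corrected by +/- 2 pi, valid while true
#' per-sample rotation stays below pi), then
#' `OMI = (theta_end - theta_start) * stim_direction`. Units are radians;
#' net displacement (not path length) is used so that the statistic is
#' antisymmetric in stimulus direction, which the clockwise/counter-
#' clockwise trial averaging relies on.
#'
#' @param trajectories Tibble of tracked samples with columns `time_s`,
#'   `angle_rad`, `stim_direction`, `spatial_frequency`, `fish_id`,
#'   `group`, `trial_id` (one or many trials; trials are identified by the
#'   id columns).
#' @return A tibble with one row per trial: `fish_id`, `group`,
#'   `trial_id`, `spatial_frequency`, `stim_direction`, `omi` (rad),
#'   `n_samples`.
#' @examples
#' sim_trajectory(0.6, seed = 2) |> compute_omi()
#' @export
compute_omi <- function(trajectories) {
  assert_columns(trajectories,
                 c("time_s", "angle_rad", "stim_direction",
                   "spatial_frequency", "fish_id", "group", "trial_id"),
                 "`trajectories`")
  trajectories |>
    dplyr::group_by(.data$fish_id, .data$group, .data$trial_id,
                    .data$spatial_frequency, .data$stim_direction) |>
    dplyr::summarise(
      omi = {
        if (dplyr::n() < 2) {
          abort("a trial needs at least 2 samples to compute an OMI",
                class = "zfeye_insufficient_data")
        }
        if (any(diff(.data$time_s) <= 0)) {
          abort("trial time stamps must be strictly increasing",
                class = "zfeye_invalid_input")
        }
        theta <- unwrap_angle(.data$angle_rad)
        (theta[length(theta)] - theta[1]) * .data$stim_direction[1]
      },
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}

#' Average trial OMIs per fish and spatial frequency
#'
#' The per-condition OMI of a fish is the arithmetic mean of its signed
#' trial OMIs (conventionally four trials: two clockwise, two
#' counter-clockwise). Partial conditions are averaged over however many
#' trials are present, with the contributing count recorded — no
#' imputation.
#'
#' @param trial_results Tibble from [compute_omi()] (or per-trial OMI rows
#'   from [sim_omr_cohort()]).
#' @return Tibble with one row per fish x frequency: `fish_id`, `group`,
#'   `spatial_frequency`, `omi_mean`, `n_trials`.
#' @export
average_trials <- function(trial_results) {
  assert_columns(trial_results,
                 c("fish_id", "group", "spatial_frequency", "omi"),
                 "`trial_results`")
  if (nrow(trial_results) == 0) {
    abort("no trial results to average", class = "zfeye_insufficient_data")
  }
  trial_results |>
    dplyr::group_by(.data$fish_id, .data$group, .data$spatial_frequency) |>
    dplyr::summarise(
      omi_mean = mean(.data$omi),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Normalize OMIs to a reference group at a reference frequency
#'
#' Divides every per-fish mean OMI by the reference group's mean OMI at
#' the reference spatial frequency (for larval data the wild-type group at
#' 0.0155 c/deg, for juveniles at 0.0620 c/deg — the condition with the
#' greatest response at that age). After normalization the reference
#' group's mean at the reference frequency is exactly 1.
#'
#' @param tuning_data Tibble from [average_trials()].
#' @param reference_group Group label supplying the normalization constant.
#' @param reference_frequency Spatial frequency (c/deg) of the reference
#'   condition; matched with a small numeric tolerance.
#' @return The input with an `omi_normalized` column added; the reference
#'   used is recorded in the `"normalization"` attribute.
#' @export
normalize_omi <- function(tuning_data, reference_group, reference_frequency) {
  assert_columns(tuning_data,
                 c("fish_id", "group", "spatial_frequency", "omi_mean"),
                 "`tuning_data`")
  ref_rows <- tuning_data |>
    dplyr::filter(.data$group == reference_group,
                  dplyr::near(.data$spatial_frequency, reference_frequency))
  if (nrow(ref_rows) == 0) {
    abort("no rows for the reference group at the reference frequency",
          class = "zfeye_invalid_input")
  }
  ref_mean <- mean(ref_rows$omi_mean)
  if (ref_mean == 0) {
    abort("reference mean OMI is zero; cannot normalize",
          class = "zfeye_degenerate_reference")
  }
  out <- dplyr::mutate(tuning_data, omi_normalized = .data$omi_mean / ref_mean)
  attr(out, "normalization") <- list(
    reference_group = reference_group,
    reference_frequency = reference_frequency,
    reference_mean_omi = ref_mean,
    units = "net signed angular displacement, rad, divided by reference mean"
  )
  out
}
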