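# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments and seed, and attaches the generating ground truth
# (retrievable with ground_truth()) so downstream expected values never have
# to be re-derived from the data themselves.

#' Spatial frequencies of the optomotor test battery
#'
#' The six windmill-grating central spatial frequencies (cycles/degree) used
#' in the optomotor assay.
#'
#' @return Numeric vector of six spatial frequencies in cycles/degree.
#' @export
omr_frequencies <- function() {
  c(0.0078, 0.0155, 0.0310, 0.0620, 0.1240, 0.2480)
}

#' Simulate one tracked optomotor swim trajectory
#'
#' Angular position follows a drift--diffusion model: the fish tracks the
#' rotating grating with gain `tuning_gain`, so
#' d(theta)/dt = tuning_gain * stim_direction * stim_speed, plus white noise
#' in angular velocity (displacement variance therefore grows linearly with
#' time). The reported angle is wrapped to (-pi, pi] as a video tracker
#' would report it; the unwrapped net displacement is stored as ground
#' truth.
#'
#' @param tuning_gain Dimensionless gain in `[0, 1]`-ish range (values
#'   outside are allowed; 1 means locked to the stimulus).
#' @param stim_direction `+1` (clockwise) or `-1` (counter-clockwise).
#' @param stim_speed Grating angular speed, rad/s.
#' @param duration Trial duration, s.
#' @param sample_rate Sampling rate of the tracker, Hz.
#' @param noise_sd Angular-velocity white-noise intensity, rad/sqrt(s).
#' @param seed Integer seed; `NULL` uses (and advances) the global RNG.
#' @param spatial_frequency,fish_id,group,trial_id Metadata carried through.
#' @return A tibble with columns `time_s`, `angle_rad` (wrapped),
#'   `stim_direction`, `stim_speed`, `spatial_frequency`, `fish_id`,
#'   `group`, `trial_id`. Ground truth (list with `net_displacement_rad`,
#'   `tuning_gain`) is attached.
#' @examples
#' traj <- sim_trajectory(tuning_gain = 1, stim_direction = 1, seed = 1)
#' ground_truth(traj)$net_displacement_rad # 15 rad for 0.5 rad/s x 30 s
#' @export
sim_trajectory <- function(tuning_gain,
                           stim_direction = 1L,
                           stim_speed = 0.5,
                           duration = 30,
                           sample_rate = 30,
                           noise_sd = 0,
                           seed = NULL,
                           spatial_frequency = NA_real_,
                           fish_id = "f1",
                           group = "g1",
                           trial_id = "t1") {
  assert_scalar_positive(duration, "duration")
  assert_scalar_positive(sample_rate, "sample_rate")
  assert_scalar_nonneg(noise_sd, "noise_sd")
  if (!stim_direction %in% c(-1, 1)) {
    abort("`stim_direction` must be +1 or -1", class = "zfeye_invalid_spec")
  }
  dt <- 1 / sample_rate
  n_steps <- round(duration * sample_rate)
  increments <- local_seed(seed, {
    tuning_gain * stim_direction * stim_speed * dt +
      rnorm(n_steps, mean = 0, sd = noise_sd * sqrt(dt))
  })
  theta <- c(0, cumsum(increments))
  out <- tibble::tibble(
    time_s = seq(0, by = dt, length.out = n_steps + 1),
    angle_rad = wrap_angle(theta),
    stim_direction = as.integer(stim_direction),
    stim_speed = stim_speed,
    spatial_frequency = spatial_frequency,
    fish_id = fish_id,
    group = group,
    trial_id = trial_id
  )
  attr(out, "ground_truth") <- list(
    net_displacement_rad = theta[length(theta)] - theta[1],
    tuning_gain = tuning_gain
  )
  out
}

#' Simulate an optomotor cohort across spatial frequencies
#'
#' For each fish, frequency and trial, the drift gain is the group's
#' log-Gaussian tuning curve evaluated at that frequency plus independent
#' per-trial Gaussian noise of SD `noise_sd_omi`. Half the trials per
#' condition run clockwise and half counter-clockwise. The ground truth
#' (per-trial gain and exact noise-free-tracking OMI) is attached.
#'
#' @param groups A data frame with columns `group`, `amplitude`,
#'   `peak_frequency` (c/deg) and `bandwidth` (log10-frequency units), one
#'   row per group.
#' @param n_fish_per_group Fish per group (>= 1).
#' @param frequencies Spatial frequencies tested, c/deg (positive,
#'   distinct). Defaults to the six-frequency battery.
#' @param trials_per_condition Trials per fish x frequency (even; split
#'   half clockwise, half counter-clockwise). Default 4.
#' @param noise_sd_omi Per-trial SD of the gain noise (normalized OMI
#'   units).
#' @param stim_speed,duration,sample_rate Stimulus/tracking parameters
#'   passed to [sim_trajectory()].
#' @param traj_noise_sd Angular-velocity noise of the tracked trajectories
#'   (rad/sqrt(s)); 0 keeps trial OMI identical to its ground truth.
#' @param seed Integer seed.
#' @param return `"trajectories"` (default) returns the full tracked
#'   trajectories; `"omi"` returns the per-trial optomotor-index table
#'   directly (identical to running [compute_omi()] on noise-free
#'   trajectories, since a trial's net displacement is
#'   gain * stim_speed * duration exactly when `traj_noise_sd = 0`).
#' @return A tibble of trajectories (long) or per-trial OMI rows, with a
#'   ground-truth tibble attached (one row per trial: true gain, true OMI)
#'   plus the generating curve parameters.
#' @export
sim_omr_cohort <- function(groups,
                           n_fish_per_group = 14,
                           frequencies = omr_frequencies(),
                           trials_per_condition = 4,
                           noise_sd_omi = 0.1,
                           stim_speed = 0.5,
                           duration = 30,
                           sample_rate = 30,
                           traj_noise_sd = 0,
                           seed = 1,
                           return = c("trajectories", "omi")) {
  return <- match.arg(return)
  groups <- tibble::as_tibble(groups)
  assert_columns(groups, c("group", "amplitude", "peak_frequency", "bandwidth"),
                 "`groups`")
  if (length(frequencies) == 0) {
    abort("`frequencies` must be non-empty", class = "zfeye_invalid_spec")
  }
  if (any(frequencies <= 0) || anyDuplicated(frequencies) > 0) {
    abort("`frequencies` must be positive and distinct",
          class = "zfeye_invalid_spec")
  }
  if (n_fish_per_group < 1) {
    abort("`n_fish_per_group` must be >= 1", class = "zfeye_invalid_spec")
  }
  if (any(groups$amplitude < 0) || any(groups$peak_frequency <= 0) ||
      any(groups$bandwidth <= 0)) {
    abort("tuning parameters must satisfy amplitude >= 0, peak > 0, bandwidth > 0",
          class = "zfeye_invalid_spec")
  }
  if (trials_per_condition < 1 || trials_per_condition %% 2 != 0) {
    abort("`trials_per_condition` must be a positive even count",
          class = "zfeye_invalid_spec")
  }

  design <- tidyr::expand_grid(
    group = groups$group,
    fish = seq_len(n_fish_per_group),
    spatial_frequency = frequencies,
    trial = seq_len(trials_per_condition)
  ) |>
    dplyr::left_join(groups, by = "group") |>
    dplyr::mutate(
      fish_id = paste0(.data$group, "_fish", sprintf("%02d", .data$fish)),
      trial_id = paste0("t", .data$trial),
      stim_direction = ifelse(.data$trial <= trials_per_condition / 2, 1L, -1L),
      curve_gain = log_gaussian(.data$spatial_frequency, .data$amplitude,
                                .data$peak_frequency, .data$bandwidth)
    )

  design <- local_seed(seed, {
    dplyr::mutate(design,
      gain = .data$curve_gain + rnorm(dplyr::n(), 0, noise_sd_omi)
    )
  })
  truth <- design |>
    dplyr::mutate(omi_true = .data$gain * stim_speed * duration) |>
    dplyr::select("group", "fish_id", "trial_id", "spatial_frequency",
                  "stim_direction", "curve_gain", "gain", "omi_true")

  out <- if (return == "omi") {
    truth |>
      dplyr::transmute(
        fish_id = .data$fish_id, group = .data$group,
        trial_id = .data$trial_id,
        spatial_frequency = .data$spatial_frequency,
        stim_direction = .data$stim_direction,
        stim_speed = stim_speed,
        omi = .data$gain * stim_speed * duration
      )
  } else {
    # trajectory-level noise seeds are derived from the cohort seed so the
    # whole cohort is reproducible from one integer
    traj_seeds <- local_seed(seed + 1L,
                             sample.int(.Machine$integer.max, nrow(design)))
    purrr::pmap(
      list(design$gain, design$stim_direction, design$spatial_frequency,
           design$fish_id, design$group, design$trial_id, traj_seeds),
      function(g, dir, f, fid, grp, tid, s) {
        sim_trajectory(
          tuning_gain = g, stim_direction = dir, stim_speed = stim_speed,
          duration = duration, sample_rate = sample_rate,
          noise_sd = traj_noise_sd, seed = s, spatial_frequency = f,
          fish_id = fid, group = grp, trial_id = tid
        )
      }
    ) |>
      purrr::list_rbind()
  }
  attr(out, "ground_truth") <- truth
  attr(out, "curve_params") <- groups
  out
}

# Gamma-type unimodal kernel with unit peak at t = peak_ms; 0 for t <= 0.
erg_kernel <- function(t_ms, peak_ms, shape) {
  k <- numeric(length(t_ms))
  pos <- t_ms > 0
  u <- t_ms[pos] / peak_ms
  k[pos] <- u^shape * exp(shape * (1 - u))
  k
}

#' Simulate a flash electroretinogram trace
#'
#' The post-stimulus voltage is a two-component sum
#' `-a_scale * K(t; a_time) + b_scale * K(t; b_time)` of gamma-type kernels
#' `K(t; tp) = (t/tp)^s exp(s (1 - t/tp))`, each normalized to unit peak at
#' its nominal time, plus white noise. Because the corneal-negative and
#' positive components overlap in time, the realized trough/peak of the sum
#' differ slightly from the nominal kernel peak times; the ground truth
#' stored with the trace is therefore computed from a dense (100x
#' oversampled) evaluation of the closed-form sum.
#'
#' @param a_scale,b_scale Component scales, microvolts (>= 0).
#' @param a_time_to_trough,b_time_to_peak Kernel peak times, ms post-flash.
#' @param kernel_shape Dimensionless shape (> 1).
#' @param noise_sd Additive white noise SD, microvolts.
#' @param sample_interval Sampling interval, ms.
#' @param pre_stimulus_ms Baseline time recorded before the flash, ms.
#' @param duration_ms Total trace duration, ms.
#' @param seed Integer seed; `NULL` uses the global RNG.
#' @param intensity Flash intensity label (log cd.s/m^2), carried through.
#' @param eye_id,fish_id,group,condition Metadata carried through.
#' @return Tibble with `time_ms`, `voltage_uv`, `onset_ms`, `intensity` and
#'   id columns; ground truth (trough/peak voltage and latency, a/b
#'   amplitudes per the baseline-to-trough / trough-to-peak definitions) is
#'   attached.
#' @export
sim_erg_trace <- function(a_scale = 100,
                          a_time_to_trough = 20,
                          b_scale = 300,
                          b_time_to_peak = 60,
                          kernel_shape = 4,
                          noise_sd = 0,
                          sample_interval = 1,
                          pre_stimulus_ms = 100,
                          duration_ms = 500,
                          seed = NULL,
                          intensity = NA_real_,
                          eye_id = "e1",
                          fish_id = "f1",
                          group = "g1",
                          condition = "cond1") {
  assert_scalar_nonneg(a_scale, "a_scale")
  assert_scalar_nonneg(b_scale, "b_scale")
  assert_scalar_positive(a_time_to_trough, "a_time_to_trough")
  assert_scalar_positive(b_time_to_peak, "b_time_to_peak")
  assert_scalar_positive(sample_interval, "sample_interval")
  assert_scalar_nonneg(pre_stimulus_ms, "pre_stimulus_ms")
  if (kernel_shape <= 1) {
    abort("`kernel_shape` must exceed 1", class = "zfeye_invalid_spec")
  }
  if (duration_ms <= pre_stimulus_ms) {
    abort("`duration_ms` must exceed `pre_stimulus_ms`",
          class = "zfeye_invalid_spec")
  }
  post_ms <- duration_ms - pre_stimulus_ms
  if ((a_scale > 0 && a_time_to_trough >= post_ms) ||
      (b_scale > 0 && b_time_to_peak >= post_ms)) {
    abort("kernel peak time falls outside the recorded trace",
          class = "zfeye_invalid_spec")
  }

  time_ms <- seq(0, duration_ms, by = sample_interval)
  t_post <- time_ms - pre_stimulus_ms
  signal <- -a_scale * erg_kernel(t_post, a_time_to_trough, kernel_shape) +
    b_scale * erg_kernel(t_post, b_time_to_peak, kernel_shape)
  noise <- local_seed(seed, rnorm(length(time_ms), 0, noise_sd))

  # dense closed-form evaluation for sub-grid ground truth
  t_dense <- seq(0, post_ms, by = sample_interval / 100)
  v_dense <- -a_scale * erg_kernel(t_dense, a_time_to_trough, kernel_shape) +
    b_scale * erg_kernel(t_dense, b_time_to_peak, kernel_shape)
  flat <- a_scale == 0 && b_scale == 0
  i_min <- which.min(v_dense)
  trough_uv <- v_dense[i_min]
  trough_ms <- t_dense[i_min]
  after <- seq_along(t_dense) > i_min
  if (any(after)) {
    i_max <- which(after)[which.max(v_dense[after])]
    peak_uv <- v_dense[i_max]
    peak_ms <- t_dense[i_max]
  } else {
    peak_uv <- NA_real_
    peak_ms <- NA_real_
  }

  out <- tibble::tibble(
    time_ms = time_ms,
    voltage_uv = signal + noise,
    onset_ms = pre_stimulus_ms,
    intensity = intensity,
    eye_id = eye_id,
    fish_id = fish_id,
    group = group,
    condition = condition
  )
  attr(out, "ground_truth") <- list(
    trough_uv = if (flat) NA_real_ else trough_uv,
    trough_ms = if (flat) NA_real_ else trough_ms,
    peak_uv = if (flat) NA_real_ else peak_uv,
    peak_ms = if (flat) NA_real_ else peak_ms,
    a_amplitude = if (flat) 0 else max(0, -trough_uv),
    b_amplitude = if (flat) 0 else max(0, peak_uv - trough_uv),
    a_implicit_time = if (flat) NA_real_ else trough_ms,
    b_implicit_time = if (flat) NA_real_ else peak_ms
  )
  out
}

#' Simulate an axial OCT B-scan of a fish eye
#'
#' Produces a grayscale image (matrix; rows = depth, columns = lateral
#' position) with four bright axial bands at the cornea apex, anterior and
#' posterior lens surfaces and the RPE, on a dark background. Bands have
#' Gaussian axial profiles (default 3 px SD) so the sub-pixel landmark
#' truth is well-defined as the band center. Optional landmark jitter and
#' speckle-like additive noise.
#'
#' @param cornea_pos,anterior_lens_pos,posterior_lens_pos,rpe_pos Landmark
#'   depths along the central axis, micrometers; must be strictly
#'   increasing and `cornea_pos > 0` so the corneal band is inside the
#'   frame.
#' @param px_per_um Axial sampling, pixels per micrometer.
#' @param width_px Image width (columns).
#' @param jitter_sd Landmark position jitter SD, micrometers (the jittered
#'   positions are the ground truth).
#' @param band_sd_px Axial Gaussian SD of each band, px.
#' @param noise_sd Additive noise SD (intensity units; band peak is 1).
#' @param seed Integer seed.
#' @return Image matrix with a ground-truth tibble (landmark, depth_um,
#'   row_px) attached.
#' @export
sim_bscan <- function(cornea_pos = 100,
                      anterior_lens_pos = 150,
                      posterior_lens_pos = 650,
                      rpe_pos = 1000,
                      px_per_um = 0.5,
                      width_px = 64,
                      jitter_sd = 0,
                      band_sd_px = 3,
                      noise_sd = 0,
                      seed = NULL) {
  pos <- c(cornea_apex = cornea_pos, anterior_lens = anterior_lens_pos,
           posterior_lens = posterior_lens_pos, rpe = rpe_pos)
  if (any(diff(pos) <= 0) || cornea_pos <= 0) {
    abort("landmarks must satisfy 0 < cornea < anterior lens < posterior lens < RPE",
          class = "zfeye_invalid_spec")
  }
  assert_scalar_positive(px_per_um, "px_per_um")
  assert_scalar_nonneg(jitter_sd, "jitter_sd")

  res <- local_seed(seed, {
    true_pos <- pos + rnorm(4, 0, jitter_sd)
    if (any(diff(true_pos) <= 0) || true_pos[1] <= 0) {
      abort("jitter produced a non-physical landmark ordering; reduce `jitter_sd`",
            class = "zfeye_invalid_spec")
    }
    rows <- true_pos * px_per_um
    height <- ceiling(max(rows)) + ceiling(4 * band_sd_px)
    depth <- seq_len(height)
    profile <- rowSums(vapply(rows, function(r) {
      exp(-(depth - r)^2 / (2 * band_sd_px^2))
    }, numeric(height)))
    img <- matrix(profile, nrow = height, ncol = width_px) +
      matrix(rnorm(height * width_px, 0, noise_sd), nrow = height)
    list(img = img, true_pos = true_pos, rows = rows)
  })
  truth <- tibble::tibble(
    landmark = names(pos),
    depth_um = unname(res$true_pos),
    row_px = unname(res$rows)
  )
  out <- res$img
  attr(out, "ground_truth") <- truth
  attr(out, "px_per_um") <- px_per_um
  out
}

#' Simulate a table of per-eye OCT axial landmarks
#'
#' Draws `n_eyes` eyes whose landmark depths are the group geometry plus
#' independent Gaussian jitter per landmark (biological variation plus
#' measurement error), keeping the anatomical ordering.
#'
#' @param geometry Data frame with columns `group`, `cornea_pos`,
#'   `anterior_lens_pos`, `posterior_lens_pos`, `rpe_pos` (micrometers).
#' @param n_eyes Eyes per group (both eyes of a fish count as independent
#'   observations).
#' @param jitter_sd Per-landmark jitter SD, micrometers.
#' @param seed Integer seed.
#' @return Tibble with `eye_id`, `group` and the four landmark columns
#'   used by [compute_biometry()]; the jitter-free biometry per group is
#'   attached as ground truth.
#' @export
sim_oct_landmarks <- function(geometry, n_eyes = 40, jitter_sd = 5,
                              seed = 1) {
  geometry <- tibble::as_tibble(geometry)
  assert_columns(geometry, c("group", "cornea_pos", "anterior_lens_pos",
                             "posterior_lens_pos", "rpe_pos"), "`geometry`")
  ok <- with(geometry, cornea_pos < anterior_lens_pos &
               anterior_lens_pos < posterior_lens_pos &
               posterior_lens_pos < rpe_pos)
  if (!all(ok)) {
    abort("geometry must be ordered cornea < anterior lens < posterior lens < RPE",
          class = "zfeye_invalid_spec")
  }
  out <- local_seed(seed, {
    tidyr::expand_grid(geometry, eye = seq_len(n_eyes)) |>
      dplyr::mutate(
        eye_id = paste0(.data$group, "_eye", sprintf("%02d", .data$eye)),
        cornea_apex = .data$cornea_pos + rnorm(dplyr::n(), 0, jitter_sd),
        anterior_lens = .data$anterior_lens_pos + rnorm(dplyr::n(), 0, jitter_sd),
        posterior_lens = .data$posterior_lens_pos + rnorm(dplyr::n(), 0, jitter_sd),
        rpe = .data$rpe_pos + rnorm(dplyr::n(), 0, jitter_sd)
      ) |>
      dplyr::select("eye_id", "group", "cornea_apex", "anterior_lens",
                    "posterior_lens", "rpe")
  })
  truth <- geometry |>
    dplyr::mutate(
      axial_length_um = .data$rpe_pos - .data$cornea_pos,
      lens_radius_um = (.data$posterior_lens_pos - .data$anterior_lens_pos) / 2,
      retinal_radius_um = .data$axial_length_um - .data$lens_radius_um,
      rl_ratio = .data$retinal_radius_um / .data$lens_radius_um
    )
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate a straightened inner-retina section image
#'
#' Produces a grayscale image whose columns run from the amacrine cell
#' layer (ACL, left) through the inner plexiform layer (IPL) to the
#' ganglion cell layer (GCL, right): each layer's columns have the
#' specified mean intensity plus optional Gaussian noise.
#'
#' @param layer_means Length-3 numeric, mean intensity of (ACL, IPL, GCL);
#'   all >= 0.
#' @param layer_widths Length-3 integer widths in pixels (each >= 1). The
#'   default (90, 210, 90) gives the 390-px two-day ROI; (90, 240, 125)
#'   gives the 455-px four-week ROI.
#' @param roi_height_px Image height, px.
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @return Image matrix (`roi_height_px` x `sum(layer_widths)`) with a
#'   ground-truth tibble (layer, start/end columns, mean) attached.
#' @export
sim_layer_image <- function(layer_means = c(0.4, 1, 0.3),
                            layer_widths = c(90, 210, 90),
                            roi_height_px = 150,
                            noise_sd = 0,
                            seed = NULL) {
  if (length(layer_means) != 3 || any(layer_means < 0)) {
    abort("`layer_means` must be 3 non-negative intensities (ACL, IPL, GCL)",
          class = "zfeye_invalid_spec")
  }
  if (length(layer_widths) != 3 || any(layer_widths < 1)) {
    abort("`layer_widths` must be 3 widths >= 1 px", class = "zfeye_invalid_spec")
  }
  if (roi_height_px < 1) {
    abort("`roi_height_px` must be >= 1", class = "zfeye_invalid_spec")
  }
  layer_widths <- as.integer(layer_widths)
  width <- sum(layer_widths)
  col_mean <- rep(layer_means, times = layer_widths)
  img <- local_seed(seed, {
    matrix(rep(col_mean, each = roi_height_px), nrow = roi_height_px) +
      matrix(rnorm(roi_height_px * width, 0, noise_sd), nrow = roi_height_px)
  })
  ends <- cumsum(layer_widths)
  truth <- tibble::tibble(
    layer = c("ACL", "IPL", "GCL"),
    start_px = c(1L, ends[1] + 1L, ends[2] + 1L),
    end_px = ends,
    mean_intensity = layer_means
  )
  attr(img, "ground_truth") <- truth
  img
}

#' Simulate a qPCR Ct table
#'
#' Generates threshold-cycle (Ct) values whose true delta-delta-Ct equals
#' `-log2(fold_change)` relative to whichever group carries fold 1 (the
#' intended calibrator). Each sample gets a shared loading offset applied
#' to every gene (so per-sample delta-Ct is exact), and each replicate adds
#' independent Ct noise. The reference gene always has fold 1.
#'
#' @param fold_changes Data frame with columns `group`, `gene`,
#'   `fold_change` (> 0) for the target genes; groups absent for a gene
#'   default to fold 1. An optional `timepoint` column stratifies the
#'   design.
#' @param reference_gene Housekeeping gene label (default `"ef1a"`).
#' @param n_samples_per_group Biological samples per group (default 4).
#' @param n_replicates Technical replicates per sample (default 3).
#' @param ct_noise_sd Replicate Ct noise SD, cycles.
#' @param loading_sd SD of the per-sample loading offset, cycles.
#' @param base_ct Named baseline Ct per gene; unnamed default 25 for
#'   targets, 20 for the reference.
#' @param seed Integer seed.
#' @return Tibble with columns `sample_id`, `group`, (`timepoint`,) `gene`,
#'   `replicate`, `ct`; ground-truth fold changes attached.
#' @export
sim_ct_table <- function(fold_changes,
                         reference_gene = "ef1a",
                         n_samples_per_group = 4,
                         n_replicates = 3,
                         ct_noise_sd = 0,
                         loading_sd = 0.5,
                         base_ct = NULL,
                         seed = 1) {
  fold_changes <- tibble::as_tibble(fold_changes)
  assert_columns(fold_changes, c("group", "gene", "fold_change"),
                 "`fold_changes`")
  if (any(fold_changes$fold_change <= 0)) {
    abort("fold changes must be > 0", class = "zfeye_invalid_spec")
  }
  if (reference_gene %in% fold_changes$gene) {
    abort("the reference gene cannot carry a fold change",
          class = "zfeye_invalid_spec")
  }
  if (n_replicates < 1 || n_samples_per_group < 1) {
    abort("sample and replicate counts must be >= 1",
          class = "zfeye_invalid_spec")
  }
  has_tp <- "timepoint" %in% names(fold_changes)
  if (!has_tp) fold_changes$timepoint <- "tp1"

  genes <- c(unique(fold_changes$gene), reference_gene)
  groups <- unique(fold_changes$group)
  timepoints <- unique(fold_changes$timepoint)
  if (is.null(base_ct)) {
    base_ct <- setNames(rep(25, length(genes)), genes)
    base_ct[reference_gene] <- 20
  }

  design <- tidyr::expand_grid(
    timepoint = timepoints, group = groups,
    sample = seq_len(n_samples_per_group)
  ) |>
    dplyr::mutate(sample_id = paste(.data$timepoint, .data$group,
                                    paste0("s", .data$sample), sep = "_"))

  full <- tidyr::expand_grid(design, gene = genes) |>
    dplyr::left_join(fold_changes,
                     by = c("timepoint", "group", "gene")) |>
    dplyr::mutate(fold_change = dplyr::coalesce(.data$fold_change, 1))

  out <- local_seed(seed, {
    loading <- setNames(rnorm(nrow(design), 0, loading_sd), design$sample_id)
    tidyr::expand_grid(full, replicate = seq_len(n_replicates)) |>
      dplyr::mutate(
        ct = base_ct[.data$gene] + loading[.data$sample_id] -
          log2(.data$fold_change) +
          rnorm(dplyr::n(), 0, ct_noise_sd)
      )
  })
  out <- dplyr::select(out, "sample_id", "group", "timepoint", "gene",
                       "replicate", "ct")
  if (!has_tp) out$timepoint <- NULL
  truth <- dplyr::select(full, "group", dplyr::any_of("timepoint"), "gene",
                         "fold_change") |> dplyr::distinct()
  if (!has_tp) truth$timepoint <- NULL
  attr(out, "ground_truth") <- truth
  out
}
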