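test_that("noise-free trajectories integrate the drift exactly", {
  traj <- sim_trajectory(tuning_gain = 1, stim_direction = 1,
                         stim_speed = 0.5, duration = 30, noise_sd = 0)
  expect_equal(ground_truth(traj)$net_displacement_rad, 15)

  still <- sim_trajectory(tuning_gain = 0, stim_direction = -1, noise_sd = 0)
  expect_equal(ground_truth(still)$net_displacement_rad, 0)
  expect_true(all(still$angle_rad == still$angle_rad[1]))
})

test_that("noisy trajectory displacement matches independent re-integration", {
  traj <- sim_trajectory(tuning_gain = 0.6, stim_direction = 1,
                         noise_sd = 0.05, seed = 7)
  # re-integrate the same seeded noise stream outside the generator
  dt <- 1 / 30
  inc <- withr::with_seed(7L, {
    0.6 * 1 * 0.5 * dt + rnorm(900, 0, 0.05 * sqrt(dt))
  })
  expect_equal(ground_truth(traj)$net_displacement_rad, sum(inc),
               tolerance = 1e-12)
  # and the displacement is within 3 SD of the drift 0.6 * 0.5 * 30 = 9
  expect_lt(abs(ground_truth(traj)$net_displacement_rad - 9),
            3 * 0.05 * sqrt(30))
})

test_that("trajectory generator rejects invalid sampling specs", {
  expect_error(sim_trajectory(1, duration = 0), class = "zfeye_invalid_spec")
  expect_error(sim_trajectory(1, sample_rate = -1),
               class = "zfeye_invalid_spec")
  expect_error(sim_trajectory(1, stim_direction = 0),
               class = "zfeye_invalid_spec")
})

test_that("cohort generator produces the full factorial design with truth", {
  groups <- tibble::tibble(group = c("a", "b"), amplitude = c(1, 0.7),
                           peak_frequency = 0.0620, bandwidth = 0.3)
  co <- sim_omr_cohort(groups, n_fish_per_group = 3, seed = 4,
                       return = "omi")
  expect_equal(nrow(co), 2 * 3 * 6 * 4)
  truth <- ground_truth(co)
  expect_equal(nrow(truth), nrow(co))
  # curve gain at the peak frequency equals the group amplitude
  at_peak <- truth[truth$spatial_frequency == 0.0620 & truth$group == "a", ]
  expect_true(all(at_peak$curve_gain == 1))
  # two clockwise and two counter-clockwise trials per condition
  dirs <- co |>
    dplyr::count(fish_id, spatial_frequency, stim_direction)
  expect_true(all(dirs$n == 2))
})

test_that("generators are pure functions of spec and seed", {
  groups <- tibble::tibble(group = "g", amplitude = 1,
                           peak_frequency = 0.062, bandwidth = 0.3)
  expect_identical(
    sim_omr_cohort(groups, n_fish_per_group = 2, seed = 9, return = "omi"),
    sim_omr_cohort(groups, n_fish_per_group = 2, seed = 9, return = "omi")
  )
  expect_identical(sim_bscan(seed = 3, jitter_sd = 2, noise_sd = 0.05),
                   sim_bscan(seed = 3, jitter_sd = 2, noise_sd = 0.05))
  fc <- tibble::tibble(group = c("c", "t"), gene = "x",
                       fold_change = c(1, 2))
  expect_identical(sim_ct_table(fc, ct_noise_sd = 0.2, seed = 5),
                   sim_ct_table(fc, ct_noise_sd = 0.2, seed = 5))
  # exported table is byte-identical across regenerations
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_zfeye_csv(sim_omr_cohort(groups, 2, seed = 9, return = "omi"), f1)
  write_zfeye_csv(sim_omr_cohort(groups, 2, seed = 9, return = "omi"), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the generator does not disturb the global RNG stream
  set.seed(42); r1 <- rnorm(1)
  set.seed(42); invisible(sim_bscan(seed = 1)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("single-component ERG traces peak where the kernel peaks", {
  tr <- sim_erg_trace(a_scale = 100, b_scale = 0, noise_sd = 0,
                      pre_stimulus_ms = 50, duration_ms = 300)
  expect_equal(min(tr$voltage_uv), -100)
  expect_equal(tr$time_ms[which.min(tr$voltage_uv)] - 50, 20)

  flat <- sim_erg_trace(a_scale = 0, b_scale = 0, noise_sd = 0)
  expect_true(all(flat$voltage_uv == 0))
  expect_equal(ground_truth(flat)$a_amplitude, 0)
})

test_that("ERG ground truth matches dense evaluation of the two-kernel sum", {
  tr <- sim_erg_trace(a_scale = 100, a_time_to_trough = 20, b_scale = 300,
                      b_time_to_peak = 60, noise_sd = 0,
                      pre_stimulus_ms = 100, duration_ms = 500)
  truth <- ground_truth(tr)
  # independent dense-grid evaluation of the closed-form sum
  k <- function(t, tp, s) ifelse(t > 0, (t / tp)^s * exp(s * (1 - t / tp)), 0)
  tg <- seq(0, 400, by = 0.01)
  vg <- -100 * k(tg, 20, 4) + 300 * k(tg, 60, 4)
  expect_equal(truth$trough_ms, tg[which.min(vg)], tolerance = 0.02)
  expect_equal(truth$peak_ms, tg[which.max(vg)], tolerance = 0.02)
  expect_equal(truth$a_amplitude, -min(vg), tolerance = 1e-6)
  expect_equal(truth$b_amplitude, max(vg) - min(vg), tolerance = 1e-6)
  # sampled trace extrema sit at the same locations
  post <- tr$time_ms - 100
  expect_equal(post[which.min(tr$voltage_uv)], round(truth$trough_ms))
  expect_equal(post[which.max(tr$voltage_uv)], round(truth$peak_ms))
})

test_that("ERG spec errors: kernel outside trace, bad durations", {
  expect_error(sim_erg_trace(b_time_to_peak = 600, duration_ms = 400),
               class = "zfeye_invalid_spec")
  expect_error(sim_erg_trace(duration_ms = 50, pre_stimulus_ms = 100),
               class = "zfeye_invalid_spec")
  expect_error(sim_erg_trace(kernel_shape = 0.5),
               class = "zfeye_invalid_spec")
})

test_that("noiseless B-scans place exactly four band maxima at true rows", {
  b <- sim_bscan(jitter_sd = 0, noise_sd = 0)
  truth <- ground_truth(b)
  profile <- rowMeans(b)
  local_max <- which(diff(sign(diff(profile))) == -2) + 1
  expect_length(local_max, 4)
  expect_equal(local_max, round(truth$row_px), tolerance = 1)
  # doubling the axial sampling doubles the landmark rows
  b2 <- sim_bscan(jitter_sd = 0, noise_sd = 0, px_per_um = 1)
  expect_equal(ground_truth(b2)$row_px, 2 * truth$row_px)
})

test_that("B-scan generator enforces anatomical ordering", {
  expect_error(sim_bscan(anterior_lens_pos = 90),
               class = "zfeye_invalid_spec")
})

test_that("layer images have the printed ROI widths and exact step means", {
  img <- sim_layer_image(layer_widths = c(90, 210, 90))
  expect_equal(ncol(img), 390)
  img4 <- sim_layer_image(layer_widths = c(90, 240, 125))
  expect_equal(ncol(img4), 455)

  step <- sim_layer_image(layer_means = c(0, 1, 0), noise_sd = 0)
  cm <- colMeans(step)
  expect_equal(unname(cm[1:90]), rep(0, 90))
  expect_equal(unname(cm[91:300]), rep(1, 210))
  expect_equal(unname(cm[301:390]), rep(0, 90))
})

test_that("Ct tables carry the replicate structure and exact truth", {
  fc <- tibble::tibble(group = c("ctrl", "mut"), gene = "efemp1",
                       fold_change = c(1, 0.5))
  ct <- sim_ct_table(fc, n_samples_per_group = 4, n_replicates = 3,
                     ct_noise_sd = 0, seed = 2)
  counts <- ct |> dplyr::count(group, gene)
  expect_true(all(counts$n == 12))
  expect_error(
    sim_ct_table(tibble::tibble(group = "g", gene = "x", fold_change = -1)),
    class = "zfeye_invalid_spec"
  )
  expect_error(
    sim_ct_table(tibble::tibble(group = "g", gene = "ef1a",
                                fold_change = 2)),
    class = "zfeye_invalid_spec"
  )
})
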