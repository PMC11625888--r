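triangle_trace <- function(baseline = 0, trough = -100, trough_ms = 20,
                           peak = 200, peak_ms = 60, onset = 100,
                           total = 400) {
  t <- seq(0, total, by = 1)
  v <- rep(baseline, length(t))
  ramp <- function(center, width, height) {
    x <- pmax(0, 1 - abs(t - (onset + center)) / width)
    x * height
  }
  v <- v + ramp(trough_ms, 10, trough) + ramp(peak_ms, 15, peak)
  tibble::tibble(time_ms = t, voltage_uv = v, onset_ms = onset,
                 intensity = 1.87, eye_id = "e1", fish_id = "f1",
                 group = "g", condition = "c")
}

test_that("amplitudes follow the baseline-to-trough / trough-to-peak rules", {
  tr <- triangle_trace()
  ft <- erg_features(tr)
  expect_equal(ft$baseline_uv, 0)
  expect_equal(ft$a_amplitude_uv, 100)
  expect_equal(ft$b_amplitude_uv, 300)
  expect_equal(ft$a_implicit_time_ms, 20)
  expect_equal(ft$b_implicit_time_ms, 60)
  expect_equal(ft$flags, "ok")
})

test_that("flat traces are flagged no-response, not given fake features", {
  flat <- triangle_trace(trough = 0, peak = 0)
  ft <- erg_features(flat)
  expect_equal(ft$a_amplitude_uv, 0)
  expect_equal(ft$b_amplitude_uv, 0)
  expect_true(is.na(ft$a_implicit_time_ms))
  expect_true(is.na(ft$b_implicit_time_ms))
  expect_match(ft$flags, "no-response")
})

test_that("features are invariant to offset and to joint time shifts", {
  tr <- triangle_trace()
  ft <- erg_features(tr)

  off <- dplyr::mutate(tr, voltage_uv = voltage_uv + 37.5)
  ft_off <- erg_features(off)
  expect_equal(ft_off$baseline_uv, 37.5)
  expect_equal(ft_off$a_amplitude_uv, ft$a_amplitude_uv)
  expect_equal(ft_off$b_amplitude_uv, ft$b_amplitude_uv)

  sh <- dplyr::mutate(tr, time_ms = time_ms + 250, onset_ms = onset_ms + 250)
  ft_sh <- erg_features(sh)
  expect_equal(
    dplyr::select(ft_sh, -dplyr::any_of("eye_id")),
    dplyr::select(ft, -dplyr::any_of("eye_id"))
  )
})

test_that("extraction equals the brute-force windowed argmin/argmax oracle", {
  for (s in 1:25) {
    tr <- sim_erg_trace(noise_sd = 5, seed = s)
    ft <- erg_features(tr)
    or <- oracle_erg_features(tr$time_ms, tr$voltage_uv, tr$onset_ms[1])
    expect_identical(ft$a_implicit_time_ms, or$a_implicit_time)
    expect_identical(ft$b_implicit_time_ms, or$b_implicit_time)
    expect_lt(abs(ft$a_amplitude_uv - or$a_amplitude), 1e-9)
    expect_lt(abs(ft$b_amplitude_uv - or$b_amplitude), 1e-9)
    if (!is.na(ft$a_implicit_time_ms) && !is.na(ft$b_implicit_time_ms)) {
      expect_gt(ft$b_implicit_time_ms, ft$a_implicit_time_ms)
    }
  }
})

test_that("group averages carry SEM with an n-1 SD and flag single traces", {
  tr <- sim_erg_trace(noise_sd = 0)
  five <- purrr::map(1:5, function(i) {
    dplyr::mutate(tr, eye_id = paste0("e", i))
  }) |> purrr::list_rbind()
  avg <- erg_group_average(five)
  expect_equal(avg$mean_uv, tr$voltage_uv)
  expect_true(all(avg$sem_uv == 0))
  expect_true(all(avg$n_traces == 5))

  # two constant traces at +1 and -1: SD = sqrt(2), SEM = sd/sqrt(2) = 1
  two <- dplyr::bind_rows(
    tibble::tibble(time_ms = 0:10, voltage_uv = 1, onset_ms = 5,
                   eye_id = "e1", group = "g"),
    tibble::tibble(time_ms = 0:10, voltage_uv = -1, onset_ms = 5,
                   eye_id = "e2", group = "g")
  )
  avg2 <- erg_group_average(two)
  expect_equal(avg2$mean_uv, rep(0, 11))
  expect_equal(avg2$sem_uv, rep(1, 11))

  single <- dplyr::mutate(tr, eye_id = "only")
  avg1 <- erg_group_average(single)
  expect_true(all(is.na(avg1$sem_uv)))
  expect_true(all(avg1$flags == "single-trace"))

  # mismatched grids refuse to average (no resampling)
  bad <- dplyr::bind_rows(
    tibble::tibble(time_ms = 0:10, voltage_uv = 1, onset_ms = 5,
                   eye_id = "e1", group = "g"),
    tibble::tibble(time_ms = seq(0, 10, by = 2), voltage_uv = 1,
                   onset_ms = 5, eye_id = "e2", group = "g")
  )
  expect_error(erg_group_average(bad), class = "zfeye_invalid_input")
})

test_that("intensity-response tables are tidy, exact and repeat-averaged", {
  base <- tidyr::expand_grid(
    eye_id = paste0("e", 1:12),
    intensity = c(-0.83, 0.73, 1.87)
  ) |>
    dplyr::mutate(
      group = "g",
      a_amplitude_uv = 10, b_amplitude_uv = 30,
      a_implicit_time_ms = 20, b_implicit_time_ms = 60
    )
  tab <- intensity_response_table(base)
  expect_equal(nrow(tab), 3 * 12 * 4)
  expect_setequal(unique(tab$intensity), c(-0.83, 0.73, 1.87))

  # three repeats at one intensity are averaged per eye before tabulation
  reps <- dplyr::bind_rows(
    dplyr::mutate(base[base$eye_id == "e1" & base$intensity == -0.83, ],
                  repeat_id = 1, a_amplitude_uv = 9),
    dplyr::mutate(base[base$eye_id == "e1" & base$intensity == -0.83, ],
                  repeat_id = 2, a_amplitude_uv = 10),
    dplyr::mutate(base[base$eye_id == "e1" & base$intensity == -0.83, ],
                  repeat_id = 3, a_amplitude_uv = 11)
  )
  tab2 <- intensity_response_table(reps)
  a_row <- tab2[tab2$feature == "a_amplitude_uv", ]
  expect_equal(a_row$value, 10)
  expect_equal(a_row$n_repeats, 3L)

  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(intensity_response_table(dup), class = "zfeye_invalid_input")
})
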