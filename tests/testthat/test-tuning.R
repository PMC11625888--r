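test_that("log_gaussian has the closed-form peak and bandwidth points", {
  expect_equal(log_gaussian(0.062, 1.3, 0.062, 0.3), 1.3)
  expect_equal(log_gaussian(0.062 * 10^0.3, 1.3, 0.062, 0.3),
               1.3 * exp(-1 / 2))
  # dual formulation: Gaussian density ratio in log10-frequency
  f <- 0.0155
  direct <- log_gaussian(f, 1, 0.062, 0.3)
  ratio <- stats::dnorm(log10(f), log10(0.062), 0.3) /
    stats::dnorm(log10(0.062), log10(0.062), 0.3)
  expect_equal(direct, ratio, tolerance = 1e-12)
  # symmetry in log-frequency about the peak
  for (d in c(0.1, 0.25, 0.6)) {
    expect_equal(log_gaussian(0.062 * 10^d, 2, 0.062, 0.4),
                 log_gaussian(0.062 * 10^-d, 2, 0.062, 0.4),
                 tolerance = 1e-12)
  }
  expect_error(log_gaussian(-1, 1, 0.062, 0.3), class = "zfeye_domain_error")
  expect_error(log_gaussian(0.1, 1, 0.062, -0.3),
               class = "zfeye_domain_error")
})

test_that("noiseless data at the six test frequencies are recovered exactly", {
  f <- rep(omr_frequencies(), 3)
  d <- tibble::tibble(spatial_frequency = f,
                      omi_normalized = log_gaussian(f, 1, 0.062, 0.3))
  fit <- fit_log_gaussian(d)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$peak_frequency, 0.062, tolerance = 1e-6)
  expect_equal(fit$bandwidth, 0.3, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$df, length(f) - 3L)
})

test_that("degenerate designs are flagged or rejected", {
  zeros <- tibble::tibble(spatial_frequency = omr_frequencies(),
                          omi_normalized = 0)
  fit <- fit_log_gaussian(zeros)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$rss, 0)
  expect_false(fit$identifiable)

  expect_error(
    fit_log_gaussian(zeros[1:3, ]),
    class = "zfeye_insufficient_data"
  )
  same_f <- tibble::tibble(spatial_frequency = 0.062,
                           omi_normalized = c(1, 2, 3, 4))
  expect_error(fit_log_gaussian(same_f), class = "zfeye_degenerate_design")
})

test_that("the optimizer matches a dense 3-D grid-search oracle", {
  ds <- make_tuning_dataset(seed = 11)
  wt <- ds[ds$group == "wt", ]
  fit <- fit_log_gaussian(wt)
  oracle <- oracle_fit_grid(wt$spatial_frequency, wt$omi_normalized,
                            n_grid = 60, rounds = 6)
  expect_lt(fit$rss, oracle$rss + 1e-6)
  expect_equal(fit$rss, oracle$rss, tolerance = 1e-4)
})

test_that("extra-sum-of-squares arithmetic matches the hand example", {
  # RSS_R = 12, RSS_F = 10, N = 24, G = 2: F = ((12-10)/3)/(10/18) = 1.2
  stat <- zfeye:::extra_sum_of_squares_f(10, 12, k_full = 6, k_restr = 3,
                                         n = 24)
  expect_equal(stat$f, 1.2)
  expect_equal(stat$df_num, 3)
  expect_equal(stat$df_den, 18)
  expect_equal(stat$p, stats::pf(1.2, 3, 18, lower.tail = FALSE))
})

test_that("identical groups give F ~ 0 and p ~ 1 in the omnibus test", {
  one <- tibble::tibble(
    fish_id = rep(paste0("f", 1:2), each = 6),
    spatial_frequency = rep(omr_frequencies(), 2),
    omi_normalized = log_gaussian(rep(omr_frequencies(), 2), 1, 0.062, 0.3) +
      rep(c(0.05, -0.05), each = 6)
  )
  both <- dplyr::bind_rows(
    dplyr::mutate(one, group = "a"),
    dplyr::mutate(one, group = "b")
  )
  cmp <- omnibus_f_test(both)
  expect_lt(cmp$f_statistic, 1e-4)
  expect_gt(cmp$p_value, 0.999)
  expect_gte(cmp$rss_restricted - cmp$rss_full, -1e-12)
})

test_that("nested test df counting and the already-true constraint", {
  # equal amplitudes, different peaks, noiseless: amplitude constraint
  # costs nothing
  f <- omr_frequencies()
  d <- dplyr::bind_rows(
    tibble::tibble(group = "a", fish_id = rep(c("f1", "f2"), each = 6),
                   spatial_frequency = rep(f, 2),
                   omi_normalized = log_gaussian(rep(f, 2), 1, 0.031, 0.3)),
    tibble::tibble(group = "b", fish_id = rep(c("f3", "f4"), each = 6),
                   spatial_frequency = rep(f, 2),
                   omi_normalized = log_gaussian(rep(f, 2), 1, 0.124, 0.3))
  )
  cmp <- nested_f_test(d, "amplitude")
  # G = 2, N = 24: df = (1, 18)
  expect_equal(cmp$df_num, 1)
  expect_equal(cmp$df_den, 18)
  expect_lt(cmp$f_statistic, 1e-4)
})

test_that("restricted fits never beat full fits across random cohorts", {
  for (s in 1:8) {
    ds <- make_tuning_dataset(amp2 = 0.85, seed = 100 + s, n_fish = 6)
    for (cmp in list(omnibus_f_test(ds),
                     nested_f_test(ds, "amplitude"),
                     nested_f_test(ds, "bandwidth"))) {
      expect_gte(cmp$rss_restricted - cmp$rss_full, -1e-12)
      expect_gte(cmp$f_statistic, 0)
    }
  }
})

test_that("amplitude-nested F matches the 5-parameter grid-search oracle", {
  for (s in 1:2) {
    ds <- make_tuning_dataset(amp2 = 0.75, seed = 200 + s)
    cmp <- nested_f_test(ds, "amplitude")
    wt <- ds[ds$group == "wt", ]; mut <- ds[ds$group == "mut", ]
    oracle_r <- oracle_restricted_amplitude_grid(
      log10(mut$spatial_frequency), mut$omi_normalized,
      log10(wt$spatial_frequency), wt$omi_normalized
    )
    oracle_f1 <- oracle_fit_grid(wt$spatial_frequency, wt$omi_normalized)
    oracle_f2 <- oracle_fit_grid(mut$spatial_frequency, mut$omi_normalized)
    rss_f <- oracle_f1$rss + oracle_f2$rss
    n <- nrow(ds)
    f_oracle <- ((oracle_r$rss - rss_f) / 1) / (rss_f / (n - 6))
    expect_equal(cmp$f_statistic, f_oracle, tolerance = 1e-4)
  }
})

test_that("tidiers expose estimates and the comparison table", {
  ds <- make_tuning_dataset(seed = 3, n_fish = 5)
  fit <- fit_log_gaussian(ds[ds$group == "wt", ])
  td <- tidy(fit)
  expect_equal(td$term, c("amplitude", "peak_frequency", "bandwidth"))
  expect_equal(glance(fit)$nobs, 30L)
  cmp <- omnibus_f_test(ds)
  expect_named(
    tidy(cmp),
    c("comparison", "f_statistic", "df_num", "df_den", "p_value",
      "rss_full", "rss_restricted")
  )
})
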