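hand_ct <- function() {
  # two groups x two samples, target/reference constructed so that the
  # calibrator-group mean delta-Ct is 4 and the case sample's is 5
  tibble::tibble(
    sample_id = rep(c("c1", "c2", "m1", "m2"), each = 2 * 3),
    group = rep(c("ctrl", "ctrl", "mut", "mut"), each = 6),
    gene = rep(rep(c("tgt", "ef1a"), each = 3), times = 4),
    replicate = rep(1:3, times = 8),
    ct = c(
      24.5, 24.5, 24.5, 20.5, 20.5, 20.5,   # c1: dCt 4
      24.0, 24.0, 24.0, 20.0, 20.0, 20.0,   # c2: dCt 4
      25.0, 25.0, 25.0, 20.0, 20.0, 20.0,   # m1: dCt 5
      25.0, 25.0, 25.0, 20.0, 20.0, 20.0    # m2: dCt 5
    )
  )
}

test_that("replicate averaging is the arithmetic mean with counts", {
  ct <- tibble::tibble(
    sample_id = "s1", group = "g", gene = "x",
    replicate = 1:3, ct = c(20.0, 20.2, 19.8)
  )
  avg <- average_ct_replicates(ct)
  expect_equal(avg$mean_ct, 20.0)
  expect_equal(avg$n_replicates, 3L)

  one <- average_ct_replicates(ct[1, ])
  expect_equal(one$mean_ct, 20.0)
  expect_equal(one$n_replicates, 1L)

  bad <- ct; bad$ct[2] <- NaN
  expect_error(average_ct_replicates(bad), class = "zfeye_invalid_input")
})

test_that("ddCt hand example: dCt 5 vs calibrator 4 gives fold 0.5", {
  expr <- relative_expression(hand_ct(), reference_gene = "ef1a",
                              calibrator_group = "ctrl")
  mut <- expr[expr$group == "mut", ]
  expect_equal(mut$delta_ct, c(5, 5))
  expect_equal(mut$delta_delta_ct, c(1, 1))
  expect_equal(mut$fold_change, c(0.5, 0.5))
  # ddCt 0 -> fold 1; one cycle lower than expected -> fold 2
  expect_equal(2^(-0), 1)
  shifted <- hand_ct()
  shifted$ct[shifted$sample_id == "m1" & shifted$gene == "tgt"] <- 23.0
  expr2 <- relative_expression(shifted, reference_gene = "ef1a",
                               calibrator_group = "ctrl")
  expect_equal(expr2$fold_change[expr2$sample_id == "m1"], 2)
})

test_that("calibrator geometric mean is exactly 1 and offsets cancel", {
  fc <- tibble::tibble(group = c("ctrl", "mut"), gene = "efemp1",
                       fold_change = c(1, 0.5))
  ct <- sim_ct_table(fc, ct_noise_sd = 0.3, seed = 6)
  expr <- relative_expression(ct, calibrator_group = "ctrl")
  gm <- exp(mean(log(expr$fold_change[expr$group == "ctrl"])))
  expect_equal(gm, 1, tolerance = 1e-12)

  # adding a constant to every Ct of one sample leaves its results unchanged
  shifted <- ct
  shifted$ct[shifted$sample_id == shifted$sample_id[1]] <-
    shifted$ct[shifted$sample_id == shifted$sample_id[1]] + 3
  expr_s <- relative_expression(shifted, calibrator_group = "ctrl")
  expect_equal(expr_s$fold_change, expr$fold_change, tolerance = 1e-12)
})

test_that("true fold changes are recovered exactly at zero Ct noise", {
  fc <- tibble::tibble(
    group = rep(c("ctrl", "mut"), times = 3),
    gene = rep(c("efemp1", "egr1", "gjd2b"), each = 2),
    fold_change = c(1, 0.5, 1, 2, 1, 1)
  )
  ct <- sim_ct_table(fc, ct_noise_sd = 0, seed = 4)
  expr <- relative_expression(ct, calibrator_group = "ctrl")
  got <- expr |>
    dplyr::group_by(group, gene) |>
    dplyr::summarise(fold = mean(fold_change), .groups = "drop") |>
    dplyr::arrange(gene, group)
  truth <- ground_truth(ct) |>
    dplyr::filter(gene != "ef1a") |>
    dplyr::arrange(gene, group)
  expect_equal(got$fold, truth$fold_change, tolerance = 1e-12)

  # fold 1 everywhere means all ddCt are 0
  flat <- sim_ct_table(
    tibble::tibble(group = c("a", "b"), gene = "x", fold_change = 1),
    ct_noise_sd = 0, seed = 9
  )
  expr_flat <- relative_expression(flat, calibrator_group = "a")
  expect_equal(expr_flat$delta_delta_ct, rep(0, nrow(expr_flat)),
               tolerance = 1e-12)
})

test_that("timepoint strata calibrate independently", {
  fc <- tibble::tibble(
    group = rep(c("ctrl", "mut"), times = 2),
    gene = "efemp1",
    timepoint = rep(c("2d", "4w"), each = 2),
    fold_change = c(1, 0.5, 1, 2)
  )
  ct <- sim_ct_table(fc, ct_noise_sd = 0, seed = 3)
  expr <- relative_expression(ct, calibrator_group = "ctrl")
  m <- expr |>
    dplyr::filter(group == "mut") |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(fold = mean(fold_change))
  expect_equal(m$fold[m$timepoint == "2d"], 0.5, tolerance = 1e-12)
  expect_equal(m$fold[m$timepoint == "4w"], 2, tolerance = 1e-12)
})

test_that("design errors are caught", {
  ct <- hand_ct()
  expect_error(relative_expression(ct, reference_gene = "actb",
                                   calibrator_group = "ctrl"),
               class = "zfeye_invalid_design")
  expect_error(relative_expression(ct, reference_gene = "ef1a",
                                   calibrator_group = "none"),
               class = "zfeye_invalid_design")
  # a sample missing the reference gene is incomplete
  broken <- ct[!(ct$sample_id == "m1" & ct$gene == "ef1a"), ]
  expect_error(relative_expression(broken, reference_gene = "ef1a",
                                   calibrator_group = "ctrl"),
               class = "zfeye_incomplete_sample")
})
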