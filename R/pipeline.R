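# End-to-end orchestration: simulate every modality from one seeded
# config, analyze each with the package's own functions, write tidy CSVs
# and a reproducibility manifest, and render a text report.

pipeline_schema <- list(
  seed = NULL, out_dir = NULL, log_level = NULL,
  omr = c("groups", "n_fish_per_group", "frequencies",
          "trials_per_condition", "noise_sd_omi", "stim_speed", "duration",
          "reference_group", "reference_frequency"),
  erg = c("groups", "n_eyes_per_group", "noise_sd", "intensity",
          "kernel_shape", "sample_interval", "pre_stimulus_ms",
          "duration_ms"),
  oct = c("geometry", "n_eyes_per_group", "jitter_sd", "control_group"),
  layers = c("groups", "n_eyes_per_group", "layer_widths", "roi_height_px",
             "noise_sd", "scheme", "control_group"),
  qpcr = c("fold_changes", "reference_gene", "n_samples_per_group",
           "n_replicates", "ct_noise_sd", "calibrator_group")
)

validate_config <- function(config) {
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "zfeye_invalid_config")
  }
  for (sec in intersect(names(config),
                        c("omr", "erg", "oct", "layers", "qpcr"))) {
    bad <- setdiff(names(config[[sec]]), pipeline_schema[[sec]])
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in config section '%s': %s",
                    sec, paste(bad, collapse = ", ")),
            class = "zfeye_invalid_config")
    }
  }
  if (is.null(config$seed)) {
    abort("config must carry a `seed`", class = "zfeye_invalid_config")
  }
  invisible(config)
}

as_group_tibble <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  purrr::map(x, tibble::as_tibble_row) |> purrr::list_rbind()
}

#' Demo pipeline configuration
#'
#' A two-group (wild-type vs mutant) study in which the mutant group has a
#' 30% tuning-amplitude deficit, an elevated R/L ratio (+0.1, a relative
#' myopic shift), smaller ERG waves, a dimmer IPL and a halved expression
#' of one target gene — the qualitative phenotype directions the pipeline
#' should report back.
#'
#' @param seed Integer seed driving every stage.
#' @return A named config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = seed,
    omr = list(
      groups = tibble::tibble(
        group = c("wildtype", "mutant"),
        amplitude = c(1, 0.7),
        peak_frequency = c(0.0620, 0.0620),
        bandwidth = c(0.3, 0.3)
      ),
      n_fish_per_group = 14,
      noise_sd_omi = 0.1,
      reference_group = "wildtype",
      reference_frequency = 0.0620
    ),
    erg = list(
      groups = tibble::tibble(
        group = c("wildtype", "mutant"),
        a_scale = c(100, 70),
        b_scale = c(300, 220)
      ),
      n_eyes_per_group = 12,
      noise_sd = 5,
      intensity = 1.87
    ),
    oct = list(
      geometry = tibble::tibble(
        group = c("wildtype", "mutant"),
        cornea_pos = c(100, 100),
        anterior_lens_pos = c(150, 150),
        posterior_lens_pos = c(650, 650),
        rpe_pos = c(1000, 1025)   # R/L 2.6 vs 2.7
      ),
      n_eyes_per_group = 30,
      jitter_sd = 5,
      control_group = "wildtype"
    ),
    layers = list(
      groups = tibble::tibble(
        group = c("wildtype", "mutant"),
        acl = c(0.4, 0.4),
        ipl = c(1.0, 0.75),
        gcl = c(0.3, 0.3)
      ),
      n_eyes_per_group = 8,
      layer_widths = c(90, 210, 90),
      roi_height_px = 150,
      noise_sd = 0.02,
      scheme = "2day",
      control_group = "wildtype"
    ),
    qpcr = list(
      fold_changes = tibble::tibble(
        group = c("wildtype", "mutant"), gene = "efemp1",
        fold_change = c(1, 0.5)
      ),
      reference_gene = "ef1a",
      n_samples_per_group = 4,
      n_replicates = 3,
      ct_noise_sd = 0.1,
      calibrator_group = "wildtype"
    )
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "zfeye_stage_error", parent = e)
  })
}

#' Run the simulate-analyze-report pipeline
#'
#' Executes every configured stage in dependency order on synthetic data:
#' optomotor cohort -> OMI -> normalization -> per-group tuning fits and
#' omnibus/nested F-tests; ERG traces -> features and group averages; OCT
#' landmarks -> biometry and relative refraction; layer images -> profiles
#' -> IPL renormalization -> layer sums; Ct table -> relative expression.
#' Each stage writes tidy CSVs into `out_dir`; a JSON manifest (config
#' echo, package version, seed, per-file MD5 hashes, warnings) is written
#' last, followed by a human-readable `report.txt`.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML file
#'   with the same structure. Unknown keys are rejected before any stage
#'   runs.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly. Output files land in `out_dir`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("zfeye_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  files <- character()
  warnings <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path, progress = FALSE)
    files <<- c(files, path)
    path
  }

  if (!is.null(config$omr)) {
    run_stage("omr", {
      oc <- config$omr
      groups <- as_group_tibble(oc$groups)
      cohort <- sim_omr_cohort(
        groups,
        n_fish_per_group = oc$n_fish_per_group %||% 14,
        frequencies = oc$frequencies %||% omr_frequencies(),
        trials_per_condition = oc$trials_per_condition %||% 4,
        noise_sd_omi = oc$noise_sd_omi %||% 0.1,
        stim_speed = oc$stim_speed %||% 0.5,
        duration = oc$duration %||% 30,
        seed = seed,
        return = "omi"
      )
      emit(cohort, "omr_trials.csv")
      tuning <- cohort |>
        average_trials() |>
        normalize_omi(oc$reference_group %||% groups$group[1],
                      oc$reference_frequency %||% 0.0620)
      emit(tuning, "omr_tuning.csv")
      fits <- split(tuning, tuning$group) |>
        purrr::map(fit_log_gaussian)
      emit(
        purrr::imap(fits, ~ dplyr::mutate(tidy(.x), group = .y)) |>
          purrr::list_rbind() |>
          dplyr::select("group", "term", "estimate"),
        "tuning_fits.csv"
      )
      comparisons <- dplyr::bind_rows(
        tidy(omnibus_f_test(tuning)),
        tidy(nested_f_test(tuning, "amplitude")),
        tidy(nested_f_test(tuning, "peak_frequency")),
        tidy(nested_f_test(tuning, "bandwidth"))
      )
      emit(comparisons, "tuning_comparisons.csv")
    })
  }

  if (!is.null(config$erg)) {
    run_stage("erg", {
      ec <- config$erg
      groups <- as_group_tibble(ec$groups)
      n_eyes <- ec$n_eyes_per_group %||% 12
      design <- tidyr::expand_grid(groups, eye = seq_len(n_eyes))
      traces <- purrr::pmap(
        list(design$group, design$a_scale, design$b_scale, design$eye,
             seq_len(nrow(design))),
        function(g, a, b, eye, i) {
          sim_erg_trace(
            a_scale = a, b_scale = b,
            kernel_shape = ec$kernel_shape %||% 4,
            noise_sd = ec$noise_sd %||% 5,
            sample_interval = ec$sample_interval %||% 1,
            pre_stimulus_ms = ec$pre_stimulus_ms %||% 100,
            duration_ms = ec$duration_ms %||% 500,
            seed = seed * 1000L + i,
            intensity = ec$intensity %||% 1.87,
            eye_id = paste0(g, "_eye", sprintf("%02d", eye)),
            fish_id = paste0(g, "_fish", sprintf("%02d", (eye + 1) %/% 2)),
            group = g
          )
        }
      ) |> purrr::list_rbind()
      features <- erg_features(traces)
      emit(features, "erg_features.csv")
      emit(erg_group_average(traces), "erg_group_average.csv")
      emit(intensity_response_table(features), "erg_intensity_response.csv")
    })
  }

  if (!is.null(config$oct)) {
    run_stage("oct", {
      xc <- config$oct
      geometry <- as_group_tibble(xc$geometry)
      lm <- sim_oct_landmarks(geometry,
                              n_eyes = xc$n_eyes_per_group %||% 30,
                              jitter_sd = xc$jitter_sd %||% 5,
                              seed = seed + 101L)
      bio <- compute_biometry(lm)
      emit(bio, "oct_biometry.csv")
      control <- xc$control_group %||% geometry$group[1]
      shifts <- purrr::map(
        setdiff(unique(bio$group), control),
        function(g) {
          relative_refraction(bio$rl_ratio[bio$group == g],
                              bio$rl_ratio[bio$group == control]) |>
            dplyr::mutate(group = g, control = control, .before = 1)
        }
      ) |> purrr::list_rbind()
      emit(shifts, "oct_refraction.csv")
    })
  }

  if (!is.null(config$layers)) {
    run_stage("layers", {
      lc <- config$layers
      groups <- as_group_tibble(lc$groups)
      widths <- lc$layer_widths %||% c(90, 210, 90)
      n_eyes <- lc$n_eyes_per_group %||% 8
      design <- tidyr::expand_grid(groups, eye = seq_len(n_eyes))
      profiles <- purrr::pmap(
        list(design$group, design$acl, design$ipl, design$gcl,
             design$eye, seq_len(nrow(design))),
        function(g, a, i, c_, eye, k) {
          img <- sim_layer_image(
            layer_means = c(a, i, c_), layer_widths = widths,
            roi_height_px = lc$roi_height_px %||% 150,
            noise_sd = lc$noise_sd %||% 0.02,
            seed = seed * 2000L + k
          )
          tr <- ground_truth(img)
          prof <- extract_profile(img, lc$roi_height_px %||% 150,
                                  ipl_bounds = c(tr$start_px[2], tr$end_px[2]))
          list(group = g, eye_id = paste0(g, "_eye", sprintf("%02d", eye)),
               profile = prof)
        }
      )
      control <- lc$control_group %||% groups$group[1]
      ipl_w <- vapply(profiles, function(p) {
        b <- attr(p$profile, "ipl_bounds"); b[2] - b[1] + 1
      }, numeric(1))
      control_ipl <- mean(ipl_w[vapply(profiles, `[[`, "", "group") == control])
      sums <- purrr::map(profiles, function(p) {
        p$profile |>
          resample_to_control_ipl(control_ipl) |>
          normalize_profile() |>
          layer_sums(scheme = lc$scheme %||% "2day") |>
          dplyr::mutate(group = p$group, eye_id = p$eye_id, .before = 1)
      }) |> purrr::list_rbind()
      emit(sums, "layer_sums.csv")
    })
  }

  if (!is.null(config$qpcr)) {
    run_stage("qpcr", {
      qc <- config$qpcr
      ct <- sim_ct_table(
        as_group_tibble(qc$fold_changes),
        reference_gene = qc$reference_gene %||% "ef1a",
        n_samples_per_group = qc$n_samples_per_group %||% 4,
        n_replicates = qc$n_replicates %||% 3,
        ct_noise_sd = qc$ct_noise_sd %||% 0.1,
        seed = seed + 707L
      )
      emit(ct, "qpcr_ct.csv")
      expr <- relative_expression(
        ct,
        reference_gene = qc$reference_gene %||% "ef1a",
        calibrator_group = qc$calibrator_group
      )
      emit(expr, "qpcr_expression.csv")
      emit(summarize_expression(expr), "qpcr_summary.csv")
    })
  }

  manifest <- list(
    package = "zfeye",
    version = as.character(utils::packageVersion("zfeye")),
    seed = seed,
    config = config,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      unname(tools::md5sum(f))
    }),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  writeLines(make_report(out_dir), file.path(out_dir, "report.txt"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_pm <- function(m, s) sprintf("%.3g +/- %.2g", m, s)

#' Render a human-readable summary report from pipeline outputs
#'
#' Reads the tidy CSVs in a pipeline output directory and produces a text
#' summary: per-group tuning fits with the F-test table, biometry means
#' with the relative-refraction call, ERG feature means, per-layer
#' intensity sums, and qPCR fold changes. Every number in the report is a
#' recomputation from the tidy files, so report and CSVs cannot drift
#' apart.
#'
#' @param out_dir Directory produced by [run_pipeline()].
#' @return Character vector of report lines (also written to
#'   `report.txt` by [run_pipeline()]).
#' @export
make_report <- function(out_dir) {
  have <- function(f) file.exists(file.path(out_dir, f))
  rd <- function(f) readr::read_csv(file.path(out_dir, f),
                                    show_col_types = FALSE, progress = FALSE)
  if (!any(vapply(c("omr_tuning.csv", "erg_features.csv", "oct_biometry.csv",
                    "layer_sums.csv", "qpcr_expression.csv"), have,
                  logical(1)))) {
    abort("no stage outputs found in `out_dir`", class = "zfeye_invalid_input")
  }
  lines <- c("zfeye pipeline report", strrep("=", 21), "")

  if (have("tuning_fits.csv")) {
    fits <- rd("tuning_fits.csv") |>
      tidyr::pivot_wider(names_from = "term", values_from = "estimate")
    lines <- c(lines, "Spatial-frequency tuning (log-Gaussian fits)",
               strrep("-", 44))
    for (i in seq_len(nrow(fits))) {
      lines <- c(lines, sprintf(
        "  %-10s amplitude %.3f, peak %.4f c/deg, bandwidth %.3f",
        fits$group[i], fits$amplitude[i], fits$peak_frequency[i],
        fits$bandwidth[i]
      ))
    }
    amp <- fits$amplitude
    names(amp) <- fits$group
    lo <- names(which.min(amp)); hi <- names(which.max(amp))
    if (length(unique(amp)) > 1) {
      lines <- c(lines, sprintf(
        "  => %s shows the lower tuning amplitude (%.0f%% of %s)",
        lo, 100 * min(amp) / max(amp), hi
      ))
    }
    if (have("tuning_comparisons.csv")) {
      cmp <- rd("tuning_comparisons.csv")
      for (i in seq_len(nrow(cmp))) {
        lines <- c(lines, sprintf(
          "  %-22s F(%d, %d) = %8.3f, p = %.4g",
          cmp$comparison[i], cmp$df_num[i], cmp$df_den[i],
          cmp$f_statistic[i], cmp$p_value[i]
        ))
      }
    }
    lines <- c(lines, "")
  }

  if (have("oct_biometry.csv")) {
    bio <- rd("oct_biometry.csv") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        mean_rl = mean(.data$rl_ratio),
        sem_rl = sd(.data$rl_ratio) / sqrt(dplyr::n()),
        mean_axial = mean(.data$axial_length_um),
        .groups = "drop"
      )
    lines <- c(lines, "Ocular biometry (Matthiessen's ratio)",
               strrep("-", 37))
    for (i in seq_len(nrow(bio))) {
      lines <- c(lines, sprintf(
        "  %-10s R/L %s  (axial %.0f um)",
        bio$group[i], fmt_pm(bio$mean_rl[i], bio$sem_rl[i]),
        bio$mean_axial[i]
      ))
    }
    if (have("oct_refraction.csv")) {
      refr <- rd("oct_refraction.csv")
      for (i in seq_len(nrow(refr))) {
        lines <- c(lines, sprintf(
          "  => %s vs %s: R/L shift %+.3f -> %s",
          refr$group[i], refr$control[i], refr$shift[i], refr$label[i]
        ))
      }
    }
    lines <- c(lines, "")
  }

  if (have("erg_features.csv")) {
    erg <- rd("erg_features.csv") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        a_amp = mean(.data$a_amplitude_uv),
        a_sem = sd(.data$a_amplitude_uv) / sqrt(dplyr::n()),
        b_amp = mean(.data$b_amplitude_uv),
        b_sem = sd(.data$b_amplitude_uv) / sqrt(dplyr::n()),
        a_t = mean(.data$a_implicit_time_ms, na.rm = TRUE),
        b_t = mean(.data$b_implicit_time_ms, na.rm = TRUE),
        .groups = "drop"
      )
    lines <- c(lines, "ERG features", strrep("-", 12))
    for (i in seq_len(nrow(erg))) {
      lines <- c(lines, sprintf(
        "  %-10s a-wave %s uV @ %.1f ms; b-wave %s uV @ %.1f ms",
        erg$group[i], fmt_pm(erg$a_amp[i], erg$a_sem[i]), erg$a_t[i],
        fmt_pm(erg$b_amp[i], erg$b_sem[i]), erg$b_t[i]
      ))
    }
    lines <- c(lines, "")
  }

  if (have("layer_sums.csv")) {
    ls_ <- rd("layer_sums.csv") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(dplyr::across(dplyr::ends_with("_sum"), mean),
                       .groups = "drop")
    lines <- c(lines, "Inner-retinal layer sums (normalized intensity)",
               strrep("-", 47))
    for (i in seq_len(nrow(ls_))) {
      lines <- c(lines, sprintf(
        "  %-10s ACL %.1f, IPL %.1f, GCL %.1f",
        ls_$group[i], ls_$acl_sum[i], ls_$ipl_sum[i], ls_$gcl_sum[i]
      ))
    }
    lines <- c(lines, "")
  }

  if (have("qpcr_summary.csv")) {
    qs <- rd("qpcr_summary.csv")
    lines <- c(lines, "Relative gene expression (2^-ddCt)", strrep("-", 34))
    for (i in seq_len(nrow(qs))) {
      lines <- c(lines, sprintf(
        "  %-10s %-8s fold %s (n = %d)",
        qs$group[i], qs$gene[i], fmt_pm(qs$mean_fold[i], qs$sem_fold[i]),
        qs$n_samples[i]
      ))
    }
    lines <- c(lines, "")
  }
  lines
}
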