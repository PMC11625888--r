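# Relative gene expression by the 2^-ddCt method: technical-replicate
# averaging, a housekeeping reference gene, and a calibrator group.

#' Average technical qPCR replicates
#'
#' Arithmetic mean Ct over the technical replicates of each sample x gene
#' (x timepoint, when present), with the replicate count recorded.
#' Non-finite or non-positive Ct values are rejected at ingest.
#'
#' @param ct_table Tibble with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct` and optionally `timepoint`.
#' @return Tibble with one row per sample x gene: `mean_ct`,
#'   `n_replicates`.
#' @export
average_ct_replicates <- function(ct_table) {
  assert_columns(ct_table, c("sample_id", "group", "gene", "ct"),
                 "`ct_table`")
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    abort("Ct values must be finite and positive",
          class = "zfeye_invalid_input")
  }
  keys <- intersect(c("sample_id", "group", "timepoint", "gene"),
                    names(ct_table))
  ct_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_ct = mean(.data$ct), n_replicates = dplyr::n(),
                     .groups = "drop")
}

#' Relative expression by 2^-ddCt
#'
#' For each sample: `dCt = Ct_target - Ct_reference` (replicate means);
#' `ddCt = dCt - mean(dCt over the calibrator group)`; fold change
#' `2^-ddCt`. When a `timepoint` column is present, calibration is
#' stratified: each timepoint uses the calibrator group's mean dCt at that
#' timepoint. With the group-mean calibrator convention, the geometric
#' mean fold change of the calibrator group is exactly 1. Amplification
#' efficiency is fixed at 2 (the 2^-ddCt assumption).
#'
#' @param ct_table Raw Ct tibble (as in [average_ct_replicates()], which is
#'   applied first) or an already-averaged table with a `mean_ct` column.
#' @param target_gene Target gene label(s); default every gene except the
#'   reference.
#' @param reference_gene Housekeeping gene (default `"ef1a"`).
#' @param calibrator_group Group whose mean dCt is the calibrator.
#' @return Tibble with one row per sample x target gene: `sample_id`,
#'   `group`, (`timepoint`,) `gene`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @examples
#' ct <- sim_ct_table(
#'   tibble::tibble(group = c("wt", "mut"), gene = "egr1",
#'                  fold_change = c(1, 0.5)),
#'   seed = 1
#' )
#' relative_expression(ct, calibrator_group = "wt")
#' @export
relative_expression <- function(ct_table,
                                target_gene = NULL,
                                reference_gene = "ef1a",
                                calibrator_group) {
  mean_ct <- if ("mean_ct" %in% names(ct_table)) {
    tibble::as_tibble(ct_table)
  } else {
    average_ct_replicates(ct_table)
  }
  genes <- unique(mean_ct$gene)
  if (!reference_gene %in% genes) {
    abort("reference gene absent from the Ct table",
          class = "zfeye_invalid_design")
  }
  if (is.null(target_gene)) target_gene <- setdiff(genes, reference_gene)
  if (!calibrator_group %in% mean_ct$group) {
    abort("calibrator group absent from the Ct table",
          class = "zfeye_invalid_design")
  }
  has_tp <- "timepoint" %in% names(mean_ct)
  strata <- if (has_tp) "timepoint" else character(0)

  ref <- mean_ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select(dplyr::all_of(c("sample_id", strata)),
                  ref_ct = "mean_ct")
  targ <- mean_ct |>
    dplyr::filter(.data$gene %in% target_gene)
  dct <- targ |>
    dplyr::inner_join(ref, by = c("sample_id", strata)) |>
    dplyr::mutate(delta_ct = .data$mean_ct - .data$ref_ct)
  if (nrow(dct) < nrow(targ)) {
    abort("some samples lack a reference-gene Ct (incomplete samples)",
          class = "zfeye_incomplete_sample")
  }
  calib <- dct |>
    dplyr::filter(.data$group == calibrator_group) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("gene", strata)))) |>
    dplyr::summarise(calibrator_mean_dct = mean(.data$delta_ct),
                     .groups = "drop")
  out <- dct |>
    dplyr::inner_join(calib, by = c("gene", strata)) |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - .data$calibrator_mean_dct,
      fold_change = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "group", strata, "gene",
                                  "delta_ct", "delta_delta_ct",
                                  "fold_change")))
  if (nrow(out) == 0) {
    abort("calibrator group has no samples for the target gene(s)",
          class = "zfeye_invalid_design")
  }
  out
}

#' Per-group expression summary
#'
#' Group mean and SEM of fold changes per gene (and timepoint), for
#' reporting.
#'
#' @param expression Tibble from [relative_expression()].
#' @return Tibble: grouping columns, `mean_fold`, `sem_fold`, `n_samples`.
#' @export
summarize_expression <- function(expression) {
  keys <- intersect(c("group", "timepoint", "gene"), names(expression))
  expression |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_fold = mean(.data$fold_change),
      sem_fold = if (dplyr::n() > 1) {
        sd(.data$fold_change) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}
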