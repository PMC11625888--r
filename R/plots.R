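# ggplot2 visualisations for the main result types.

#' Plot spatial-frequency tuning data with fitted curves
#'
#' Per-group mean +/- SEM of the normalized OMI against spatial frequency
#' (log scale), with the fitted log-Gaussian curves overlaid.
#'
#' @param tuning_data Tibble from [normalize_omi()] (columns `group`,
#'   `spatial_frequency`, `omi_normalized`).
#' @param fits Optional named list of `log_gaussian_fit` objects (one per
#'   group, names matching group labels).
#' @return A ggplot object.
#' @export
plot_tuning_curves <- function(tuning_data, fits = NULL) {
  assert_columns(tuning_data, c("group", "spatial_frequency"),
                 "`tuning_data`")
  resp <- default_response(tuning_data)
  summ <- tuning_data |>
    dplyr::group_by(.data$group, .data$spatial_frequency) |>
    dplyr::summarise(
      m = mean(.data[[resp]]),
      sem = sd(.data[[resp]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$spatial_frequency, .data$m,
                                          colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$sem,
                                          ymax = .data$m + .data$sem)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Spatial frequency (c/deg)", y = "Normalized OMI",
                  colour = "Group") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    f_grid <- exp(seq(log(min(summ$spatial_frequency)),
                      log(max(summ$spatial_frequency)), length.out = 120))
    curves <- purrr::imap(fits, function(fit, g) {
      tibble::tibble(group = g, spatial_frequency = f_grid,
                     m = predict(fit, f_grid))
    }) |> purrr::list_rbind()
    p <- p + ggplot2::geom_line(data = curves)
  }
  p
}

#' @rdname fit_log_gaussian
#' @export
autoplot.log_gaussian_fit <- function(object, ...) {
  f_grid <- exp(seq(log(min(object$data$spatial_frequency)),
                    log(max(object$data$spatial_frequency)),
                    length.out = 120))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$spatial_frequency, .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(
      data = tibble::tibble(spatial_frequency = f_grid,
                            response = predict(object, f_grid))
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Spatial frequency (c/deg)", y = object$response) +
    ggplot2::theme_minimal()
}

#' Plot group-average ERG traces with SEM ribbons
#'
#' @param averaged Tibble from [erg_group_average()].
#' @param colour Column mapped to colour (default `"group"` if present).
#' @return A ggplot object.
#' @export
plot_erg_traces <- function(averaged, colour = NULL) {
  assert_columns(averaged, c("time_ms", "mean_uv"), "`averaged`")
  if (is.null(colour)) {
    colour <- if ("group" %in% names(averaged)) "group" else NULL
  }
  p <- ggplot2::ggplot(averaged, ggplot2::aes(.data$time_ms, .data$mean_uv))
  if (!is.null(colour)) {
    p <- p + ggplot2::aes(colour = .data[[colour]], fill = .data[[colour]])
  }
  if ("sem_uv" %in% names(averaged) && any(is.finite(averaged$sem_uv))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_uv - .data$sem_uv,
                   ymax = .data$mean_uv + .data$sem_uv),
      alpha = 0.25, colour = NA
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (uV)") +
    ggplot2::theme_minimal()
}

#' @rdname extract_profile
#' @param object A `layer_profile`.
#' @param ... Unused.
#' @export
autoplot.layer_profile <- function(object, ...) {
  b <- attr(object, "ipl_bounds")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$position_px, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position (px, ACL to GCL)",
                  y = if (isTRUE(attr(object, "normalized"))) {
                    "Normalized intensity"
                  } else {
                    "Intensity"
                  }) +
    ggplot2::theme_minimal()
  if (!is.null(b)) {
    p <- p + ggplot2::geom_vline(xintercept = b, linetype = "dashed",
                                 alpha = 0.5)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
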