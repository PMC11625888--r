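# Log-Gaussian spatial-frequency tuning curves and extra-sum-of-squares
# F-tests (omnibus and single-parameter nested comparisons).

#' Log-Gaussian tuning function
#'
#' The spatial-frequency tuning model
#' `A * exp(-(log10(f) - log10(p))^2 / (2 * sigma^2))`: a Gaussian in
#' log10-frequency with amplitude `A` (height of the peak), peak frequency
#' `p` (c/deg) and bandwidth `sigma` (standard deviation in log10-frequency
#' units). Base 10 is a package convention; changing the base only rescales
#' `sigma`.
#'
#' @param f Spatial frequency, c/deg (> 0; vectorized).
#' @param amplitude Peak height, response units.
#' @param peak_frequency Frequency of the peak, c/deg (> 0).
#' @param bandwidth Standard deviation, log10-frequency units (> 0).
#' @return Model response at `f`.
#' @examples
#' log_gaussian(0.062, amplitude = 1, peak_frequency = 0.062, bandwidth = 0.3)
#' @export
log_gaussian <- function(f, amplitude, peak_frequency, bandwidth) {
  if (any(f <= 0) || any(peak_frequency <= 0)) {
    abort("frequencies and peak_frequency must be positive",
          class = "zfeye_domain_error")
  }
  if (any(bandwidth <= 0)) {
    abort("bandwidth must be positive", class = "zfeye_domain_error")
  }
  amplitude * exp(-(log10(f) - log10(peak_frequency))^2 / (2 * bandwidth^2))
}

# Profiled RSS: given nonlinear parameters (lp = log10 peak, sigma), the
# least-squares amplitude has the closed form A = sum(y g) / sum(g^2)
# (clamped to its bounds), so the 3-parameter least-squares problem
# reduces to 2 nonlinear dimensions.
lg_gain_basis <- function(lf, lp, sigma) {
  exp(-(lf - lp)^2 / (2 * sigma^2))
}

lg_profiled <- function(lp, sigma, lf, y, a_lo, a_hi) {
  g <- lg_gain_basis(lf, lp, sigma)
  d <- sum(g * g)
  if (d == 0) return(list(amplitude = 0, rss = sum(y * y)))
  a <- sum(y * g) / d
  a <- min(max(a, a_lo), a_hi)
  list(amplitude = a, rss = sum((y - a * g)^2))
}

# Multi-start bounded fit over (lp, sigma) with profiled amplitude.
# extra_starts: optional matrix with columns (lp, sigma).
lg_fit_core <- function(lf, y, n_starts = 8, bounds = NULL,
                        extra_starts = NULL) {
  f_range <- range(10^lf)
  default_bounds <- list(
    amplitude = c(0, 10 * max(y, 0)),
    peak_frequency = f_range * c(1 / 4, 4),
    bandwidth = c(0.05, 2)
  )
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  b <- default_bounds
  lp_lo <- log10(b$peak_frequency[1]); lp_hi <- log10(b$peak_frequency[2])
  s_lo <- b$bandwidth[1]; s_hi <- b$bandwidth[2]

  starts <- cbind(seq(min(lf), max(lf), length.out = n_starts), 0.3)
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  starts[, 1] <- pmin(pmax(starts[, 1], lp_lo), lp_hi)
  starts[, 2] <- pmin(pmax(starts[, 2], s_lo), s_hi)

  obj <- function(par) {
    lg_profiled(par[1], par[2], lf, y, b$amplitude[1], b$amplitude[2])$rss
  }
  cand <- apply(starts, 1, function(p0) {
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(lp_lo, s_lo), upper = c(lp_hi, s_hi),
            control = list(factr = 1e2, maxit = 200,
                           ndeps = c(1e-7, 1e-7))),
      error = function(e) list(par = p0, value = obj(p0))
    )
    c(fit$par, fit$value)
  })
  cand <- t(cand)
  # ties among equally good starts broken by smallest sigma, then smallest
  # peak; deterministic given input order
  best_rss <- min(cand[, 3])
  ok <- cand[, 3] <= best_rss + 1e-12 + 1e-9 * abs(best_rss)
  pick <- which(ok)[order(cand[ok, 2], cand[ok, 1])][1]
  lp <- cand[pick, 1]; sigma <- cand[pick, 2]
  prof <- lg_profiled(lp, sigma, lf, y, b$amplitude[1], b$amplitude[2])
  list(amplitude = prof$amplitude, lp = lp, sigma = sigma,
       rss = prof$rss, bounds = b)
}

default_response <- function(data) {
  cand <- intersect(c("omi_normalized", "omi_mean", "omi"), names(data))
  if (length(cand) == 0) {
    abort("no response column found (expected omi_normalized, omi_mean or omi)",
          class = "zfeye_invalid_input")
  }
  cand[1]
}

#' Fit a three-parameter log-Gaussian tuning function
#'
#' Least-squares fit of [log_gaussian()] to (spatial frequency, response)
#' points. The amplitude enters the model linearly and is profiled out in
#' closed form, so the optimizer runs over (log10 peak, bandwidth) only —
#' numerically identical to the full 3-parameter least-squares problem.
#' Because the objective is multimodal in the peak, a multi-start over
#' log-spaced initial peaks is used, with bounded parameters.
#'
#' @param data Tibble with a `spatial_frequency` column and a response
#'   column (per-fish normalized OMIs, typically).
#' @param response Response column name; defaults to the first of
#'   `omi_normalized`, `omi_mean`, `omi` present.
#' @param n_starts Number of log-spaced initial peak frequencies.
#' @param bounds Optional named list overriding the default box
#'   constraints: `amplitude` in `[0, 10 max(y)]`, `peak_frequency` within
#'   the tested range times `[1/4, 4]`, `bandwidth` in `[0.05, 2]`.
#' @return An object of class `log_gaussian_fit` with [tidy()] and
#'   [glance()] methods: amplitude, peak frequency (c/deg), bandwidth
#'   (log10-frequency units), `rss`, `df` (= n - 3), `r_squared` and an
#'   identifiability flag (all-zero responses give amplitude 0 with
#'   meaningless location/width).
#' @examples
#' d <- tibble::tibble(
#'   spatial_frequency = rep(omr_frequencies(), 2),
#'   omi_normalized = log_gaussian(rep(omr_frequencies(), 2), 1, 0.062, 0.3)
#' )
#' fit_log_gaussian(d)
#' @export
fit_log_gaussian <- function(data, response = NULL, n_starts = 8,
                             bounds = NULL) {
  assert_columns(data, "spatial_frequency", "`data`")
  if (is.null(response)) response <- default_response(data)
  assert_columns(data, response, "`data`")
  f <- data$spatial_frequency
  y <- data[[response]]
  keep <- is.finite(f) & is.finite(y)
  f <- f[keep]; y <- y[keep]
  if (length(y) < 4) {
    abort("need at least 4 points to fit a 3-parameter tuning function",
          class = "zfeye_insufficient_data")
  }
  if (length(unique(f)) < 3) {
    abort("need at least 3 distinct spatial frequencies",
          class = "zfeye_degenerate_design")
  }
  if (any(f <= 0)) {
    abort("spatial frequencies must be positive", class = "zfeye_domain_error")
  }
  lf <- log10(f)
  n <- length(y)
  tss <- sum((y - mean(y))^2)

  if (all(y == 0)) {
    fit <- list(amplitude = 0, lp = mean(lf), sigma = 0.3, rss = 0,
                bounds = NULL)
    identifiable <- FALSE
  } else {
    fit <- lg_fit_core(lf, y, n_starts = n_starts, bounds = bounds)
    identifiable <- TRUE
  }
  structure(
    list(
      amplitude = fit$amplitude,
      peak_frequency = 10^fit$lp,
      bandwidth = fit$sigma,
      rss = fit$rss,
      n_points = n,
      df = n - 3L,
      r_squared = if (tss > 0) 1 - fit$rss / tss else NA_real_,
      identifiable = identifiable,
      response = response,
      log_base = 10,
      data = tibble::tibble(spatial_frequency = f, response = y)
    ),
    class = "log_gaussian_fit"
  )
}

#' @export
print.log_gaussian_fit <- function(x, ...) {
  cat("Log-Gaussian tuning fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  amplitude      %.4g\n", x$amplitude))
  cat(sprintf("  peak frequency %.4g c/deg\n", x$peak_frequency))
  cat(sprintf("  bandwidth      %.4g log10 units\n", x$bandwidth))
  cat(sprintf("  rss %.4g, df %d, r^2 %.3f\n", x$rss, x$df, x$r_squared))
  if (!x$identifiable) {
    cat("  note: flat response; peak and bandwidth are unidentifiable\n")
  }
  invisible(x)
}

#' @rdname fit_log_gaussian
#' @param object,x A `log_gaussian_fit`.
#' @param ... Unused.
#' @export
tidy.log_gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "peak_frequency", "bandwidth"),
    estimate = c(x$amplitude, x$peak_frequency, x$bandwidth)
  )
}

#' @rdname fit_log_gaussian
#' @export
glance.log_gaussian_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, r.squared = x$r_squared, df.residual = x$df,
    nobs = x$n_points, identifiable = x$identifiable
  )
}

#' @rdname fit_log_gaussian
#' @param newdata Optional tibble with a `spatial_frequency` column (or a
#'   numeric vector of frequencies).
#' @export
predict.log_gaussian_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) {
    object$data$spatial_frequency
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$spatial_frequency
  }
  log_gaussian(f, object$amplitude, object$peak_frequency, object$bandwidth)
}

# ---- group comparisons -----------------------------------------------------

lg_group_data <- function(data, response, collapse_fish) {
  if (collapse_fish) {
    assert_columns(data, c("fish_id", "group", "spatial_frequency"), "`data`")
    data <- data |>
      dplyr::group_by(.data$group, .data$spatial_frequency) |>
      dplyr::summarise(..y.. = mean(.data[[response]]), .groups = "drop")
    response <- "..y.."
  }
  split(
    tibble::tibble(lf = log10(data$spatial_frequency), y = data[[response]]),
    data$group
  )
}

extra_sum_of_squares_f <- function(rss_full, rss_restricted, k_full, k_restr, n) {
  df_num <- k_full - k_restr
  df_den <- n - k_full
  if (df_den < 1) {
    abort("not enough points for the residual degrees of freedom",
          class = "zfeye_insufficient_data")
  }
  if (rss_full == 0 && rss_restricted > 0) {
    return(list(f = Inf, p = 0, df_num = df_num, df_den = df_den))
  }
  # a perfect (or numerically perfect) shared fit explains the data as well
  # as the full model: the extra sum of squares is zero, not 0/0 noise
  if (rss_restricted - rss_full <= 1e-10 * max(1, rss_full)) {
    return(list(f = 0, p = 1, df_num = df_num, df_den = df_den))
  }
  f <- max(0, ((rss_restricted - rss_full) / df_num) / (rss_full / df_den))
  list(f = f, p = pf(f, df_num, df_den, lower.tail = FALSE),
       df_num = df_num, df_den = df_den)
}

new_tuning_comparison <- function(kind, stat, rss_full, rss_restricted,
                                  full_fits, restricted) {
  structure(
    list(
      comparison_kind = kind,
      f_statistic = stat$f,
      df_num = stat$df_num,
      df_den = stat$df_den,
      p_value = stat$p,
      rss_full = rss_full,
      rss_restricted = rss_restricted,
      full_fits = full_fits,
      restricted = restricted
    ),
    class = "tuning_comparison"
  )
}

#' @export
print.tuning_comparison <- function(x, ...) {
  cat("Tuning-curve model comparison (", x$comparison_kind, ")\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value))
  cat(sprintf("  RSS full %.6g, RSS restricted %.6g\n",
              x$rss_full, x$rss_restricted))
  invisible(x)
}

#' @rdname omnibus_f_test
#' @param x A `tuning_comparison`.
#' @export
tidy.tuning_comparison <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison_kind,
    f_statistic = x$f_statistic,
    df_num = x$df_num,
    df_den = x$df_den,
    p_value = x$p_value,
    rss_full = x$rss_full,
    rss_restricted = x$rss_restricted
  )
}

#' @rdname omnibus_f_test
#' @export
glance.tuning_comparison <- function(x, ...) tidy(x, ...)

#' Omnibus F-test: do tuning curves differ between groups at all?
#'
#' Compares a full model in which each group has its own three tuning
#' parameters against a restricted model with one shared parameter set
#' (a single log-Gaussian fit to the pooled data), via the extra sum of
#' squares:
#' `F = ((RSS_R - RSS_F) / (3G - 3)) / (RSS_F / (N - 3G))`,
#' referred to the F distribution with `(3G - 3, N - 3G)` degrees of
#' freedom. This is the residual-based equivalent of comparing goodness of
#' fit (r^2) between the two models on a common dataset. To guarantee the
#' nesting inequality `RSS_R >= RSS_F` numerically, the restricted solution
#' is added to each group's multi-start set.
#'
#' @param data Tibble with `group`, `spatial_frequency` and a response
#'   column (per-fish points by default).
#' @param response Response column; see [fit_log_gaussian()].
#' @param n_starts Multi-start count per fit.
#' @param collapse_fish If `TRUE`, fit group means over fish at each
#'   frequency instead of per-fish points.
#' @return A `tuning_comparison` object (F statistic, numerator/denominator
#'   df, p-value, both RSS, and the underlying fits) with [tidy()] /
#'   [glance()] methods.
#' @export
omnibus_f_test <- function(data, response = NULL, n_starts = 8,
                           collapse_fish = FALSE) {
  assert_columns(data, c("group", "spatial_frequency"), "`data`")
  if (is.null(response)) response <- default_response(data)
  gd <- lg_group_data(data, response, collapse_fish)
  if (length(gd) < 2) {
    abort("need at least 2 groups", class = "zfeye_invalid_input")
  }
  G <- length(gd)
  pooled <- dplyr::bind_rows(gd)
  n <- nrow(pooled)
  a_hi <- 10 * max(pooled$y, 0)
  bounds <- list(amplitude = c(0, a_hi))

  restricted <- lg_fit_core(pooled$lf, pooled$y, n_starts, bounds)
  full <- lapply(gd, function(d) {
    lg_fit_core(d$lf, d$y, n_starts, bounds,
                extra_starts = matrix(c(restricted$lp, restricted$sigma), 1))
  })
  rss_full <- sum(vapply(full, `[[`, numeric(1), "rss"))
  stat <- extra_sum_of_squares_f(rss_full, restricted$rss,
                                 k_full = 3 * G, k_restr = 3, n = n)
  new_tuning_comparison("omnibus", stat, rss_full, restricted$rss,
                        full, restricted)
}

# Joint restricted fit sharing one parameter across groups. Nonlinear
# parameters are optimized jointly; amplitudes are profiled per group
# (or jointly, when the shared parameter is the amplitude).
lg_restricted_fit <- function(gd, constrain, n_starts, a_hi,
                              start_sets = NULL) {
  G <- length(gd)
  lf_all <- lapply(gd, `[[`, "lf")
  y_all <- lapply(gd, `[[`, "y")
  lp_lo <- min(vapply(lf_all, min, 0)) + log10(1 / 4)
  lp_hi <- max(vapply(lf_all, max, 0)) + log10(4)
  s_lo <- 0.05; s_hi <- 2

  eval_rss <- switch(constrain,
    amplitude = function(par) {
      # par = (lp_1..G, sigma_1..G); single profiled shared amplitude
      cs <- 0; ds <- 0; s2 <- 0
      gs <- vector("list", G)
      for (g in seq_len(G)) {
        gg <- lg_gain_basis(lf_all[[g]], par[g], par[G + g])
        gs[[g]] <- gg
        cs <- cs + sum(y_all[[g]] * gg)
        ds <- ds + sum(gg * gg)
        s2 <- s2 + sum(y_all[[g]]^2)
      }
      if (ds == 0) return(s2)
      a <- min(max(cs / ds, 0), a_hi)
      s2 - 2 * a * cs + a^2 * ds
    },
    peak_frequency = function(par) {
      # par = (lp_shared, sigma_1..G); per-group profiled amplitude
      sum(vapply(seq_len(G), function(g) {
        lg_profiled(par[1], par[1 + g], lf_all[[g]], y_all[[g]], 0, a_hi)$rss
      }, numeric(1)))
    },
    bandwidth = function(par) {
      # par = (sigma_shared, lp_1..G)
      sum(vapply(seq_len(G), function(g) {
        lg_profiled(par[1 + g], par[1], lf_all[[g]], y_all[[g]], 0, a_hi)$rss
      }, numeric(1)))
    }
  )
  dims <- switch(constrain,
    amplitude = list(lower = c(rep(lp_lo, G), rep(s_lo, G)),
                     upper = c(rep(lp_hi, G), rep(s_hi, G))),
    peak_frequency = list(lower = c(lp_lo, rep(s_lo, G)),
                          upper = c(lp_hi, rep(s_hi, G))),
    bandwidth = list(lower = c(s_lo, rep(lp_lo, G)),
                     upper = c(s_hi, rep(lp_hi, G)))
  )
  if (is.null(start_sets)) start_sets <- list()
  # generic fallback starts over the frequency range
  mids <- seq(lp_lo + log10(4), lp_hi - log10(4), length.out = max(2, n_starts %/% 2))
  for (m in mids) {
    start_sets <- c(start_sets, list(switch(constrain,
      amplitude = c(rep(m, G), rep(0.3, G)),
      peak_frequency = c(m, rep(0.3, G)),
      bandwidth = c(0.3, rep(m, G))
    )))
  }
  best <- NULL
  for (p0 in start_sets) {
    p0 <- pmin(pmax(p0, dims$lower), dims$upper)
    fit <- tryCatch(
      optim(p0, eval_rss, method = "L-BFGS-B",
            lower = dims$lower, upper = dims$upper,
            control = list(factr = 1e2, maxit = 300,
                           ndeps = rep(1e-7, length(p0)))),
      error = function(e) list(par = p0, value = eval_rss(p0))
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  # recover full parameter sets per group from the optimum
  per_group <- switch(constrain,
    amplitude = {
      cs <- 0; ds <- 0
      gs <- lapply(seq_len(G), function(g) {
        lg_gain_basis(lf_all[[g]], par[g], par[G + g])
      })
      for (g in seq_len(G)) {
        cs <- cs + sum(y_all[[g]] * gs[[g]])
        ds <- ds + sum(gs[[g]]^2)
      }
      a <- if (ds > 0) min(max(cs / ds, 0), a_hi) else 0
      lapply(seq_len(G), function(g) {
        list(amplitude = a, lp = par[g], sigma = par[G + g])
      })
    },
    peak_frequency = lapply(seq_len(G), function(g) {
      pr <- lg_profiled(par[1], par[1 + g], lf_all[[g]], y_all[[g]], 0, a_hi)
      list(amplitude = pr$amplitude, lp = par[1], sigma = par[1 + g])
    }),
    bandwidth = lapply(seq_len(G), function(g) {
      pr <- lg_profiled(par[1 + g], par[1], lf_all[[g]], y_all[[g]], 0, a_hi)
      list(amplitude = pr$amplitude, lp = par[1 + g], sigma = par[1])
    })
  )
  names(per_group) <- names(gd)
  list(rss = best$value, par = par, per_group = per_group,
       constrain = constrain)
}

#' Nested F-test: does one named tuning parameter differ between groups?
#'
#' Compares the full model (independent three-parameter fits per group)
#' against a restricted model in which the named parameter — amplitude,
#' peak frequency or bandwidth — is constrained to a single shared value
#' across groups. The restricted model is a joint refit over all groups
#' (not a post-hoc constraint on the full-model estimates). With G groups
#' the restriction removes `G - 1` parameters, so
#' `F = ((RSS_R - RSS_F) / (G - 1)) / (RSS_F / (N - 3G))` with
#' `(G - 1, N - 3G)` degrees of freedom. The restricted solution is added
#' to the full-model start set so `RSS_R >= RSS_F` holds numerically.
#'
#' @inheritParams omnibus_f_test
#' @param constrain Which parameter the restricted model shares across
#'   groups: `"amplitude"`, `"peak_frequency"` or `"bandwidth"`.
#' @return A `tuning_comparison`; `comparison_kind` is
#'   `"nested:<parameter>"`.
#' @export
nested_f_test <- function(data,
                          constrain = c("amplitude", "peak_frequency",
                                        "bandwidth"),
                          response = NULL, n_starts = 8,
                          collapse_fish = FALSE) {
  constrain <- match.arg(constrain)
  assert_columns(data, c("group", "spatial_frequency"), "`data`")
  if (is.null(response)) response <- default_response(data)
  gd <- lg_group_data(data, response, collapse_fish)
  if (length(gd) < 2) {
    abort("need at least 2 groups", class = "zfeye_invalid_input")
  }
  G <- length(gd)
  n <- sum(vapply(gd, nrow, 0L))
  a_hi <- 10 * max(vapply(gd, function(d) max(d$y, 0), numeric(1)))
  bounds <- list(amplitude = c(0, a_hi))

  full <- lapply(gd, function(d) lg_fit_core(d$lf, d$y, n_starts, bounds))

  # seed the joint restricted fit from the full-model estimates
  full_lp <- vapply(full, `[[`, numeric(1), "lp")
  full_s <- vapply(full, `[[`, numeric(1), "sigma")
  shared_cands <- switch(constrain,
    amplitude = list(NULL),                  # amplitude is profiled anyway
    peak_frequency = as.list(unique(c(full_lp, mean(full_lp)))),
    bandwidth = as.list(unique(c(full_s, mean(full_s))))
  )
  start_sets <- lapply(shared_cands, function(sc) {
    switch(constrain,
      amplitude = c(full_lp, full_s),
      peak_frequency = c(sc, full_s),
      bandwidth = c(sc, full_lp)
    )
  })
  restricted <- lg_restricted_fit(gd, constrain, n_starts, a_hi, start_sets)

  # re-polish full fits from the restricted optimum to enforce nesting
  full <- purrr::map2(gd, restricted$per_group, function(d, pg) {
    lg_fit_core(d$lf, d$y, n_starts, bounds,
                extra_starts = matrix(c(pg$lp, pg$sigma), 1))
  })
  rss_full <- sum(vapply(full, `[[`, numeric(1), "rss"))
  stat <- extra_sum_of_squares_f(rss_full, restricted$rss,
                                 k_full = 3 * G, k_restr = 3 * G - (G - 1),
                                 n = n)
  new_tuning_comparison(paste0("nested:", constrain), stat, rss_full,
                        restricted$rss, full, restricted)
}
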