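# Independent oracles used to validate the package's optimizers and
# extractors. These deliberately avoid the code paths they check: fits are
# dense grid searches with direct RSS evaluation, interpolation is a
# hand-written piecewise-linear rule, and ERG features come from explicit
# windowed argmin/argmax indexing.

# Dense iteratively-refined 3-D grid search over (amplitude, log10 peak,
# bandwidth). RSS is evaluated exactly at every grid point; each round
# shrinks the search box around the incumbent.
oracle_fit_grid <- function(f, y, n_grid = 25, rounds = 9, shrink = 0.4) {
  lf <- log10(f)
  s_tot <- sum(y^2)
  full_a <- c(0, 10 * max(y))
  full_lp <- range(lf) + c(log10(1 / 4), log10(4))
  full_s <- c(0.05, 2)
  box_a <- full_a; box_lp <- full_lp; box_s <- full_s
  best <- list(rss = Inf)
  for (r in seq_len(rounds)) {
    a_g <- seq(box_a[1], box_a[2], length.out = n_grid)
    lp_g <- seq(box_lp[1], box_lp[2], length.out = n_grid)
    s_g <- seq(box_s[1], box_s[2], length.out = n_grid)
    combos <- expand.grid(lp = lp_g, s = s_g)
    dev <- outer(lf, combos$lp, "-")
    G <- exp(-sweep(dev^2, 2, 2 * combos$s^2, "/"))
    cv <- as.vector(crossprod(y, G))
    dv <- colSums(G^2)
    rss <- s_tot - 2 * outer(a_g, cv) + outer(a_g^2, dv)
    idx <- arrayInd(which.min(rss), dim(rss))
    cur <- list(
      amplitude = a_g[idx[1]],
      lp = combos$lp[idx[2]],
      sigma = combos$s[idx[2]],
      rss = rss[idx[1], idx[2]]
    )
    if (cur$rss < best$rss) best <- cur
    half <- function(box) diff(box) * shrink / 2
    clip <- function(ctr, h, full) {
      c(max(full[1], ctr - h), min(full[2], ctr + h))
    }
    box_a <- clip(best$amplitude, half(box_a), full_a)
    box_lp <- clip(best$lp, half(box_lp), full_lp)
    box_s <- clip(best$sigma, half(box_s), full_s)
  }
  best$peak_frequency <- 10^best$lp
  best
}

# Dense grid search over the 5-parameter restricted space of the
# amplitude-constrained two-group model: (shared A, lp1, s1, lp2, s2).
# For each (lp, s) pair per group the basis cross-products are
# precomputed, so RSS at every 5-D grid point is evaluated exactly.
oracle_restricted_amplitude_grid <- function(lf1, y1, lf2, y2,
                                             n_grid = 13, n_a = 17,
                                             rounds = 11, shrink = 0.45) {
  s_tot <- sum(y1^2) + sum(y2^2)
  lf_all <- c(lf1, lf2)
  full_lp <- range(lf_all) + c(log10(1 / 4), log10(4))
  full_s <- c(0.05, 2)
  full_a <- c(0, 10 * max(c(y1, y2)))
  box <- list(lp1 = full_lp, s1 = full_s, lp2 = full_lp, s2 = full_s,
              a = full_a)
  best <- list(rss = Inf)
  basis <- function(lf, y, lp_g, s_g) {
    combos <- expand.grid(lp = lp_g, s = s_g)
    dev <- outer(lf, combos$lp, "-")
    G <- exp(-sweep(dev^2, 2, 2 * combos$s^2, "/"))
    list(cv = as.vector(crossprod(y, G)), dv = colSums(G^2),
         combos = combos)
  }
  for (r in seq_len(rounds)) {
    lp1_g <- seq(box$lp1[1], box$lp1[2], length.out = n_grid)
    s1_g <- seq(box$s1[1], box$s1[2], length.out = n_grid)
    lp2_g <- seq(box$lp2[1], box$lp2[2], length.out = n_grid)
    s2_g <- seq(box$s2[1], box$s2[2], length.out = n_grid)
    a_g <- seq(box$a[1], box$a[2], length.out = n_a)
    b1 <- basis(lf1, y1, lp1_g, s1_g)
    b2 <- basis(lf2, y2, lp2_g, s2_g)
    cc <- outer(b1$cv, b2$cv, "+")
    dd <- outer(b1$dv, b2$dv, "+")
    rss_min <- matrix(Inf, nrow(cc), ncol(cc))
    a_best <- rss_min
    for (a in a_g) {
      rss_a <- s_tot - 2 * a * cc + a^2 * dd
      sel <- rss_a < rss_min
      a_best[sel] <- a
      rss_min[sel] <- rss_a[sel]
    }
    idx <- arrayInd(which.min(rss_min), dim(rss_min))
    cur <- list(
      lp1 = b1$combos$lp[idx[1]], s1 = b1$combos$s[idx[1]],
      lp2 = b2$combos$lp[idx[2]], s2 = b2$combos$s[idx[2]],
      a = a_best[idx[1], idx[2]], rss = rss_min[idx[1], idx[2]]
    )
    if (cur$rss < best$rss) best <- cur
    half <- function(b) diff(b) * shrink / 2
    clip <- function(ctr, h, full) {
      c(max(full[1], ctr - h), min(full[2], ctr + h))
    }
    box <- list(
      lp1 = clip(best$lp1, half(box$lp1), full_lp),
      s1 = clip(best$s1, half(box$s1), full_s),
      lp2 = clip(best$lp2, half(box$lp2), full_lp),
      s2 = clip(best$s2, half(box$s2), full_s),
      a = clip(best$a, half(box$a), full_a)
    )
  }
  best
}

# Brute-force windowed argmin/argmax ERG feature oracle: explicit index
# arithmetic over the same windows and definitions.
oracle_erg_features <- function(time_ms, v, onset, a_window = c(3, 100),
                                b_window_end = 300, baseline_window = 50,
                                floor_uv = NULL) {
  base <- v[time_ms >= onset - baseline_window & time_ms < onset]
  baseline <- sum(base) / length(base)
  if (is.null(floor_uv)) floor_uv <- 3 * stats::sd(base)
  if (!is.finite(floor_uv)) floor_uv <- 0
  ia <- which(time_ms >= onset + a_window[1] & time_ms <= onset + a_window[2])
  trough <- ia[1]
  for (i in ia) if (v[i] < v[trough]) trough <- i
  if (baseline - v[trough] > floor_uv) {
    a_amp <- baseline - v[trough]
    a_time <- time_ms[trough] - onset
    ib <- which(time_ms > time_ms[trough] & time_ms <= onset + b_window_end)
    ref <- v[trough]
  } else {
    a_amp <- 0
    a_time <- NA_real_
    ib <- which(time_ms >= onset + a_window[1] &
                  time_ms <= onset + b_window_end)
    ref <- baseline
  }
  peak <- ib[1]
  for (i in ib) if (v[i] > v[peak]) peak <- i
  if (v[peak] - ref > floor_uv) {
    b_amp <- v[peak] - ref
    b_time <- time_ms[peak] - onset
  } else {
    b_amp <- 0
    b_time <- NA_real_
  }
  list(baseline = baseline, a_amplitude = a_amp, b_amplitude = b_amp,
       a_implicit_time = a_time, b_implicit_time = b_time)
}

# Hand-written piecewise-linear interpolation with flat extrapolation.
oracle_linear_interp <- function(x, y, xq) {
  vapply(xq, function(q) {
    if (q <= x[1]) return(y[1])
    n <- length(x)
    if (q >= x[n]) return(y[n])
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# Two-group cohort -> normalized tuning dataset, the standard analysis path.
make_tuning_dataset <- function(amp2 = 1, seed = 1, n_fish = 14,
                                noise_sd_omi = 0.1) {
  groups <- tibble::tibble(
    group = c("wt", "mut"),
    amplitude = c(1, amp2),
    peak_frequency = 0.0620,
    bandwidth = 0.3
  )
  sim_omr_cohort(groups, n_fish_per_group = n_fish, seed = seed,
                 noise_sd_omi = noise_sd_omi, return = "omi") |>
    average_trials() |>
    normalize_omi("wt", 0.0620)
}

# Wrap a plain intensity vector into a layer profile via the public API.
as_unit_profile <- function(v) {
  extract_profile(matrix(rep(v, each = 4), nrow = 4), roi_height_px = 4)
}

new_unit_profile <- function(n) {
  normalize_profile(as_unit_profile(rep(1, n)))
}
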