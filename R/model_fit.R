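#' Maximum time-lagged Pearson correlation between two series
#'
#' Pearson correlation between `a` and `b` over a fixed window of `a`, at
#' every integer-sample lag within `±max_lag` (positive lag: `b` lags `a`).
#' Returns the maximum and the lag at which it occurs; ties are broken toward
#' zero lag.
#'
#' @param a,b Tibbles with columns `time`, `value` on a shared uniform grid
#'   (e.g. [erp()] output for one channel), or plain numeric vectors (then
#'   `rate` and `t0` describe the grid).
#' @param max_lag Maximum lag magnitude in seconds (default 0.2).
#' @param window Length-2 correlation window in seconds, applied to `a`
#'   (default `c(0, 1)`).
#' @param rate,t0 Grid description when `a`, `b` are bare vectors.
#' @return One-row tibble with `r_max`, `lag` (s), `n` (samples correlated).
#' @export
lagged_correlation <- function(a, b, max_lag = 0.2, window = c(0, 1),
                               rate = NULL, t0 = NULL) {
  if (is.data.frame(a)) {
    rate <- 1 / stats::median(diff(a$time)); t0 <- a$time[1]
    av <- a$value; bv <- b$value
  } else {
    stopifnot(!is.null(rate), !is.null(t0))
    av <- a; bv <- b
  }
  if (length(av) != length(bv)) stop("series must share the time grid",
                                     call. = FALSE)
  tt <- t0 + (seq_along(av) - 1) / rate
  idx <- which(tt >= window[1] & tt <= window[2])
  max_k <- as.integer(round(max_lag * rate))
  lags <- -max_k:max_k
  r <- vapply(lags, function(k) {
    ib <- idx + k
    ok <- ib >= 1 & ib <= length(bv)
    xa <- av[idx[ok]]; xb <- bv[ib[ok]]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      stop("constant series in window: correlation undefined", call. = FALSE)
    }
    stats::cor(xa, xb)
  }, numeric(1))
  best <- which(r == max(r))
  best <- best[which.min(abs(lags[best]))]   # ties toward zero lag
  tibble::tibble(r_max = r[best], lag = lags[best] / rate, n = length(idx))
}

#' Fit the square-root timing law t = k * sqrt(T) + c
#'
#' Ordinary least squares of observed event times against the square root of
#' the oscillation period, the scaling the Firefly model posits for both
#' synchronization and desynchronization latencies.
#'
#' @param periods Oscillation periods `T` in seconds (>= 3 values, positive).
#' @param times Observed times in seconds, same length.
#' @return One-row tibble with `k`, `c`, `r_squared`, `rmse`.
#' @examples
#' fit_sqrt_law(c(0.01, 0.04, 0.16), 0.5 * sqrt(c(0.01, 0.04, 0.16)))
#' @export
fit_sqrt_law <- function(periods, times) {
  stopifnot(length(periods) == length(times), length(periods) >= 3,
            all(periods > 0))
  s <- sqrt(periods)
  if (stats::sd(s) < 1e-12) stop("degenerate design: periods collinear",
                                 call. = FALSE)
  fit <- stats::lm(times ~ s)
  res <- stats::residuals(fit)
  tss <- sum((times - mean(times))^2)
  tibble::tibble(
    k = unname(stats::coef(fit)[2]),
    c = unname(stats::coef(fit)[1]),
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    rmse = sqrt(mean(res^2))
  )
}

#' Systematic search for the target phase
#'
#' Finds the target phase `phi_target` whose simulated ERP best matches a
#' reference ERP, by zero-lag Pearson correlation on a degree grid spanning
#' -180..+180. The simulation seed is fixed across grid points so the
#' correlation profile is smooth; ties are broken toward the smallest
#' absolute phase. Because the target phase enters every oscillation as a
#' common additive constant, the simulated ERP at any phase is exactly
#' `cos(phi) * ERP(0) + sin(phi) * ERP(90)`, so two simulations suffice to
#' evaluate the whole grid without approximation.
#'
#' @param reference_erp Tibble with columns `time`, `value` (a single-channel
#'   ERP on the epoch grid) or numeric vector of length `sampling$n_samples`.
#' @param cfg A [firefly_config()]; its `rng_seed` fixes the simulation.
#' @param w Optional `spectrum_weights` (default synthetic spectrum).
#' @param sampling A [sampling_spec()].
#' @param grid_step Grid resolution in degrees (default 1).
#' @param window Correlation window in seconds (default `c(0, 1)`).
#' @param baseline,lowpass ERP pipeline applied to both the reference and the
#'   simulated trial means before correlating (defaults match [erp()]:
#'   baseline `c(-0.2, 0)`, 20 Hz zero-phase low-pass). The low-pass
#'   suppresses high-frequency Monte-Carlo noise that would otherwise blur
#'   the correlation peak. Set `lowpass = NULL` to correlate raw averages.
#' @return List with `phi_target` (radians), `phi_target_deg`, `r_max`, and
#'   `profile` (tibble `phi_deg`, `r`).
#' @export
search_target_phase <- function(reference_erp, cfg, w = NULL,
                                sampling = sampling_spec(500, -2, 2),
                                grid_step = 1, window = c(0, 1),
                                baseline = c(-0.2, 0), lowpass = 20) {
  ref <- if (is.data.frame(reference_erp)) reference_erp$value else reference_erp
  if (length(ref) != sampling$n_samples) {
    stop("reference ERP is not on the epoch grid", call. = FALSE)
  }
  if (stats::sd(ref) == 0) stop("constant reference: correlation undefined",
                                call. = FALSE)
  pipeline <- function(x) {
    x <- x - mean(x[window_mask(sampling, baseline[1], baseline[2])])
    if (!is.null(lowpass)) x <- zero_phase_fir(x, sampling$rate, f_hi = lowpass)
    x
  }
  base_cfg <- cfg
  erp_basis <- lapply(c(0, pi / 2), function(p) {
    base_cfg$phi_target <- p
    sim <- simulate_firefly(base_cfg, w = w, sampling = sampling,
                            channels = "ref")
    pipeline(rowMeans(epoch_matrix(sim, "ref")))
  })
  mask <- window_mask(sampling, window[1], window[2])
  refw <- pipeline(ref)[mask]
  e0 <- erp_basis[[1]][mask]; e90 <- erp_basis[[2]][mask]
  phi_deg <- seq(-180, 180 - grid_step, by = grid_step)
  r <- vapply(phi_deg, function(pd) {
    p <- pd * pi / 180
    stats::cor(refw, cos(p) * e0 + sin(p) * e90)
  }, numeric(1))
  best <- which(r == max(r))
  best <- best[which.min(abs(phi_deg[best]))]
  list(phi_target = phi_deg[best] * pi / 180,
       phi_target_deg = phi_deg[best],
       r_max = r[best],
       profile = tibble::tibble(phi_deg = phi_deg, r = r))
}

#' Estimate synchronization timing from phase-locking curves
#'
#' For each ordinal IMF: `t_synch` is the time at which the trial-aggregate
#' phase-locking value reaches its post-onset maximum; the phase-locked
#' interval is the contiguous run of samples around that maximum with PLV
#' within 5% of it, and `t_desynch` is the end of that run. The IMF's period
#' is the reciprocal of its baseline mean frequency.
#'
#' @param summary An `imf_summary` from [summarize_imfs()].
#' @param t_start Onset of the modulated window in seconds (default 0.08);
#'   the PLV maximum is searched after this time.
#' @param search_end Latest time searched (default 0.3 s before the epoch end,
#'   clear of the Hilbert edge guard).
#' @param min_plv Threshold for a *clear* phase-locking peak (default 0.3,
#'   comfortably above both the uniform-phase noise floor and typical
#'   baseline maxima). Timing estimates are only meaningful for IMFs whose
#'   PLV actually peaks; the `clear` column flags them and square-root-law
#'   fits should use those rows.
#' @return Tibble with columns `imf`, `period` (s), `t_synch` (s),
#'   `t_desynch` (s), `plv_max`, `clear`. A warning is raised when a maximum
#'   sits at the search boundary.
#' @export
estimate_tsynch_from_plv <- function(summary, t_start = 0.08,
                                     search_end = NULL, min_plv = 0.3) {
  sp <- summary$sampling
  if (is.null(search_end)) search_end <- sp$epoch_end - 0.3
  out <- list()
  for (k in sort(unique(summary$timecourse$imf))) {
    d <- summary$timecourse[summary$timecourse$imf == k, , drop = FALSE]
    sel <- d$time >= t_start & d$time <= search_end
    pv <- d$plv[sel]; tv <- d$time[sel]
    i_max <- which.max(pv)
    boundary <- i_max == 1L || i_max == length(pv)
    if (boundary) {
      warning(sprintf("IMF %d: PLV maximum at the search boundary", k),
              call. = FALSE)
    }
    thr <- 0.95 * pv[i_max]
    j <- i_max
    while (j < length(pv) && pv[j + 1] >= thr) j <- j + 1
    bl <- summary$baseline[summary$baseline$imf == k, ]
    out[[length(out) + 1L]] <- tibble::tibble(
      imf = k, period = 1 / bl$freq_mean,
      t_synch = tv[i_max], t_desynch = tv[j], plv_max = pv[i_max],
      clear = pv[i_max] >= min_plv && !boundary)
  }
  dplyr::bind_rows(out)
}
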