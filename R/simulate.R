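#' Configuration of the Firefly phase-alignment simulator
#'
#' The Firefly model generates event-related EEG as the amplitude-weighted sum
#' of ongoing sinusoidal oscillations, one per frequency on a dense grid, whose
#' phases transiently align to a per-channel target oscillation. Each
#' oscillation passes through five stages: baseline (random phase), a linear
#' slowing that accumulates the phase shift needed to reach the target by
#' `t_synch`, a phase-locked stage until `t_desynch`, a linear rebound that
#' restores the baseline phase by `t_end`, and baseline again. The stage
#' boundaries scale with the square root of the oscillation period `T`:
#' `t_synch = t_start + k_synch * sqrt(T)` and
#' `t_desynch = t_start + k_desynch * sqrt(T) + c_desynch`, so high frequencies
#' align early and low frequencies late, which is what gives the trial average
#' its down-chirp ERP shape.
#'
#' `k_synch`, `k_desynch` and `c_desynch` are calibration parameters: defaults
#' place the synchronization times near the phase-locking peak latencies seen
#' in empirical-mode analyses of event-related EEG.
#'
#' @param f_min,f_max,f_step Frequency grid in Hz (defaults 0.1, 250, 0.1).
#'   Frequencies at or above the sampling Nyquist are dropped at simulation
#'   time with a warning.
#' @param t_start Onset of the event-related phase modulation, seconds
#'   post-stimulus (default 0.08: cortical response latency).
#' @param k_synch Coefficient (s^0.5) of the synchronization-time law
#'   `t_synch - t_start = k_synch * sqrt(T)`.
#' @param k_desynch,c_desynch Coefficient (s^0.5) and offset (s) of the
#'   desynchronization-time law `t_desynch - t_start = k_desynch*sqrt(T) + c_desynch`.
#' @param t_end_offset Seconds between `t_desynch` and `t_end` (default 1.5).
#' @param phi_target Target phase(s) in radians, one per channel (recycled).
#'   The target oscillation of each channel is `cos(2*pi*f*(t - t_start) + phi_target)`,
#'   anchored at stimulus-modulation onset for every frequency.
#' @param responding_fraction Fraction in `[0, 1]` of grid oscillators that
#'   respond to the stimulus (default 0.5): a fixed, evenly interleaved
#'   subset is phase-modulated on every trial, the rest always keep their
#'   baseline trajectory. Every oscillator keeps its full amplitude
#'   throughout, so signal power is unchanged for any value.
#' @param n_trials Trials per simulated set (default 100).
#' @param rng_seed Integer seed for the per-trial, per-frequency phase draws;
#'   `NULL` uses the current RNG stream.
#' @return An object of class `firefly_config` (a named list).
#' @seealso [simulate_firefly()], [synthetic_spectrum()], [stage_times()]
#' @export
firefly_config <- function(f_min = 0.1, f_max = 250, f_step = 0.1,
                           t_start = 0.08,
                           k_synch = 0.5, k_desynch = 0.9, c_desynch = 0.05,
                           t_end_offset = 1.5,
                           phi_target = 0,
                           responding_fraction = 0.5,
                           n_trials = 100,
                           rng_seed = NULL) {
  stopifnot(f_min > 0, f_min < f_max, f_step > 0, t_start >= 0,
            k_synch > 0, k_desynch > 0, c_desynch >= 0, t_end_offset > 0,
            responding_fraction >= 0, responding_fraction <= 1,
            n_trials >= 1)
  structure(
    list(f_min = f_min, f_max = f_max, f_step = f_step, t_start = t_start,
         k_synch = k_synch, k_desynch = k_desynch, c_desynch = c_desynch,
         t_end_offset = t_end_offset, phi_target = phi_target,
         responding_fraction = responding_fraction,
         n_trials = as.integer(n_trials), rng_seed = rng_seed),
    class = "firefly_config"
  )
}

#' Frequency grid of a configuration, restricted to below Nyquist
#'
#' @param cfg A [firefly_config()].
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of frequencies; errors if empty after exclusion.
#' @export
frequency_grid <- function(cfg, rate) {
  f <- seq(cfg$f_min, cfg$f_max, by = cfg$f_step)
  keep <- f < rate / 2
  if (!all(keep)) {
    warning(sprintf("dropping %d grid frequencies at or above Nyquist (%g Hz)",
                    sum(!keep), rate / 2), call. = FALSE)
  }
  f <- f[keep]
  if (length(f) == 0L) {
    stop("frequency grid is empty after Nyquist exclusion", call. = FALSE)
  }
  f
}

#' Square-root timing laws for synchronization and desynchronization
#'
#' Time (relative to the modulation onset `t_start`) at which an oscillation of
#' a given period reaches the target phase (`synch_time`) or starts returning
#' to baseline (`desynch_time`). Both grow with the square root of the period,
#' so quadrupling the period doubles the synchronization delay.
#'
#' @param period Oscillation period `T` in seconds (positive; vectorized).
#' @param cfg A [firefly_config()].
#' @return Time offset from `t_start`, in seconds.
#' @examples
#' synch_time(0.04, firefly_config(k_synch = 0.5)) # 0.1 s
#' @export
synch_time <- function(period, cfg) {
  stopifnot(all(period >= 0))
  cfg$k_synch * sqrt(period)
}

#' @rdname synch_time
#' @export
desynch_time <- function(period, cfg) {
  stopifnot(all(period >= 0))
  cfg$k_desynch * sqrt(period) + cfg$c_desynch
}

#' Absolute stage boundaries per frequency
#'
#' @param cfg A [firefly_config()].
#' @param frequency Frequencies in Hz.
#' @return Tibble with columns `frequency`, `t_synch`, `t_desynch`, `t_end`
#'   (seconds post-stimulus). Errors if the stage ordering
#'   `t_start < t_synch < t_desynch < t_end` is violated anywhere.
#' @export
stage_times <- function(cfg, frequency) {
  period <- 1 / frequency
  ts <- cfg$t_start + synch_time(period, cfg)
  td <- cfg$t_start + desynch_time(period, cfg)
  te <- td + cfg$t_end_offset
  if (any(!(cfg$t_start < ts & ts < td & td < te))) {
    stop("configuration violates t_start < t_synch < t_desynch < t_end",
         call. = FALSE)
  }
  tibble::tibble(frequency = frequency, t_synch = ts, t_desynch = td, t_end = te)
}

#' Phase trajectory of a single Firefly oscillation
#'
#' Defines the piecewise phase schedule of one oscillation with preferred
#' frequency `f0` whose baseline phase is offset from the channel's target
#' oscillation by `delta_phi` at `t_start`. The offset is mapped to the
#' backward shift `delta_phi_prime = delta_phi mod 2*pi` in `[0, 2*pi)`, so
#' alignment is always achieved by slowing (a non-positive linear phase ramp),
#' never by speeding up.
#'
#' @param f0 Preferred frequency in Hz.
#' @param delta_phi Baseline phase offset from the target oscillation at
#'   `t_start`, radians (any real; drawn uniform on `(-pi, pi]` in simulation).
#' @param cfg A [firefly_config()].
#' @param phi_target Target phase in radians (default first element of
#'   `cfg$phi_target`).
#' @return An object of class `phase_trajectory` with the stage boundaries and
#'   phase parameters.
#' @seealso [phase_at()], [inst_frequency_model()]
#' @export
phase_trajectory <- function(f0, delta_phi, cfg, phi_target = cfg$phi_target[1]) {
  stopifnot(f0 > 0)
  st <- stage_times(cfg, f0)
  structure(
    list(f0 = f0, delta_phi = delta_phi,
         delta_phi_prime = delta_phi %% (2 * pi),
         t_start = cfg$t_start, t_synch = st$t_synch,
         t_desynch = st$t_desynch, t_end = st$t_end,
         phi_target = phi_target),
    class = "phase_trajectory"
  )
}

# Unitless modulation schedule s(t): 0 at baseline, ramps 0 -> 1 over
# [t_start, t_synch], 1 while phase-locked, ramps back to 0 over
# [t_desynch, t_end]. The accumulated phase shift is -delta_phi_prime * s(t).
modulation_schedule <- function(t, t_start, t_synch, t_desynch, t_end) {
  clamp01((t - t_start) / (t_synch - t_start)) -
    clamp01((t - t_desynch) / (t_end - t_desynch))
}

#' Phase of a Firefly oscillation at time t
#'
#' Piecewise phase function: baseline `2*pi*f0*(t - t_start) + phi_target +
#' delta_phi` outside the modulated window; during synchronization a linear
#' ramp accumulates exactly `-delta_phi_prime` by `t_synch`; while phase-locked
#' the phase equals the target oscillation's phase (mod 2*pi); during
#' desynchronization the ramp reverses, restoring the baseline offset by
#' `t_end`. Continuous at every stage boundary.
#'
#' @param traj A [phase_trajectory()].
#' @param t Time(s) in seconds post-stimulus (vectorized).
#' @return Phase in radians (unwrapped, continuous).
#' @export
phase_at <- function(traj, t) {
  s <- modulation_schedule(t, traj$t_start, traj$t_synch, traj$t_desynch, traj$t_end)
  2 * pi * traj$f0 * (t - traj$t_start) + traj$phi_target + traj$delta_phi -
    traj$delta_phi_prime * s
}

#' Instantaneous frequency of a Firefly oscillation at time t
#'
#' The analytic derivative `(1/2*pi) * d(phase)/dt` of [phase_at()]: `f0` in
#' the baseline and phase-locked stages, `f0 - delta_phi_prime /
#' (2*pi*(t_synch - t_start))` during synchronization (slowing), and `f0 +
#' delta_phi_prime / (2*pi*(t_end - t_desynch))` during desynchronization
#' (rebound). At a stage boundary the right-sided value is returned.
#'
#' @inheritParams phase_at
#' @return Frequency in Hz.
#' @export
inst_frequency_model <- function(traj, t) {
  f <- rep(traj$f0, length(t))
  in_synch <- t >= traj$t_start & t < traj$t_synch
  in_desynch <- t >= traj$t_desynch & t < traj$t_end
  f[in_synch] <- traj$f0 -
    traj$delta_phi_prime / (2 * pi * (traj$t_synch - traj$t_start))
  f[in_desynch] <- traj$f0 +
    traj$delta_phi_prime / (2 * pi * (traj$t_end - traj$t_desynch))
  f
}

#' Synthetic baseline amplitude spectrum: 1/f power law plus an alpha peak
#'
#' Amplitude weights for the canonical resting EEG spectrum, whose *power* is
#' approximately proportional to `1/f` apart from the alpha peak; amplitude
#' weights therefore go as `f^(-1/2)`, with a Gaussian alpha bump whose height
#' at the peak is `alpha_gain` times the aperiodic floor there. Weights are
#' normalized to unit total power (`sum(weight^2) = 1`). With
#' `alpha_gain = 1` the spectrum is the pure aperiodic power law.
#'
#' @param grid Frequency grid in Hz (e.g. `frequency_grid(cfg, rate)`).
#' @param alpha_peak_hz Alpha peak frequency (default 10 Hz); must lie within
#'   the grid range.
#' @param alpha_gain Peak-to-floor amplitude ratio at the peak (>= 1). The
#'   default 5 gives the alpha band the clear power dominance over theta that
#'   characterizes pre-stimulus posterior EEG under fixation; a prominent
#'   alpha peak is the spectral precondition for the theta-inflow mechanism
#'   by which alpha-range oscillations slowing through the theta band produce
#'   event-related theta synchronization.
#' @param alpha_width_hz Gaussian standard deviation of the bump (default 1 Hz).
#' @return A tibble of class `spectrum_weights` with columns `frequency`,
#'   `weight`.
#' @export
synthetic_spectrum <- function(grid, alpha_peak_hz = 10, alpha_gain = 5,
                               alpha_width_hz = 1) {
  stopifnot(alpha_gain >= 1, alpha_width_hz > 0,
            alpha_peak_hz >= min(grid), alpha_peak_hz <= max(grid))
  a <- 1 / sqrt(grid) +
    (alpha_gain - 1) / sqrt(alpha_peak_hz) *
      exp(-(grid - alpha_peak_hz)^2 / (2 * alpha_width_hz^2))
  a <- a / sqrt(sum(a^2))
  structure(tibble::tibble(frequency = grid, weight = a),
            class = c("spectrum_weights", class(tibble::tibble())))
}

#' Amplitude weights from a baseline power spectral density
#'
#' Interpolates the square root of a [welch_psd()] estimate (amplitude is the
#' square root of power) onto a simulation frequency grid and normalizes to
#' unit total power.
#'
#' @param psd A `psd_estimate` tibble (columns `channel`, `frequency`,
#'   `power`); if several channels are present they are averaged.
#' @param grid Target frequency grid in Hz.
#' @return A `spectrum_weights` tibble.
#' @export
spectrum_from_psd <- function(psd, grid) {
  avg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(psd), frequency),
                          power = mean(power), .groups = "drop")
  amp <- stats::approx(avg$frequency, sqrt(pmax(avg$power, 0)), xout = grid,
                       rule = 2)$y
  amp <- amp / sqrt(sum(amp^2))
  structure(tibble::tibble(frequency = grid, weight = amp),
            class = c("spectrum_weights", class(tibble::tibble())))
}

# Check that a weight table matches the grid exactly.
check_weights <- function(w, grid) {
  stopifnot(is.data.frame(w), all(c("frequency", "weight") %in% names(w)))
  if (nrow(w) != length(grid) || max(abs(w$frequency - grid)) > 1e-9) {
    stop("spectrum weights must be defined on exactly the simulation grid",
         call. = FALSE)
  }
  if (any(w$weight < 0) || all(w$weight == 0)) {
    stop("spectrum weights must be non-negative with at least one positive",
         call. = FALSE)
  }
  w$weight
}

# Core trial synthesis. Returns a list of channel matrices
# (n_samples x n_trials). `modulated = FALSE` freezes every oscillation on its
# baseline trajectory (used by the evoked background).
#
# responding_fraction r selects a fixed, evenly interleaved subset holding a
# fraction r of the grid oscillators; those undergo phase modulation on every
# trial, the rest always keep their baseline trajectory. Every oscillator
# keeps its full amplitude a_f at all times, so the model's no-power-change
# assumption holds exactly per oscillator. (Splitting each amplitude into a
# modulated and a stationary part instead lets the two halves decohere during
# the response, silently cutting mean-square power to r^2 + (1-r)^2 of
# baseline; re-drawing the subset per trial adds composition noise that
# obscures the across-trial phase coherence the subset is meant to carry.)
#
# delta_phi draws and the responding subset are shared across channels within
# a trial; channels differ only in phi_target. The channel sum is assembled
# from quadrature components:
# V_ch(t) = cos(phi_ch) * C(t) - sin(phi_ch) * S(t) with
# C = sum_f a_f cos(theta_f(t)), S = sum_f a_f sin(theta_f(t)), where theta is
# the phase at phi_target = 0. This is exact, not an approximation.
synthesize_trials <- function(cfg, weight, f, sampling, modulated = TRUE) {
  tt <- time_points(sampling)
  n <- sampling$n_samples
  phi_ch <- cfg$phi_target
  r <- if (modulated) cfg$responding_fraction else 0
  st <- stage_times(cfg, f)
  base <- 2 * pi * outer(f, tt - cfg$t_start) # F x T baseline phase, phi=0
  out <- lapply(phi_ch, function(p) matrix(0, n, cfg$n_trials))
  dphi_prime_sched <- if (r > 0) {
    # schedule s(t) per frequency row; trial-independent
    Tm <- matrix(tt, length(f), n, byrow = TRUE)
    clamp01((Tm - cfg$t_start) / (st$t_synch - cfg$t_start)) -
      clamp01((Tm - st$t_desynch) / (cfg$t_end_offset))
  } else NULL
  # evenly interleaved responding subset, identical on every trial
  i <- seq_along(f)
  responds <- floor(i * r) > floor((i - 1) * r)
  for (tr in seq_len(cfg$n_trials)) {
    dphi <- stats::runif(length(f), -pi, pi)
    theta <- base + dphi
    if (r > 0) {
      dpp <- ifelse(responds, dphi %% (2 * pi), 0)
      theta <- theta - dpp * dphi_prime_sched
    }
    Cc <- colSums(weight * cos(theta))
    Ss <- colSums(weight * sin(theta))
    for (k in seq_along(phi_ch)) {
      out[[k]][, tr] <- cos(phi_ch[k]) * Cc - sin(phi_ch[k]) * Ss
    }
  }
  out
}

#' Simulate event-related EEG trials under the Firefly model
#'
#' Each trial is `V(t) = sum_f a_f * cos(phi_f(t))` over the configuration's
#' frequency grid, with an independent phase offset `delta_phi_f` drawn uniform
#' on `(-pi, pi]` per frequency per trial. A fixed interleaved subset of
#' oscillators (fraction `responding_fraction` of the grid) follows the
#' phase-aligning trajectory ([phase_at()]); the rest keep their baseline
#' trajectory. Trials are reproducible given `cfg$rng_seed`.
#'
#' @param cfg A [firefly_config()].
#' @param w A `spectrum_weights` tibble on exactly
#'   `frequency_grid(cfg, sampling$rate)`; `NULL` (default) uses
#'   [synthetic_spectrum()] with its defaults.
#' @param sampling A [sampling_spec()]; default 500 Hz, -2..+2 s.
#' @param channels Channel names, one per element of `cfg$phi_target`.
#' @param condition Condition label applied to every trial (default
#'   `"firefly"`).
#' @return An [epoch_set()] with `cfg$n_trials` trials per channel.
#' @examples
#' cfg <- firefly_config(f_max = 40, f_step = 0.5, n_trials = 4, rng_seed = 1)
#' e <- simulate_firefly(cfg, sampling = sampling_spec(250, -1, 1))
#' @export
simulate_firefly <- function(cfg, w = NULL, sampling = sampling_spec(500, -2, 2),
                             channels = paste0("ch", seq_along(cfg$phi_target)),
                             condition = "firefly") {
  stopifnot(inherits(cfg, "firefly_config"), inherits(sampling, "sampling_spec"))
  f <- frequency_grid(cfg, sampling$rate)
  if (is.null(w)) w <- synthetic_spectrum(f)
  a <- check_weights(w, f)
  mats <- with_seed(cfg$rng_seed,
                    synthesize_trials(cfg, a, f, sampling, modulated = TRUE))
  names(mats) <- rep_len(channels, length(mats))
  epoch_set(mats, sampling, conditions = condition)
}

#' Simulate trials under the competing evoked (additive) model
#'
#' Background trials are generated exactly as in [simulate_firefly()] but with
#' the phase modulation disabled (every oscillation keeps its random baseline
#' trajectory), and a fixed stimulus-locked template is added to every trial.
#' Averaging across trials recovers the template as the background cancels.
#'
#' @inheritParams simulate_firefly
#' @param template The evoked waveform added to each trial: a numeric vector of
#'   length `sampling$n_samples` (applied to every channel) or a tibble with
#'   columns `channel`, `time`, `value` aligned to the epoch grid.
#' @param condition Condition label (default `"evoked"`).
#' @return An [epoch_set()].
#' @export
simulate_evoked <- function(cfg, w = NULL, template,
                            sampling = sampling_spec(500, -2, 2),
                            channels = paste0("ch", seq_along(cfg$phi_target)),
                            condition = "evoked") {
  stopifnot(inherits(cfg, "firefly_config"), inherits(sampling, "sampling_spec"))
  f <- frequency_grid(cfg, sampling$rate)
  if (is.null(w)) w <- synthetic_spectrum(f)
  a <- check_weights(w, f)
  channels <- rep_len(channels, length(cfg$phi_target))
  if (is.data.frame(template)) {
    tmpl <- lapply(channels, function(ch) {
      v <- template$value[template$channel == ch]
      if (length(v) != sampling$n_samples) {
        stop("template length does not match the epoch grid for channel ", ch,
             call. = FALSE)
      }
      v
    })
  } else {
    if (length(template) != sampling$n_samples) {
      stop("template length does not match the epoch grid", call. = FALSE)
    }
    tmpl <- rep(list(as.numeric(template)), length(channels))
  }
  mats <- with_seed(cfg$rng_seed,
                    synthesize_trials(cfg, a, f, sampling, modulated = FALSE))
  for (k in seq_along(mats)) mats[[k]] <- mats[[k]] + tmpl[[k]]
  names(mats) <- channels
  epoch_set(mats, sampling, conditions = condition)
}
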