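#' Conventional EEG frequency band definitions
#'
#' @return Tibble with columns `band`, `f_lo`, `f_hi` (Hz): delta 0.1-3.9,
#'   theta 4-7.9, alpha 8-12.9, beta1 13-19.9, beta2 20-29.9, gamma 30-48.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "gamma"),
    f_lo = c(0.1, 4, 8, 13, 20, 30),
    f_hi = c(3.9, 7.9, 12.9, 19.9, 29.9, 48)
  )
}

# Zero-phase FIR filtering: windowed-sinc (Hamming) design via signal::fir1,
# applied forward-backward with signal::filtfilt. Order is 3x the longest
# period in the pass band, capped so filtfilt's edge transients fit the record.
zero_phase_fir <- function(x, rate, f_lo = NULL, f_hi = NULL) {
  nyq <- rate / 2
  n <- length(x)
  # low-pass: 6x the cutoff period keeps pass-band ripple well under 1%;
  # band-pass: 3x the longest in-band period bounds the order for slow bands
  if (!is.null(f_lo) && f_lo > 0) {
    ord <- as.integer(round(3 * rate / f_lo))
  } else {
    ord <- as.integer(round(6 * rate / f_hi))
  }
  ord <- min(ord, as.integer(floor((n - 2) / 3)))
  ord <- max(ord, 8L)
  if (ord %% 2 == 1) ord <- ord + 1L   # even order -> odd-length symmetric FIR
  if (is.null(f_lo) || f_lo <= 0) {
    b <- signal::fir1(ord, f_hi / nyq, type = "low")
  } else {
    b <- signal::fir1(ord, c(f_lo, f_hi) / nyq, type = "pass")
  }
  signal::filtfilt(b, x)
}

#' Event-related potential: baseline-corrected trial average
#'
#' Subtracts each trial's mean over the baseline window, averages across
#' trials per channel, and smooths the average with a zero-phase FIR low-pass
#' filter (forward-backward windowed-sinc, so no group delay).
#'
#' @param e An [epoch_set()].
#' @param baseline Length-2 baseline window in seconds (default `c(-0.2, 0)`).
#' @param lowpass Low-pass cutoff in Hz (default 20); `NULL` skips smoothing.
#' @return Tibble with columns `channel`, `time`, `value` (microvolts).
#' @export
erp <- function(e, baseline = c(-0.2, 0), lowpass = 20) {
  sp <- sampling_of(e)
  if (baseline[1] < sp$epoch_start || baseline[2] > sp$epoch_end) {
    stop("baseline window lies outside the epoch", call. = FALSE)
  }
  mask <- window_mask(sp, baseline[1], baseline[2])
  tt <- time_points(sp)
  out <- lapply(unique(e$channel), function(ch) {
    m <- epoch_matrix(e, ch)
    m <- sweep(m, 2, colMeans(m[mask, , drop = FALSE]))
    avg <- rowMeans(m)
    if (!is.null(lowpass)) avg <- zero_phase_fir(avg, sp$rate, f_hi = lowpass)
    tibble::tibble(channel = ch, time = tt, value = avg)
  })
  dplyr::bind_rows(out)
}

#' Event-related (de)synchronization as percent amplitude change
#'
#' Band-pass filters every trial with a zero-phase FIR filter, takes the
#' Hilbert amplitude envelope per trial, averages envelopes across trials, and
#' expresses the result as a percentage of the mean baseline amplitude:
#' `100 * (envelope / baseline_mean - 1)`. Positive values are event-related
#' synchronization (amplitude increase), negative desynchronization.
#'
#' @param e An [epoch_set()].
#' @param band Either a band name from [eeg_bands()] or a length-2 numeric
#'   `c(f_lo, f_hi)` in Hz.
#' @param baseline Length-2 baseline window in seconds (default `c(-0.5, 0)`).
#' @param by_trial If `TRUE`, skip the trial average and normalize each
#'   trial's envelope by the across-trial baseline mean, returning one curve
#'   per trial (for across-trial tests of a deflection's sign).
#' @return Tibble with columns `channel`, `band`, `time`, `erd` (percent),
#'   plus `trial` when `by_trial = TRUE`.
#' @export
erd_ers <- function(e, band = "alpha", baseline = c(-0.5, 0),
                    by_trial = FALSE) {
  sp <- sampling_of(e)
  if (is.character(band)) {
    bd <- eeg_bands()
    row <- bd[bd$band == band, ]
    if (nrow(row) == 0) stop("unknown band: ", band, call. = FALSE)
    f_lo <- row$f_lo; f_hi <- row$f_hi; bname <- band
  } else {
    f_lo <- band[1]; f_hi <- band[2]; bname <- sprintf("%g-%g Hz", f_lo, f_hi)
  }
  if (f_hi >= sp$rate / 2) stop("band extends to or above Nyquist", call. = FALSE)
  mask <- window_mask(sp, baseline[1], baseline[2])
  tt <- time_points(sp)
  out <- lapply(unique(e$channel), function(ch) {
    m <- epoch_matrix(e, ch)
    env <- apply(m, 2, function(x) {
      Mod(analytic_signal(zero_phase_fir(x, sp$rate, f_lo, f_hi)))
    })
    mean_env <- rowMeans(env)
    b <- mean(mean_env[mask])
    if (b <= .Machine$double.eps) {
      stop("zero baseline amplitude in band: normalization undefined",
           call. = FALSE)
    }
    if (by_trial) {
      trial_ids <- as.integer(colnames(m))
      tibble::tibble(
        channel = ch, band = bname,
        trial = rep(trial_ids, each = length(tt)),
        time = rep(tt, ncol(env)),
        erd = 100 * (as.vector(env) / b - 1))
    } else {
      tibble::tibble(channel = ch, band = bname, time = tt,
                     erd = 100 * (mean_env / b - 1))
    }
  })
  dplyr::bind_rows(out)
}

#' Welch power spectral density of an epoch window
#'
#' Averaged modified periodogram: the chosen window of every trial is split
#' into Hanning-tapered segments with the given overlap, each segment's
#' periodogram is computed, and all segments of all trials are averaged per
#' channel. Frequency resolution (bin spacing) is `rate / segment_length`.
#'
#' @param e An [epoch_set()].
#' @param window Length-2 time range in seconds; default the pre-stimulus
#'   second `c(-1.024, -0.001)`.
#' @param segment_length Samples per segment (default 512).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Tibble of class `psd_estimate` with columns `channel`, `frequency`
#'   (Hz), `power` (uV^2/Hz); attributes `segment_length`, `window_name`,
#'   `overlap`, `rate`.
#' @examples
#' sp <- sampling_spec(500, -2, 2)
#' e <- epoch_set(matrix(rnorm(2000 * 3), 2000), sp)
#' p <- welch_psd(e)
#' diff(unique(p$frequency))[1] # 0.977 Hz at 500 Hz / 512 samples
#' @export
welch_psd <- function(e, window = c(-1.024, -0.001), segment_length = 512,
                      overlap = 0.5) {
  sp <- sampling_of(e)
  mask <- window_mask(sp, window[1], window[2])
  if (sum(mask) < segment_length) {
    stop("window too short for the requested segment length", call. = FALSE)
  }
  win <- signal::hanning(segment_length)
  norm <- sum(win^2) * sp$rate      # density scaling
  starts <- seq(1, sum(mask) - segment_length + 1,
                by = max(1, round(segment_length * (1 - overlap))))
  nf <- floor(segment_length / 2) + 1
  freqs <- (seq_len(nf) - 1) * sp$rate / segment_length
  out <- lapply(unique(e$channel), function(ch) {
    m <- epoch_matrix(e, ch)[mask, , drop = FALSE]
    acc <- numeric(nf)
    n_seg <- 0L
    for (j in seq_len(ncol(m))) {
      for (s0 in starts) {
        seg <- m[s0:(s0 + segment_length - 1), j]
        seg <- (seg - mean(seg)) * win
        P <- Mod(stats::fft(seg))^2 / norm
        p1 <- P[seq_len(nf)]
        # fold negative frequencies (one-sided density)
        if (segment_length %% 2 == 0) {
          p1[2:(nf - 1)] <- 2 * p1[2:(nf - 1)]
        } else {
          p1[2:nf] <- 2 * p1[2:nf]
        }
        acc <- acc + p1
        n_seg <- n_seg + 1L
      }
    }
    tibble::tibble(channel = ch, frequency = freqs, power = acc / n_seg)
  })
  structure(dplyr::bind_rows(out),
            segment_length = as.integer(segment_length),
            window_name = "hanning", overlap = overlap, rate = sp$rate,
            class = c("psd_estimate", class(tibble::tibble())))
}
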