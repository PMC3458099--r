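#' Locate local extrema with plateau-midpoint tie-breaking
#'
#' Strict-inequality extremum detection: a turning point between a rising and
#' a falling run. Flat plateaus at a turning point contribute a single
#' extremum at the plateau centre.
#'
#' @param x Numeric vector.
#' @return List with integer index vectors `maxima` and `minima`.
#' @keywords internal
local_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(maxima = integer(), minima = integer()))
  s <- sign(d[nz])
  turn <- which(s[-1] != s[-length(s)])
  # slope segment j runs from nz[j] to nz[j]+1; a turn at j means the plateau
  # (possibly of length 1) spans indices nz[j]+1 .. nz[j+1]
  idx <- as.integer(floor((nz[turn] + 1 + nz[turn + 1]) / 2))
  list(maxima = idx[s[turn] > 0], minima = idx[s[turn] < 0])
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' The elementary sifting step of empirical mode decomposition: natural cubic
#' splines are fitted through the local maxima and through the local minima,
#' and their pointwise mean is returned. Ends are handled by mirroring the two
#' nearest extrema of each kind about the first and last sample, which keeps
#' end swings small.
#'
#' @param x Numeric time series with at least 2 maxima and 2 minima.
#' @return Numeric vector, same length as `x`.
#' @section Errors: signals a condition of class `monotonic_signal` when fewer
#'   than 2 maxima or 2 minima exist (the caller stops sifting).
#' @export
envelope_mean <- function(x) {
  n <- length(x)
  ex <- local_extrema(x)
  if (length(ex$maxima) < 2 || length(ex$minima) < 2) {
    stop(structure(
      class = c("monotonic_signal", "error", "condition"),
      list(message = "too few extrema: signal is (near-)monotonic",
           call = sys.call())))
  }
  env_of <- function(idx) {
    # mirror up to two extrema about each end of the record
    head_i <- idx[seq_len(min(2, length(idx)))]
    tail_i <- idx[length(idx) - seq_len(min(2, length(idx))) + 1]
    xi <- c(2 - rev(head_i), idx, 2 * n - tail_i)
    yi <- c(x[rev(head_i)], x[idx], x[tail_i])
    keep <- !duplicated(xi)
    stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "natural")$y
  }
  (env_of(ex$maxima) + env_of(ex$minima)) / 2
}

# One complete IMF via iterated sifting with a Cauchy-type stop:
# SD = sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh, hard cap max_sift.
sift_one <- function(x, sd_thresh, max_sift) {
  h <- x
  for (k in seq_len(max_sift)) {
    m <- tryCatch(envelope_mean(h), monotonic_signal = function(e) NULL)
    if (is.null(m)) return(if (k == 1) NULL else h)
    h_new <- h - m
    sd_k <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    if (is.finite(sd_k) && sd_k < sd_thresh) break
  }
  h
}

#' Empirical mode decomposition by sifting
#'
#' Decomposes a time series into intrinsic mode functions (IMFs), ordered from
#' highest to lowest frequency, plus a residual. Each IMF is isolated by
#' repeatedly subtracting the mean spline envelope ([envelope_mean()]) until a
#' Cauchy-type criterion is met, then subtracted from the running remainder;
#' decomposition stops at `max_imfs` or when the remainder is monotonic. The
#' returned components reconstruct the input exactly by construction:
#' `rowSums(imfs) + residual == x`.
#'
#' @param x Finite numeric series, length >= 16.
#' @param max_imfs Maximum number of IMFs to extract (default 6); any
#'   remaining oscillation is folded into the residual.
#' @param sd_thresh Cauchy stopping threshold for one IMF (default 0.2).
#' @param max_sift Hard cap on sifting iterations per IMF (default 50).
#' @return List of class `imf_set`: `imfs` (matrix, one column per IMF),
#'   `residual` (numeric vector), `n_imfs`.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' d <- sift(sin(2 * pi * 10 * t) + sin(2 * pi * 1 * t))
#' d$n_imfs
#' @export
sift <- function(x, max_imfs = 6, sd_thresh = 0.2, max_sift = 50) {
  if (!all(is.finite(x))) stop("sift: input must be finite", call. = FALSE)
  if (length(x) < 16) stop("sift: series too short (< 16 samples)", call. = FALSE)
  rem <- x
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    imf <- sift_one(rem, sd_thresh, max_sift)
    if (is.null(imf)) break
    imfs[[k]] <- imf
    rem <- rem - imf
  }
  if (length(imfs) == 0L) {
    return(structure(list(imfs = matrix(numeric(0), length(x), 0),
                          residual = rem, n_imfs = 0L), class = "imf_set"))
  }
  structure(list(imfs = do.call(cbind, imfs), residual = rem,
                 n_imfs = length(imfs)), class = "imf_set")
}

#' Decompose every trial of an epoch set into IMFs
#'
#' Runs [sift()] on each (trial, channel) series and returns a long IMF store.
#' Exactly `n_imfs` rows of components are produced per trial: if sifting
#' stops early the missing IMFs are zero-filled, so aggregation by ordinal IMF
#' number is always well defined.
#'
#' @param e An [epoch_set()].
#' @param n_imfs IMFs per trial (default 6).
#' @param ... Passed to [sift()].
#' @return A tibble of class `imf_store` with columns `trial`, `channel`,
#'   `condition`, `imf`, `time`, `value`, carrying the sampling spec.
#' @export
emd_epochs <- function(e, n_imfs = 6, ...) {
  sp <- sampling_of(e)
  tt <- time_points(sp)
  conds <- trial_conditions(e)
  chans <- unique(e$channel)
  rows <- list()
  for (ch in chans) {
    m <- epoch_matrix(e, ch)
    trial_ids <- as.integer(colnames(m))
    for (j in seq_len(ncol(m))) {
      d <- sift(m[, j], max_imfs = n_imfs, ...)
      comp <- matrix(0, sp$n_samples, n_imfs)
      if (d$n_imfs > 0) comp[, seq_len(d$n_imfs)] <- d$imfs
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial = trial_ids[j],
        channel = ch,
        condition = conds$condition[match(trial_ids[j], conds$trial)],
        imf = rep(seq_len(n_imfs), each = sp$n_samples),
        time = rep(tt, n_imfs),
        value = as.vector(comp)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, sampling = sp,
            class = c("imf_store", class(tibble::tibble())))
}

#' Amplitude-weighted mean instantaneous frequency of an IMF
#'
#' The Hilbert instantaneous frequency of the series, averaged over a time
#' window with the amplitude envelope as weight, so low-amplitude (noisy
#' phase) stretches contribute little.
#'
#' @param imf Numeric series (one IMF).
#' @param sampling A [sampling_spec()] for the series.
#' @param window Length-2 time range in seconds (default the whole epoch minus
#'   the 100 ms Hilbert edge guard).
#' @return Mean frequency in Hz.
#' @export
imf_mean_frequency <- function(imf, sampling,
                               window = c(sampling$epoch_start + 0.1,
                                          sampling$epoch_end - 0.1)) {
  a <- analytic(imf, sampling$rate)
  mask <- window_mask(sampling, window[1], window[2])
  wgt <- a$amplitude[mask]
  if (sum(wgt) <= 0) stop("zero-amplitude IMF: frequency undefined", call. = FALSE)
  sum(a$frequency[mask] * wgt) / sum(wgt)
}
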