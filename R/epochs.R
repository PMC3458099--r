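#' Sampling specification for an epoched recording
#'
#' Describes the uniform time grid of a stimulus-locked epoch: the sampling
#' rate and the epoch window relative to stimulus onset (time 0). Sample index
#' 1 falls at `epoch_start`; the stimulus falls at sample
#' `round(-epoch_start * rate) + 1`.
#'
#' @param rate Sampling rate in Hz (samples per second); must be positive.
#' @param epoch_start Epoch start in seconds relative to the stimulus
#'   (negative, i.e. pre-stimulus).
#' @param epoch_end Epoch end in seconds relative to the stimulus (positive).
#' @return An object of class `sampling_spec`: a list with fields `rate`,
#'   `epoch_start`, `epoch_end` and the derived `n_samples`.
#' @examples
#' sp <- sampling_spec(500, -2, 2)
#' sp$n_samples # 2000
#' @export
sampling_spec <- function(rate, epoch_start, epoch_end) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  stopifnot(is.numeric(epoch_start), is.numeric(epoch_end))
  if (!(epoch_start < 0 && 0 < epoch_end)) {
    stop("epoch window must straddle the stimulus: epoch_start < 0 < epoch_end",
         call. = FALSE)
  }
  n <- round((epoch_end - epoch_start) * rate)
  if (n < 2) stop("epoch must contain at least 2 samples", call. = FALSE)
  structure(
    list(rate = rate, epoch_start = epoch_start, epoch_end = epoch_end,
         n_samples = as.integer(n)),
    class = "sampling_spec"
  )
}

#' @export
print.sampling_spec <- function(x, ...) {
  cat(sprintf("<sampling_spec> %g Hz, %g..%g s (%d samples, stimulus at sample %d)\n",
              x$rate, x$epoch_start, x$epoch_end, x$n_samples, stimulus_index(x)))
  invisible(x)
}

#' Time grid of a sampling specification
#'
#' @param sampling A [sampling_spec()].
#' @return Numeric vector of sample times in seconds relative to the stimulus;
#'   the first time is `epoch_start`.
#' @export
time_points <- function(sampling) {
  stopifnot(inherits(sampling, "sampling_spec"))
  sampling$epoch_start + (seq_len(sampling$n_samples) - 1) / sampling$rate
}

#' Sample index of stimulus onset
#'
#' @param sampling A [sampling_spec()].
#' @return Integer index (1-based) of the sample at (or immediately at) time 0.
#' @export
stimulus_index <- function(sampling) {
  stopifnot(inherits(sampling, "sampling_spec"))
  as.integer(round(-sampling$epoch_start * sampling$rate)) + 1L
}

#' Build an epoch set from per-trial matrices
#'
#' An `epoch_set` is the pipeline's universal currency: a long tibble of
#' potentials with one row per (trial, channel, sample) and columns `trial`,
#' `channel`, `condition`, `time` (s, stimulus at 0) and `value` (microvolts),
#' carrying its [sampling_spec()] as an attribute.
#'
#' @param data A named list, one element per channel, each a numeric matrix of
#'   size `n_samples x n_trials` (columns are trials), or a single matrix for a
#'   one-channel set.
#' @param sampling A [sampling_spec()].
#' @param conditions Character vector of condition labels, one per trial
#'   (recycled if length 1). Default `"a"`.
#' @param channel One or more channel names; used when `data` is an unnamed
#'   matrix/list.
#' @return A tibble of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling, conditions = "a", channel = "Cz") {
  stopifnot(inherits(sampling, "sampling_spec"))
  if (is.matrix(data)) data <- stats::setNames(list(data), channel[1])
  if (is.null(names(data)) || any(!nzchar(names(data)))) {
    stopifnot(length(channel) == length(data))
    names(data) <- channel
  }
  n_trials <- unique(vapply(data, ncol, integer(1)))
  n_samp <- unique(vapply(data, nrow, integer(1)))
  if (length(n_trials) != 1L || length(n_samp) != 1L) {
    stop("all channels must have identical trial and sample counts", call. = FALSE)
  }
  if (n_samp != sampling$n_samples) {
    stop(sprintf("data has %d samples but sampling spec implies %d",
                 n_samp, sampling$n_samples), call. = FALSE)
  }
  if (!all(vapply(data, function(m) all(is.finite(m)), logical(1)))) {
    stop("epoch data must be finite", call. = FALSE)
  }
  conditions <- rep_len(as.character(conditions), n_trials)
  tt <- time_points(sampling)
  out <- purrr::map2_dfr(data, names(data), function(m, ch) {
    tibble::tibble(
      trial = rep(seq_len(n_trials), each = n_samp),
      channel = ch,
      condition = rep(conditions, each = n_samp),
      time = rep(tt, times = n_trials),
      value = as.vector(m)
    )
  })
  new_epoch_set(out, sampling)
}

new_epoch_set <- function(tbl, sampling) {
  structure(tbl, sampling = sampling,
            class = c("epoch_set", class(tibble::tibble())))
}

#' Sampling specification of an epoch set or IMF store
#'
#' @param x An `epoch_set` or any object carrying a `sampling` attribute.
#' @return The [sampling_spec()].
#' @export
sampling_of <- function(x) {
  sp <- attr(x, "sampling")
  if (is.null(sp)) stop("object carries no sampling specification", call. = FALSE)
  sp
}

#' Extract one channel of an epoch set as a samples-by-trials matrix
#'
#' @param e An `epoch_set`.
#' @param channel Channel name; defaults to the first channel present.
#' @return Numeric matrix, `n_samples x n_trials`, columns named by trial.
#' @export
epoch_matrix <- function(e, channel = NULL) {
  sp <- sampling_of(e)
  chans <- unique(e$channel)
  if (is.null(channel)) channel <- chans[1]
  if (!channel %in% chans) stop("unknown channel: ", channel, call. = FALSE)
  d <- e[e$channel == channel, , drop = FALSE]
  trials <- unique(d$trial)
  m <- matrix(d$value, nrow = sp$n_samples, ncol = length(trials))
  colnames(m) <- trials
  m
}

#' Condition label per trial
#' @param e An `epoch_set`.
#' @return Tibble with columns `trial`, `condition`.
#' @export
trial_conditions <- function(e) {
  dplyr::distinct(tibble::as_tibble(e)[c("trial", "condition")])
}

#' @export
print.epoch_set <- function(x, ...) {
  sp <- sampling_of(x)
  cat(sprintf("<epoch_set> %d trial(s) x %d channel(s) x %d samples @ %g Hz (%g..%g s)\n",
              dplyr::n_distinct(x$trial), dplyr::n_distinct(x$channel),
              sp$n_samples, sp$rate, sp$epoch_start, sp$epoch_end))
  NextMethod()
}

#' Write an epoch set to a columnar text file with a metadata sidecar
#'
#' Samples go to a tab-separated file (one row per sample, one column per
#' trial-by-channel combination, named `t<trial>.<channel>`); the sampling
#' rate, window, channel list and per-trial condition labels go to a flat
#' key-value sidecar at `<path>.meta`. Values are written with shortest
#' round-trip precision so [read_epochs()] reproduces the set bit-identically.
#'
#' @param e An `epoch_set`.
#' @param path Output path for the sample table.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(e, path) {
  sp <- sampling_of(e)
  chans <- unique(e$channel)
  trials <- unique(e$trial)
  cols <- list()
  for (i in seq_along(trials)) { # trials renumbered sequentially on disk
    for (ch in chans) {
      v <- e$value[e$trial == trials[i] & e$channel == ch]
      cols[[sprintf("t%d.%s", i, ch)]] <- v
    }
  }
  # %.17g is the shortest format guaranteed to round-trip IEEE doubles
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = "\t"))
  writeLines(c(paste(names(cols), collapse = "\t"), body), path)
  cond <- trial_conditions(e)$condition
  meta <- c(
    sprintf("rate_hz=%.17g", sp$rate),
    sprintf("epoch_start_s=%.17g", sp$epoch_start),
    sprintf("epoch_end_s=%.17g", sp$epoch_end),
    paste0("channels=", paste(chans, collapse = ",")),
    paste0("conditions=", paste(cond, collapse = ","))
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Path to the sample table; `<path>.meta` must exist.
#' @return An `epoch_set` equal to the one written, in all fields.
#' @export
read_epochs <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  }
  kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  need <- c("rate_hz", "epoch_start_s", "epoch_end_s", "channels", "conditions")
  if (!all(need %in% keys)) {
    stop("sidecar is missing keys: ", paste(setdiff(need, keys), collapse = ", "),
         call. = FALSE)
  }
  get <- function(k) vals[match(k, keys)]
  sp <- sampling_spec(as.numeric(get("rate_hz")),
                      as.numeric(get("epoch_start_s")),
                      as.numeric(get("epoch_end_s")))
  chans <- strsplit(get("channels"), ",", fixed = TRUE)[[1]]
  conds <- strsplit(get("conditions"), ",", fixed = TRUE)[[1]]
  # base strtod parsing is correctly rounded, so %.17g output round-trips
  tab <- utils::read.delim(path, check.names = FALSE)
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1]
      stop(sprintf("non-numeric cell at row %d, column %d of %s",
                   bad, j, path), call. = FALSE)
    }
  }
  n_trials <- length(conds)
  if (ncol(tab) != n_trials * length(chans)) {
    stop(sprintf(
      "file has %d columns but sidecar declares %d trials x %d channels",
      ncol(tab), n_trials, length(chans)), call. = FALSE)
  }
  if (nrow(tab) != sp$n_samples) {
    stop(sprintf("file has %d rows but sidecar sampling implies %d samples",
                 nrow(tab), sp$n_samples), call. = FALSE)
  }
  data <- lapply(chans, function(ch) {
    m <- sapply(seq_len(n_trials),
                function(tr) tab[[sprintf("t%d.%s", tr, ch)]])
    matrix(m, nrow = sp$n_samples)
  })
  names(data) <- chans
  epoch_set(data, sp, conditions = conds)
}

#' Reject trials containing out-of-range samples
#'
#' Drops every trial in which any sample, on any channel, lies outside
#' `[-limit, +limit]` microvolts (the bound itself is retained). Trials are
#' judged jointly across channels and trial order is preserved. Idempotent.
#'
#' @param e An `epoch_set`.
#' @param limit Positive rejection bound in microvolts (default 120, the
#'   conventional gross-artifact threshold).
#' @return An `epoch_set` containing only the retained trials.
#' @export
artifact_reject <- function(e, limit = 120) {
  stopifnot(is.numeric(limit), length(limit) == 1L, limit > 0)
  sp <- sampling_of(e)
  bad <- unique(e$trial[abs(e$value) > limit])
  keep <- setdiff(unique(e$trial), bad)
  if (length(keep) == 0L) {
    stop("artifact_reject: all trials exceeded the limit", call. = FALSE)
  }
  out <- e[e$trial %in% keep, , drop = FALSE]
  new_epoch_set(tibble::as_tibble(out), sp)
}
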