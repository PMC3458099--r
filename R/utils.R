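# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring prior RNG state.
# `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation: a single pipeline seed expands into
# per-stage seeds so module-level reruns match full pipeline runs.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# nearest sample index for a time (s) on the epoch grid
time_index <- function(sampling, t) {
  i <- as.integer(round((t - sampling$epoch_start) * sampling$rate)) + 1L
  pmin(pmax(i, 1L), sampling$n_samples)
}

#' Logical mask of epoch samples within a time window
#'
#' @param sampling A [sampling_spec()].
#' @param from,to Window bounds in seconds (inclusive), stimulus at 0.
#' @return Logical vector over the epoch's samples.
#' @export
window_mask <- function(sampling, from, to) {
  tt <- time_points(sampling)
  tt >= from & tt <= to
}
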