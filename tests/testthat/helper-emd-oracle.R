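# Minimal reference sifter, written independently of the package
# implementation as a cross-check oracle. Deliberately different design
# choices: fixed number of sifting passes (no Cauchy criterion), extrema by
# simple strict three-point comparison (no plateau handling), and boundary
# handling by reflecting the whole signal about each end before enveloping
# (the package mirrors extrema instead). Exact agreement with the package is
# not expected; strong per-IMF correlation is.

oracle_extrema <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  list(maxima = i[x[i] > x[i - 1] & x[i] > x[i + 1]],
       minima = i[x[i] < x[i - 1] & x[i] < x[i + 1]])
}

oracle_sift_one <- function(x, passes = 10, pad = 256) {
  n <- length(x)
  h <- x
  for (k in seq_len(passes)) {
    # reflect the signal about both ends, envelope, then crop
    ext <- c(rev(h[2:(pad + 1)]), h, rev(h[(n - pad):(n - 1)]))
    ex <- oracle_extrema(ext)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) {
      return(if (k == 1) NULL else h)
    }
    up <- stats::spline(ex$maxima, ext[ex$maxima], xout = seq_along(ext),
                        method = "natural")$y
    lo <- stats::spline(ex$minima, ext[ex$minima], xout = seq_along(ext),
                        method = "natural")$y
    h <- h - ((up + lo) / 2)[(pad + 1):(pad + n)]
  }
  h
}

oracle_emd <- function(x, max_imfs = 6, passes = 10) {
  rem <- x
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    imf <- oracle_sift_one(rem, passes)
    if (is.null(imf)) break
    imfs[[k]] <- imf
    rem <- rem - imf
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs) else NULL, residual = rem)
}

# 1/f-weighted random signal on a small grid (for oracle comparisons)
pink_signal <- function(n, rate, f_lo = 0.5, f_hi = 80) {
  f <- seq(f_lo, f_hi, by = 0.5)
  a <- (1 / f) / sqrt(sum(1 / f^2))
  t <- (seq_len(n) - 1) / rate
  phases <- stats::runif(length(f), -pi, pi)
  as.vector(cos(2 * pi * outer(t, f) + rep(phases, each = n)) %*% a)
}
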