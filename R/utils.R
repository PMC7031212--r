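# Internal numerics shared across stages.

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from (seed, index); stays within 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Frame a signal into overlapping windows: returns nwin x nframes matrix.
frame_signal <- function(x, nwin, step) {
  n <- length(x)
  if (n < nwin) stop("signal shorter than one window")
  starts <- seq(1L, n - nwin + 1L, by = step)
  idx <- outer(seq_len(nwin) - 1L, starts, `+`)
  matrix(x[idx], nrow = nwin)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# One-sided power spectral density of framed data (rows = samples in window).
# Density scaling: integral over frequency of a stationary signal's PSD
# approximates its variance (Welch convention, Hann taper).
frames_psd <- function(frames, fs) {
  nwin <- nrow(frames)
  w <- hann_window(nwin)
  scale <- 1 / (fs * sum(w^2))
  X <- stats::mvfft(frames * w)
  nf <- floor(nwin / 2) + 1L
  p <- (Mod(X[seq_len(nf), , drop = FALSE])^2) * scale
  # fold negative frequencies into positive bins (except DC and Nyquist)
  if (nf > 2L) {
    last <- if (nwin %% 2L == 0L) nf - 1L else nf
    p[2L:last, ] <- 2 * p[2L:last, , drop = FALSE]
  }
  list(power = p, freqs = (seq_len(nf) - 1L) * fs / nwin)
}

# Welch PSD of a single segment vector x, given segment length and overlap.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  step <- max(1L, round(seg_len * (1 - overlap)))
  fr <- frame_signal(x, seg_len, step)
  ps <- frames_psd(fr, fs)
  list(power = rowMeans(ps$power), freqs = ps$freqs, n_segments = ncol(fr))
}

# Zero-phase Butterworth bandpass (forward-backward).
bandpass_filtfilt <- function(x, fs, low, high, order = 4L) {
  nyq <- fs / 2
  if (high >= nyq) stop("band edge ", high, " Hz at or above Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

# Gaussian smoothing of a regularly sampled trace, sigma in samples.
# Edge handling: replicate-padding. FFT convolution for long kernels.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  if (as.double(n) * length(k) > 2e6) {
    m <- length(xp) + length(k) - 1L
    m2 <- stats::nextn(m, 2)
    conv <- Re(stats::fft(stats::fft(c(xp, numeric(m2 - length(xp)))) *
                            stats::fft(c(k, numeric(m2 - length(k)))),
                          inverse = TRUE)) / m2
    conv[(2L * half + 1L):(2L * half + n)]
  } else {
    as.numeric(stats::filter(xp, k, sides = 2)[(half + 1L):(half + n)])
  }
}
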