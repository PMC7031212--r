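#' Short-time power spectrogram
#'
#' Magnitude-squared short-time Fourier estimate per window (Hann taper,
#' one-sided density scaling), the intermediate from which the MUA firing-rate
#' estimate is derived. For long recordings prefer [compute_mua()], which
#' processes channels one at a time and keeps only the high band.
#'
#' @param rec an [recording()] object.
#' @param window window length, s (default 0.005).
#' @param step hop between windows, s (default 0.001).
#' @param channels optional channel index subset.
#' @return `so_spectrogram`: list with `power` (channels x freqs x windows,
#'   uV^2/Hz), `freqs` (Hz), `times` (window centres, s), `window`, `step`.
#' @export
compute_spectrogram <- function(rec, window = 0.005, step = 0.001,
                                channels = NULL) {
  validate_recording(rec)
  if (window < 4 / 1500)
    stop("window too short to resolve the high band")
  nwin <- max(2L, round(window * rec$fs))
  nstep <- max(1L, round(step * rec$fs))
  if (is.null(channels)) channels <- seq_len(nrow(rec$signals))
  first <- frames_psd(frame_signal(rec$signals[channels[1L], ], nwin, nstep),
                      rec$fs)
  nf <- length(first$freqs)
  nt <- ncol(first$power)
  power <- array(NA_real_, c(length(channels), nf, nt))
  power[1L, , ] <- first$power
  for (k in seq_along(channels)[-1L]) {
    power[k, , ] <- frames_psd(
      frame_signal(rec$signals[channels[k], ], nwin, nstep), rec$fs)$power
  }
  starts <- seq(1L, ncol(rec$signals) - nwin + 1L, by = nstep)
  structure(list(
    power = power, freqs = first$freqs,
    times = rec$t0 + (starts - 1L + nwin / 2) / rec$fs,
    window = nwin / rec$fs, step = nstep / rec$fs,
    channel_ids = rec$channel_ids[channels]
  ), class = "so_spectrogram")
}

#' Normalize high-band power into an MUA estimate
#'
#' Population firing rate is estimated from the high-frequency (by default
#' 200-1500 Hz) content of the LFP spectrum: each frequency bin in the band
#' is divided by its own time-average over the whole recording — removing the
#' electrode's linear frequency response and any overall gain — and the
#' normalized bins are then averaged (in power) across the band. The result
#' is dimensionless with time-average 1 per channel; `log_mua` is its
#' logarithm, floored at `log_floor`.
#'
#' @param spec an `so_spectrogram`.
#' @param band frequency band `(low, high)`, Hz.
#' @param log_floor floor inside the log (default 1e-3): near-silent Down
#'   windows can yield vanishing estimates.
#' @return `mua_trace`: list with `mua`, `log_mua` (channels x windows),
#'   `times`, `band`, `window`, `step`, `averaging = "power"`.
#' @export
normalize_mua <- function(spec, band = c(200, 1500), log_floor = 1e-3) {
  if (band[1] < min(spec$freqs) || band[2] > max(spec$freqs))
    stop("band unreachable at this sampling rate")
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(sel) < 1L) stop("no frequency bins inside the band")
  n_ch <- dim(spec$power)[1L]
  nt <- dim(spec$power)[3L]
  mua <- matrix(NA_real_, n_ch, nt)
  for (i in seq_len(n_ch)) {
    p <- spec$power[i, sel, , drop = TRUE]
    if (length(sel) == 1L) p <- matrix(p, nrow = 1L)
    denom <- rowMeans(p)
    if (any(denom == 0))
      stop("degenerate recording: zero time-average power in band bin")
    mua[i, ] <- colMeans(p / denom)
  }
  structure(list(
    mua = mua, log_mua = log(pmax(mua, log_floor)), times = spec$times,
    band = band, window = spec$window, step = spec$step,
    averaging = "power", channel_ids = spec$channel_ids
  ), class = "mua_trace")
}

#' One-step MUA computation, streaming over channels
#'
#' Equivalent to `normalize_mua(compute_spectrogram(rec, ...), band)` but
#' never materializes the full spectrogram, so it scales to long multichannel
#' recordings.
#'
#' @inheritParams compute_spectrogram
#' @inheritParams normalize_mua
#' @return An `mua_trace`.
#' @examples
#' sim <- simulate_recording(synth_config(n_channels = 2, duration = 10), seed = 1)
#' mua <- compute_mua(sim$recording)
#' rowMeans(mua$mua)   # ~1 per channel by construction
#' @export
compute_mua <- function(rec, window = 0.005, step = 0.001,
                        band = c(200, 1500), log_floor = 1e-3) {
  validate_recording(rec)
  if (rec$fs < 2 * band[1])
    stop("band unreachable at this sampling rate")
  band_hi <- min(band[2], rec$fs / 2)
  nwin <- max(2L, round(window * rec$fs))
  nstep <- max(1L, round(step * rec$fs))
  n_ch <- nrow(rec$signals)
  out <- NULL
  for (i in seq_len(n_ch)) {
    ps <- frames_psd(frame_signal(rec$signals[i, ], nwin, nstep), rec$fs)
    sel <- which(ps$freqs >= band[1] & ps$freqs <= band_hi)
    if (!length(sel)) stop("no frequency bins inside the band")
    p <- ps$power[sel, , drop = FALSE]
    denom <- rowMeans(p)
    if (any(denom == 0))
      stop("degenerate recording: zero time-average power in band bin")
    if (is.null(out)) out <- matrix(NA_real_, n_ch, ncol(p))
    out[i, ] <- colMeans(p / denom)
  }
  starts <- seq(1L, ncol(rec$signals) - nwin + 1L, by = nstep)
  structure(list(
    mua = out, log_mua = log(pmax(out, log_floor)),
    times = rec$t0 + (starts - 1L + nwin / 2) / rec$fs,
    band = c(band[1], band_hi), window = nwin / rec$fs, step = nstep / rec$fs,
    averaging = "power", channel_ids = rec$channel_ids
  ), class = "mua_trace")
}

#' @export
print.mua_trace <- function(x, ...) {
  cat(sprintf("<mua_trace> %d channels x %d windows (band %g-%g Hz, window %g ms, step %g ms)\n",
              nrow(x$mua), ncol(x$mua), x$band[1], x$band[2],
              1000 * x$window, 1000 * x$step))
  invisible(x)
}

#' Up-state firing rate relative to the Down state
#'
#' Mean MUA over Up-state windows divided by mean MUA over Down-state
#' windows, per channel. Because the MUA estimate is normalized to
#' time-average 1, only this ratio (not the absolute level) is meaningful
#' across recordings.
#'
#' @param mua an `mua_trace`.
#' @param seg a `state_segmentation` (see [detect_states()]) covering the
#'   MUA times.
#' @return numeric vector, one ratio per channel.
#' @export
relative_up_fr <- function(mua, seg) {
  n_ch <- nrow(mua$mua)
  if (length(seg$intervals) != n_ch)
    stop("segmentation must have one interval list per MUA channel")
  vapply(seq_len(n_ch), function(i) {
    lab <- label_times(seg$intervals[[i]], mua$times)
    if (!any(lab == "Down")) stop("no Down windows in segmentation")
    if (!any(lab == "Up")) stop("no Up windows in segmentation")
    mean(mua$mua[i, lab == "Up"]) / mean(mua$mua[i, lab == "Down"])
  }, numeric(1))
}

# Label each time point by the interval containing it.
label_times <- function(intervals, times) {
  idx <- findInterval(times, intervals$start)
  idx[idx < 1L] <- 1L
  out <- intervals$label[idx]
  out[times > intervals$end[nrow(intervals)]] <- NA
  out
}
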