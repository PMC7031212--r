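#' Choose an Up/Down log-MUA threshold
#'
#' The log-MUA distribution of a bistable recording is bimodal (Down and Up
#' modes). The threshold is placed at the minimum of a kernel-smoothed
#' histogram between the two largest modes; if the distribution is unimodal
#' the midpoint of the 10th and 90th percentiles is used instead.
#'
#' @param log_mua numeric vector of log MUA values (one channel).
#' @param adjust bandwidth multiplier passed to [stats::density()].
#' @return scalar threshold.
#' @export
choose_threshold <- function(log_mua, adjust = 1) {
  x <- log_mua[is.finite(log_mua)]
  if (length(unique(x)) < 2L) stop("no bistability: constant trace")
  d <- stats::density(x, n = 512, adjust = adjust)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) >= 2L) {
    top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
    between <- seq(top2[1L], top2[2L])
    return(d$x[between[which.min(y[between])]])
  }
  mean(stats::quantile(x, c(0.1, 0.9)))
}

#' Detect Up and Down states from one log-MUA trace
#'
#' Samples above the threshold are Up, below are Down. Runs shorter than the
#' minimum duration for their state are merged into the flanking state
#' (shortest offender first), which enforces the alternation invariant and
#' absorbs glitches such as a 2 ms spike of noise inside a Down state.
#'
#' @param log_mua numeric vector (one channel).
#' @param times window-centre times, s (regular grid).
#' @param threshold scalar from [choose_threshold()].
#' @param min_up,min_down minimum state durations, s.
#' @return data.frame with columns `label`, `start`, `end` tiling the
#'   analyzed span with alternating labels.
#' @export
detect_states <- function(log_mua, times, threshold,
                          min_up = 0.05, min_down = 0.05) {
  if (!length(log_mua)) stop("empty trace")
  if (!is.finite(threshold)) stop("threshold must be finite")
  step <- if (length(times) > 1L) stats::median(diff(times)) else 1
  r <- rle(log_mua > threshold)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  runs <- data.frame(
    up = r$values,
    start = times[starts_idx] - step / 2,
    end = times[ends_idx] + step / 2
  )
  repeat {
    dur <- runs$end - runs$start
    minim <- ifelse(runs$up, min_up, min_down)
    short <- which(dur < minim)
    if (!length(short) || nrow(runs) == 1L) break
    k <- short[which.min(dur[short])]
    if (k == 1L) {
      runs$start[2L] <- runs$start[1L]
      runs <- runs[-1L, , drop = FALSE]
    } else if (k == nrow(runs)) {
      runs$end[k - 1L] <- runs$end[k]
      runs <- runs[-k, , drop = FALSE]
    } else {
      runs$end[k - 1L] <- runs$end[k + 1L]
      runs <- runs[-c(k, k + 1L), , drop = FALSE]
    }
    rownames(runs) <- NULL
  }
  data.frame(label = ifelse(runs$up, "Up", "Down"),
             start = runs$start, end = runs$end)
}

#' Segment a whole recording into Up/Down states
#'
#' Smooths each channel's log MUA (Gaussian kernel, `smooth` seconds),
#' chooses a per-channel threshold and detects states.
#'
#' @param mua an `mua_trace` from [compute_mua()].
#' @param smooth smoothing sigma, s (0 disables).
#' @param min_up,min_down minimum state durations, s.
#' @param threshold optional fixed threshold (scalar or per channel);
#'   `NULL` (default) chooses per channel via [choose_threshold()].
#' @return `state_segmentation`: list with `intervals` (per-channel
#'   data.frames), `threshold` (per channel), `smooth`.
#' @examples
#' sim <- simulate_recording(synth_config(n_channels = 2, duration = 30), seed = 1)
#' seg <- segment_recording(compute_mua(sim$recording))
#' head(seg$intervals[[1]])
#' @export
segment_recording <- function(mua, smooth = 0.02, min_up = 0.05,
                              min_down = 0.05, threshold = NULL) {
  n_ch <- nrow(mua$log_mua)
  sigma <- smooth / mua$step
  thr <- numeric(n_ch)
  intervals <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    lm <- as.numeric(mua$log_mua[i, ])
    if (sigma > 0) lm <- as.numeric(gauss_smooth(lm, sigma))
    thr[i] <- if (is.null(threshold)) choose_threshold(lm)
              else threshold[min(i, length(threshold))]
    intervals[[i]] <- detect_states(lm, mua$times, thr[i], min_up, min_down)
  }
  structure(list(intervals = intervals, threshold = thr, smooth = smooth,
                 channel_ids = mua$channel_ids),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  n_up <- vapply(x$intervals, function(iv) sum(iv$label == "Up"), integer(1))
  cat(sprintf("<state_segmentation> %d channels, %d-%d Up states per channel\n",
              length(x$intervals), min(n_up), max(n_up)))
  invisible(x)
}

# Interior durations of a label (first/last interval dropped: truncated by
# the recording edges).
interior_durations <- function(intervals, label) {
  iv <- intervals[-c(1L, nrow(intervals)), , drop = FALSE]
  d <- iv$end[iv$label == label] - iv$start[iv$label == label]
  d[d > 0]
}

# Population (divide-by-N) coefficient of variation.
cv_pop <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Slow-oscillation metrics per channel
#'
#' Computes, per channel: mean Up and Down durations and their coefficients
#' of variation; slow-oscillation frequency as the mean over cycles of the
#' inverse complete Up-to-Down cycle duration, with its CV; Up-state firing
#' rate relative to Down ([relative_up_fr()]); mean Down-state MUA; the
#' Down-to-Up transition slope in degrees ([upward_slope()]); and, when the
#' recording is supplied, Up-state band power in the alpha (8-12), beta
#' (15-32) and gamma (32-100 Hz) bands ([up_state_psd()]).
#'
#' Edge intervals truncated by the recording boundaries are excluded from
#' duration statistics; CVs use the population (divide-by-N) standard
#' deviation.
#'
#' @param seg a `state_segmentation`.
#' @param mua the `mua_trace` the segmentation came from.
#' @param rec optional [recording()] for band PSDs.
#' @param bands named list of PSD bands, Hz.
#' @param slope_window window for the transition-slope fit, s.
#' @param welch_segment Welch segment length for band PSDs, s.
#' @return data.frame, one row per channel, columns `up_dur_mean`,
#'   `down_dur_mean`, `so_freq`, `cv_up`, `cv_down`, `cv_so`, `up_fr_rel`,
#'   `down_fr`, `upward_slope`, and `<band>_psd`.
#' @export
so_metrics <- function(seg, mua, rec = NULL,
                       bands = list(alpha = c(8, 12), beta = c(15, 32),
                                    gamma = c(32, 100)),
                       slope_window = 0.1, welch_segment = 0.25) {
  n_ch <- length(seg$intervals)
  rows <- vector("list", n_ch)
  fr_rel <- relative_up_fr(mua, seg)
  psd <- if (!is.null(rec)) up_state_psd(rec, seg, bands, welch_segment)
  for (i in seq_len(n_ch)) {
    iv <- seg$intervals[[i]]
    ups <- interior_durations(iv, "Up")
    downs <- interior_durations(iv, "Down")
    if (length(ups) < 2L || length(downs) < 2L)
      stop("fewer than 2 complete cycles on channel ", i)
    # complete cycles: interior Up followed by its Down
    ii <- iv[-c(1L, nrow(iv)), , drop = FALSE]
    up_pos <- which(ii$label == "Up")
    up_pos <- up_pos[up_pos < nrow(ii)]
    cyc <- (ii$end[up_pos + 1L] - ii$start[up_pos])
    lab <- label_times(iv, mua$times)
    down_fr <- mean(mua$mua[i, which(lab == "Down")])
    tr <- iv$start[iv$label == "Up"]
    tr <- tr[tr > min(mua$times) & tr < max(mua$times)]
    slope <- tryCatch(
      upward_slope(mua$log_mua[i, ], mua$times, tr,
                   fit_window = slope_window,
                   cycle_dur = mean(cyc),
                   level_span = mean(mua$log_mua[i, lab == "Up"], na.rm = TRUE) -
                     mean(mua$log_mua[i, lab == "Down"], na.rm = TRUE)),
      error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      channel = seg$channel_ids[i] %||% i,
      up_dur_mean = mean(ups), down_dur_mean = mean(downs),
      so_freq = mean(1 / cyc), cv_up = cv_pop(ups), cv_down = cv_pop(downs),
      cv_so = cv_pop(1 / cyc), up_fr_rel = fr_rel[i], down_fr = down_fr,
      upward_slope = slope
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(rec)) {
    colnames(psd) <- paste0(colnames(psd), "_psd")
    out <- cbind(out, psd)
  }
  rownames(out) <- NULL
  out
}

#' Down-to-Up transition slope
#'
#' Least-squares line fit to log MUA in a window around each Down-to-Up
#' crossing, on standardized axes — time in units of the mean cycle duration
#' and log MUA in units of the Up-Down level span — reported as the
#' arctangent in degrees, averaged over transitions. Degrees are meaningless
#' without an axis convention; this one is explicit and configurable through
#' `cycle_dur` and `level_span`.
#'
#' @param log_mua numeric vector (one channel).
#' @param times sample times, s.
#' @param transitions Down-to-Up crossing times, s.
#' @param fit_window fit window centred on each crossing, s.
#' @param cycle_dur time-axis unit, s (mean Up+Down cycle duration).
#' @param level_span amplitude-axis unit (Up minus Down mean log MUA).
#' @return mean slope angle, degrees. Transitions whose window exceeds the
#'   recording are skipped with a warning; if all are skipped, an error.
#' @export
upward_slope <- function(log_mua, times, transitions, fit_window = 0.1,
                         cycle_dur, level_span) {
  if (length(transitions) < 1L) stop("no transitions")
  if (!is.finite(level_span) || level_span == 0)
    stop("level_span must be nonzero")
  half <- fit_window / 2
  angles <- rep(NA_real_, length(transitions))
  skipped <- 0L
  tstep <- if (length(times) > 1L) times[2L] - times[1L] else 1
  for (k in seq_along(transitions)) {
    t0 <- transitions[k]
    sel <- seq(max(1L, ceiling((t0 - half - times[1L]) / tstep) + 1L),
               min(length(times), floor((t0 + half - times[1L]) / tstep) + 1L))
    if (length(sel) < 2L || t0 - half < min(times) || t0 + half > max(times)) {
      skipped <- skipped + 1L
      next
    }
    x <- (times[sel] - t0) / cycle_dur
    y <- log_mua[sel] / level_span
    slope <- stats::cov(x, y) / stats::var(x)
    angles[k] <- atan(slope) * 180 / pi
  }
  if (skipped > 0L)
    warning(skipped, " transition(s) skipped: fit window outside recording")
  if (all(is.na(angles))) stop("all transitions skipped")
  mean(angles, na.rm = TRUE)
}

#' Up-state band power (Welch)
#'
#' Welch power spectral density over Up-state epochs: each epoch at least as
#' long as the Welch segment is framed into 50%-overlapping Hann segments,
#' periodograms are pooled across all epochs, and band power is the mean
#' density over the band's bins. Shorter epochs are dropped.
#'
#' @param rec an [recording()].
#' @param seg a `state_segmentation`.
#' @param bands named list of `(low, high)` bands, Hz.
#' @param welch_segment segment length, s.
#' @param label which state to analyze (default `"Up"`).
#' @return matrix channels x bands, uV^2/Hz.
#' @export
up_state_psd <- function(rec, seg,
                         bands = list(alpha = c(8, 12), beta = c(15, 32),
                                      gamma = c(32, 100)),
                         welch_segment = 0.25, label = "Up") {
  validate_recording(rec)
  nyq <- rec$fs / 2
  for (b in bands)
    if (b[2] >= nyq) stop("band above Nyquist")
  seg_len <- round(welch_segment * rec$fs)
  n_ch <- nrow(rec$signals)
  out <- matrix(NA_real_, n_ch, length(bands),
                dimnames = list(rec$channel_ids, names(bands)))
  for (i in seq_len(n_ch)) {
    iv <- seg$intervals[[min(i, length(seg$intervals))]]
    ep <- iv[iv$label == label, , drop = FALSE]
    acc <- NULL
    total <- 0
    for (k in seq_len(nrow(ep))) {
      i0 <- max(1L, round((ep$start[k] - rec$t0) * rec$fs) + 1L)
      i1 <- min(ncol(rec$signals), round((ep$end[k] - rec$t0) * rec$fs))
      if (i1 - i0 + 1L < seg_len) next
      w <- welch_psd(rec$signals[i, i0:i1], rec$fs, seg_len)
      acc <- if (is.null(acc)) w$power * w$n_segments
             else acc + w$power * w$n_segments
      total <- total + w$n_segments
      freqs <- w$freqs
    }
    if (total == 0) stop("Up-state epochs too short for the Welch segment")
    dens <- acc / total
    for (b in seq_along(bands)) {
      sel <- freqs >= bands[[b]][1] & freqs <= bands[[b]][2]
      out[i, b] <- mean(dens[sel])
    }
  }
  out
}

#' Task-initiation-normalized firing-rate timecourse
#'
#' Windowed mean MUA from task start, divided by the mean in the initial
#' window, so the timecourse is 1 at initiation. Used to compare firing-rate
#' evolution between groups during a behavioural task.
#'
#' @param mua an `mua_trace`.
#' @param t_task_start task initiation time, s.
#' @param window window length, s.
#' @return list with `times` (window centres), `per_channel` (channels x
#'   windows) and `grand` (channel average).
#' @export
task_normalized_fr <- function(mua, t_task_start, window) {
  if (t_task_start + window > max(mua$times))
    stop("recording does not cover the first task window")
  edges <- seq(t_task_start, max(mua$times), by = window)
  if (length(edges) < 2L) stop("recording does not cover the first task window")
  nwin <- length(edges) - 1L
  n_ch <- nrow(mua$mua)
  tc <- matrix(NA_real_, n_ch, nwin)
  for (w in seq_len(nwin)) {
    sel <- mua$times >= edges[w] & mua$times < edges[w + 1L]
    tc[, w] <- rowMeans(mua$mua[, sel, drop = FALSE])
  }
  if (any(tc[, 1L] == 0)) stop("zero baseline window")
  tc <- tc / tc[, 1L]
  list(times = (edges[-1L] + edges[-length(edges)]) / 2,
       per_channel = tc, grand = colMeans(tc))
}
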