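#' Synthetic recording configuration
#'
#' Parameters of the statistical LFP generator. The generator does not model
#' membrane or synaptic biophysics; it produces signals with exactly the
#' statistical features the analysis stages measure, each under independent
#' control:
#' bistable Up/Down alternation with gamma-distributed durations, a smoothed
#' two-level slow LFP component, gamma-band oscillation confined to Up
#' states, high-band (200-1500 Hz) Gaussian noise whose standard deviation is
#' proportional to a firing-rate parameter, a 1/f background, per-channel
#' gains, wavefronts propagating across the electrode array, and
#' block-structured inter-channel correlation.
#'
#' @param n_channels number of channels.
#' @param geometry an [electrode_geometry()]; default a linear depth probe at
#'   0.1 mm pitch (16 electrodes) or, when `n_channels == 32`, an 8 x 4
#'   surface grid at 0.55 mm pitch.
#' @param fs sampling rate, Hz.
#' @param duration recording length, s.
#' @param up_mean,down_mean mean Up/Down state durations, s.
#' @param up_cv,down_cv coefficients of variation of the durations (0 gives a
#'   strictly periodic oscillation).
#' @param slow_amp amplitude of the two-level slow LFP component, microvolts.
#' @param rise_time Gaussian smoothing sigma of the slow component, s.
#' @param polarity sign of the Up-state slow deflection (-1: negative at
#'   depth, the default).
#' @param gamma_freq gamma oscillation frequency, Hz.
#' @param gamma_amp_up gamma amplitude during Up states, microvolts.
#' @param hf_rate_up,hf_rate_down dimensionless firing-rate levels; the
#'   high-band component's standard deviation is `hf_amp * rate`, so band
#'   *power* scales with `rate^2`.
#' @param hf_amp high-band amplitude scale, microvolts.
#' @param one_over_f_amp standard deviation of the power-law (1/f-family)
#'   background, microvolts.
#' @param one_over_f_exponent power-spectrum slope of the background
#'   (default 2, the steep coloring typical of cortical LFP above a few Hz;
#'   1 gives classic pink noise). The steep default keeps the background out
#'   of the 200-1500 Hz band while still dominating low frequencies.
#' @param channel_gains scalar or per-channel multiplicative gains.
#' @param wave_mode `"planar"`, `"radial"`, or `"none"`.
#' @param wave_speed propagation speed, mm/s.
#' @param wave_directions planar propagation directions in degrees; waves
#'   cycle through them (default two opposed directions).
#' @param wave_origin radial origin `(x, y)` in mm; default the array centre.
#' @param module_assignment integer community label per channel (`NULL`: all
#'   channels one community).
#' @param shared_fraction within-community common-signal mixing weight in
#'   [0, 1); the expected within-community Pearson correlation of the
#'   broadband background.
#' @param global_fraction common-signal weight shared by *all* channels in
#'   [0, 1), applied after the community mixing.
#'
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_channels = 16L, geometry = NULL, fs = 5000,
                         duration = 60,
                         up_mean = 0.4, down_mean = 0.85,
                         up_cv = 0.5, down_cv = 0.5,
                         slow_amp = 300, rise_time = 0.02, polarity = -1,
                         gamma_freq = 60, gamma_amp_up = 35,
                         hf_rate_up = 1.86, hf_rate_down = 1, hf_amp = 20,
                         one_over_f_amp = 40, one_over_f_exponent = 2,
                         channel_gains = 1,
                         wave_mode = c("none", "planar", "radial"),
                         wave_speed = 20,
                         wave_directions = c(0, 180), wave_origin = NULL,
                         module_assignment = NULL,
                         shared_fraction = 0, global_fraction = 0) {
  wave_mode <- match.arg(wave_mode)
  if (is.null(geometry)) {
    geometry <- if (n_channels == 32L) grid_geometry(8L, 4L, 0.55)
                else linear_probe_geometry(n_channels, 0.1)
  }
  if (nrow(geometry$positions) != n_channels)
    stop("geometry must have one electrode per channel")
  if (length(channel_gains) == 1L)
    channel_gains <- rep(channel_gains, n_channels)
  if (length(channel_gains) != n_channels)
    stop("channel_gains must be scalar or one per channel")
  if (is.null(module_assignment)) module_assignment <- rep(1L, n_channels)
  if (length(module_assignment) != n_channels)
    stop("module_assignment must have one label per channel")
  cfg <- structure(list(
    n_channels = as.integer(n_channels), geometry = geometry, fs = fs,
    duration = duration, up_mean = up_mean, down_mean = down_mean,
    up_cv = up_cv, down_cv = down_cv, slow_amp = slow_amp,
    rise_time = rise_time, polarity = polarity,
    gamma_freq = gamma_freq, gamma_amp_up = gamma_amp_up,
    hf_rate_up = hf_rate_up, hf_rate_down = hf_rate_down, hf_amp = hf_amp,
    one_over_f_amp = one_over_f_amp,
    one_over_f_exponent = one_over_f_exponent,
    channel_gains = channel_gains,
    wave_mode = wave_mode, wave_speed = wave_speed,
    wave_directions = wave_directions, wave_origin = wave_origin,
    module_assignment = module_assignment,
    shared_fraction = shared_fraction, global_fraction = global_fraction
  ), class = "synth_config")
  stopifnot(cfg$fs > 0, cfg$duration > 0,
            cfg$up_mean > 0, cfg$down_mean > 0,
            cfg$up_cv >= 0, cfg$down_cv >= 0,
            cfg$slow_amp >= 0, cfg$gamma_amp_up >= 0, cfg$hf_amp >= 0,
            cfg$hf_rate_up >= 0, cfg$hf_rate_down >= 0,
            cfg$one_over_f_amp >= 0)
  if (cfg$shared_fraction < 0 || cfg$shared_fraction >= 1 ||
      cfg$global_fraction < 0 || cfg$global_fraction >= 1)
    stop("shared/global fractions must lie in [0, 1)")
  if (cfg$gamma_amp_up > 0 && cfg$gamma_freq >= fs / 2)
    stop("gamma_freq at or above Nyquist for this sampling rate")
  cfg
}

#' Draw an alternating Up/Down state sequence
#'
#' Durations are gamma-distributed with the configured mean and coefficient
#' of variation (`shape = 1/cv^2`, `scale = mean * cv^2`); `cv = 0` gives
#' fixed durations. The sequence starts in a Down state and is truncated at
#' `duration`. Consumes the session RNG; seed upstream for reproducibility.
#'
#' @param duration total length, s.
#' @param up_mean,down_mean,up_cv,down_cv duration statistics.
#' @return data.frame with columns `label` ("Up"/"Down"), `start`, `end` (s);
#'   intervals tile `[0, duration]` with alternating labels.
#' @export
sample_state_sequence <- function(duration, up_mean = 0.4, down_mean = 0.85,
                                  up_cv = 0.5, down_cv = 0.5) {
  if (duration < up_mean + down_mean)
    stop("duration shorter than one mean Up/Down cycle")
  draw <- function(n, mean, cv) {
    if (cv == 0) rep(mean, n)
    else stats::rgamma(n, shape = 1 / cv^2, scale = mean * cv^2)
  }
  n_guess <- ceiling(2 * duration / (up_mean + down_mean)) + 10L
  repeat {
    downs <- draw(n_guess, down_mean, down_cv)
    ups <- draw(n_guess, up_mean, up_cv)
    durs <- as.vector(rbind(downs, ups))   # Down, Up, Down, Up, ...
    ends <- cumsum(durs)
    if (ends[length(ends)] >= duration) break
    n_guess <- n_guess * 2L
  }
  k <- which(ends >= duration)[1L]
  durs <- durs[seq_len(k)]
  ends <- ends[seq_len(k)]
  ends[k] <- duration
  starts <- c(0, ends[-k])
  keep <- ends > starts
  data.frame(
    label = rep(c("Down", "Up"), length.out = k)[keep],
    start = starts[keep], end = ends[keep]
  )
}

# Rectangular state indicator sampled at fs: 1 in Up, 0 in Down.
state_indicator <- function(states, fs, duration) {
  n <- round(duration * fs)
  up <- states[states$label == "Up", , drop = FALSE]
  ind <- numeric(n)
  i0 <- pmax(1L, pmin(n, ceiling(up$start * fs + 0.5)))
  i1 <- pmax(1L, pmin(n, ceiling(up$end * fs - 0.5)))
  for (i in seq_len(nrow(up))) {
    if (i1[i] >= i0[i]) ind[i0[i]:i1[i]] <- 1
  }
  ind
}

# Power-law background noise via spectral shaping, unit variance; exponent
# is the power-spectrum slope (2 = Brownian-like, typical of LFP above a
# few Hz).
pink_noise <- function(n, fs, exponent = 2, f_floor = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]     # mirror for negative frequencies
  shape <- pmax(f, f_floor)^(-exponent / 2)
  shape[1L] <- 0
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Phase-randomized surrogate: same amplitude spectrum, scrambled phases.
phase_randomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq(2L, ceiling((n + 1L) / 2))
  ph <- stats::runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  # enforce conjugate symmetry for a real output
  mirror <- n + 2L - half
  ok <- mirror > max(half)
  X[mirror[ok]] <- Conj(X[half][ok])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize one LFP channel from a state sequence
#'
#' The trace is the sum of: a smoothed two-level slow component (Up level
#' `polarity * slow_amp`), a gamma sinusoid with per-state random phase
#' present only during Up states, high-band (200-1500 Hz bandpassed) Gaussian
#' noise with standard deviation `hf_amp * hf_rate` of the current state, and
#' a 1/f background; the whole trace is multiplied by `gain`. Consumes the
#' session RNG.
#'
#' @param states state sequence from [sample_state_sequence()].
#' @param cfg a [synth_config()].
#' @param gain channel gain multiplier.
#' @param components if `TRUE`, return the list of components instead of
#'   their sum (used by [simulate_recording()] to mix backgrounds without
#'   touching the slow wave).
#' @return numeric vector (microvolts), or a list of component vectors.
#' @export
synthesize_channel <- function(states, cfg, gain = 1, components = FALSE) {
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 0.5) / fs
  ind <- state_indicator(states, fs, cfg$duration)

  slow <- cfg$polarity * cfg$slow_amp *
    gauss_smooth(ind, cfg$rise_time * fs)

  gamma <- numeric(n)
  if (cfg$gamma_amp_up > 0) {
    up <- states[states$label == "Up", , drop = FALSE]
    i0 <- pmax(1L, pmin(n, ceiling(up$start * fs + 0.5)))
    i1 <- pmax(1L, pmin(n, ceiling(up$end * fs - 0.5)))
    for (i in seq_len(nrow(up))) {
      if (i1[i] < i0[i]) next
      sel <- i0[i]:i1[i]
      gamma[sel] <- cfg$gamma_amp_up *
        sin(2 * pi * cfg$gamma_freq * t[sel] + stats::runif(1, 0, 2 * pi))
    }
  }

  hf <- numeric(n)
  if (cfg$hf_amp > 0) {
    band_hi <- min(1500, 0.95 * fs / 2)
    if (fs / 2 <= 200)
      stop("fs too low for the 200-1500 Hz high band")
    raw <- bandpass_filtfilt(stats::rnorm(n), fs, 200, band_hi)
    raw <- raw / stats::sd(raw)
    rate <- cfg$hf_rate_down + (cfg$hf_rate_up - cfg$hf_rate_down) * ind
    hf <- cfg$hf_amp * rate * raw
  }

  pink <- if (cfg$one_over_f_amp > 0)
    cfg$one_over_f_amp * pink_noise(n, fs, cfg$one_over_f_exponent)
  else numeric(n)

  out <- list(slow = slow * gain, gamma = gamma * gain, hf = hf * gain,
              pink = pink * gain)
  if (components) out else out$slow + out$gamma + out$hf + out$pink
}

#' Propagate a state sequence across the array
#'
#' Each Down-to-Up transition (one wave) reaches channel `i` with lag
#' `proj(position_i, direction)/speed` (planar) or
#' `dist(position_i, origin)/speed` (radial); lags are recentred to zero mean
#' so the wave's mean time is unchanged. Planar waves cycle through
#' `cfg$wave_directions`. Shifted interval boundaries are nudged minimally if
#' a lag would make neighbouring states collide, and the *realized* lags are
#' returned as ground truth.
#'
#' @param states global state sequence.
#' @param geometry an [electrode_geometry()].
#' @param cfg a [synth_config()] with `wave_mode != "none"` and
#'   `wave_speed > 0`.
#' @return list with `channel_states` (per-channel interval data.frames) and
#'   `lag_matrix` (waves x channels, s).
#' @export
apply_propagation <- function(states, geometry, cfg) {
  if (cfg$wave_mode == "none") stop("wave_mode is 'none'")
  if (cfg$wave_speed <= 0) stop("wave_speed must be > 0")
  pos <- geometry$positions
  n_ch <- nrow(pos)
  up_idx <- which(states$label == "Up")
  n_waves <- length(up_idx)
  lag <- matrix(0, n_waves, n_ch)
  for (w in seq_len(n_waves)) {
    if (cfg$wave_mode == "planar") {
      ang <- cfg$wave_directions[((w - 1L) %% length(cfg$wave_directions)) + 1L]
      dir <- c(cos(ang * pi / 180), sin(ang * pi / 180))
      lag[w, ] <- (pos %*% dir) / cfg$wave_speed
    } else {
      origin <- cfg$wave_origin %||% colMeans(pos)
      lag[w, ] <- sqrt((pos[, 1] - origin[1])^2 +
                         (pos[, 2] - origin[2])^2) / cfg$wave_speed
    }
    lag[w, ] <- lag[w, ] - mean(lag[w, ])
  }
  eps <- 1 / cfg$fs
  channel_states <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    st <- states
    st$start[up_idx] <- st$start[up_idx] + lag[, i]
    st$end[up_idx] <- st$end[up_idx] + lag[, i]
    # keep boundaries ordered and inside the recording
    for (k in seq_len(nrow(st))[-1L]) {
      if (st$start[k] < st$end[k - 1L]) {
        mid <- st$start[k]
        if (states$label[k] == "Up") st$end[k - 1L] <- mid
        else st$start[k] <- st$end[k - 1L]
      }
      st$start[k] <- min(max(st$start[k], eps), cfg$duration - eps)
      st$end[k] <- min(max(st$end[k], st$start[k] + eps), cfg$duration)
      st$end[k - 1L] <- st$start[k]
    }
    st$start[1L] <- 0
    st$end[nrow(st)] <- cfg$duration
    # record the lags actually realized after collision handling
    lag[, i] <- st$start[up_idx] - states$start[up_idx]
    channel_states[[i]] <- st
  }
  # re-centre realized lags per wave
  lag <- lag - rowMeans(lag)
  list(channel_states = channel_states, lag_matrix = lag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mix a common signal into communities of channels
#'
#' Each channel becomes `sqrt(1 - f) * own + sqrt(f) * common`, where the
#' community's common signal is a phase-randomized surrogate of one of its
#' members (same spectrum, asymptotically uncorrelated with all originals),
#' rescaled to each channel's standard deviation. The expected within-
#' community Pearson correlation of previously independent channels is `f`;
#' across communities it stays ~0. Consumes the session RNG.
#'
#' @param traces channels x samples matrix.
#' @param module_assignment community label per channel.
#' @param shared_fraction mixing weight `f` in [0, 1).
#' @param common optional list of common-signal vectors, one per community
#'   level (overrides the surrogate construction).
#' @return mixed channels x samples matrix.
#' @export
mix_shared_signal <- function(traces, module_assignment, shared_fraction,
                              common = NULL) {
  f <- shared_fraction
  if (f < 0 || f >= 1) stop("shared_fraction must be in [0, 1)")
  if (length(module_assignment) != nrow(traces))
    stop("unknown community assignment length")
  if (f == 0) return(traces)
  labs <- unique(module_assignment)
  out <- traces
  for (li in seq_along(labs)) {
    members <- which(module_assignment == labs[li])
    c_sig <- if (!is.null(common)) {
      if (is.null(common[[li]])) stop("unknown community label")
      common[[li]]
    } else {
      phase_randomize(traces[members[1L], ])
    }
    c_sig <- c_sig / stats::sd(c_sig)
    for (i in members) {
      out[i, ] <- sqrt(1 - f) * traces[i, ] +
        sqrt(f) * stats::sd(traces[i, ]) * c_sig
    }
  }
  out
}

#' Simulate a full multichannel recording with ground truth
#'
#' Pipeline: draw the global state sequence; propagate it across the array
#' (unless `wave_mode = "none"`); synthesize each channel's components from
#' its shifted states; mix the broadband background (gamma + high band + 1/f)
#' within communities (`shared_fraction`) and then across all channels
#' (`global_fraction`); add the slow component and apply channel gains. The
#' slow wave is left out of the mixing so that state timing stays exactly as
#' recorded in the ground truth.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; the same (cfg, seed) always yields identical
#'   arrays.
#' @param metadata metadata list stored in the recording.
#' @return list with `recording` (an [recording()] object) and `truth`:
#'   `state_intervals` (per channel), `transition_times` (per-channel
#'   Down-to-Up times), `wave_lags` (waves x channels or NULL), `partition`
#'   (community labels).
#' @examples
#' sim <- simulate_recording(synth_config(n_channels = 4, duration = 10), seed = 1)
#' sim$recording
#' @export
simulate_recording <- function(cfg, seed = 1L, metadata = list()) {
  with_seed(seed, {
    states <- sample_state_sequence(cfg$duration, cfg$up_mean, cfg$down_mean,
                                    cfg$up_cv, cfg$down_cv)
    if (cfg$wave_mode != "none") {
      prop <- apply_propagation(states, cfg$geometry, cfg)
      channel_states <- prop$channel_states
      wave_lags <- prop$lag_matrix
    } else {
      channel_states <- rep(list(states), cfg$n_channels)
      wave_lags <- NULL
    }
    n <- round(cfg$duration * cfg$fs)
    slow <- matrix(0, cfg$n_channels, n)
    noise <- matrix(0, cfg$n_channels, n)
    for (i in seq_len(cfg$n_channels)) {
      comp <- synthesize_channel(channel_states[[i]], cfg, gain = 1,
                                 components = TRUE)
      slow[i, ] <- comp$slow
      noise[i, ] <- comp$gamma + comp$hf + comp$pink
    }
    if (cfg$shared_fraction > 0)
      noise <- mix_shared_signal(noise, cfg$module_assignment,
                                 cfg$shared_fraction)
    if (cfg$global_fraction > 0)
      noise <- mix_shared_signal(noise, rep(1L, cfg$n_channels),
                                 cfg$global_fraction)
    signals <- (slow + noise) * cfg$channel_gains
    rec <- recording(signals, cfg$fs, geometry = cfg$geometry,
                     metadata = metadata)
    truth <- list(
      state_intervals = channel_states,
      transition_times = lapply(channel_states, function(st)
        st$start[st$label == "Up"]),
      wave_lags = wave_lags,
      partition = cfg$module_assignment
    )
    list(recording = rec, truth = truth)
  })
}

#' Cohort presets
#'
#' Group-level generator settings for a wild-type-like ("WT") and a
#' Williams-Beuren-syndrome-model-like ("WBS") cohort. Mean state durations
#' and their CVs follow the respective group means of the anesthetized
#' recordings (Up 0.39/0.40 s, Down 0.82/0.89 s, CV Up 0.51/0.63, CV Down
#' 0.49/0.60); high-band rate levels are set so the Up/Down band-power ratio
#' matches the groups' relative firing rates (0.69/0.20 vs 0.53/0.24); gamma
#' amplitude is set so Up-state gamma-band density lands near 9 vs 6
#' uV^2/Hz. The WBS-like preset additionally carries a larger *global*
#' common-signal fraction, which raises pairwise correlations across the
#' whole array and therefore lowers modularity and shortens weighted path
#' lengths, reproducing the reported connectivity phenotype.
#'
#' @param preset `"WT"` or `"WBS"`.
#' @return named list of [synth_config()] overrides.
#' @export
cohort_preset <- function(preset = c("WT", "WBS")) {
  preset <- match.arg(preset)
  base <- list(
    fs = 5000, gamma_freq = 60, hf_amp = 20, hf_rate_down = 1,
    one_over_f_amp = 40, slow_amp = 300,
    shared_fraction = 0.35, wave_speed = 20
  )
  if (preset == "WT") {
    c(base, list(up_mean = 0.39, down_mean = 0.82, up_cv = 0.51,
                 down_cv = 0.49, hf_rate_up = sqrt(0.69 / 0.20),
                 gamma_amp_up = 35, global_fraction = 0.10))
  } else {
    c(base, list(up_mean = 0.40, down_mean = 0.89, up_cv = 0.63,
                 down_cv = 0.60, hf_rate_up = sqrt(0.53 / 0.24),
                 gamma_amp_up = 28.6, global_fraction = 0.35))
  }
}

#' Generate a cohort of synthetic animals
#'
#' Per-animal parameters are jittered around the preset means by 5%
#' multiplicative lognormal noise (jitter RNG seeded from `(seed, animal)`),
#' creating between-animal variance for group statistics. `type = "depth"`
#' gives 16-channel linear-probe recordings without horizontal propagation
#' (the probe samples one column); `type = "surface"` gives 32-channel grid
#' recordings with planar waves and a two-community (anterior/posterior)
#' correlation structure.
#'
#' @param preset `"WT"` or `"WBS"` (see [cohort_preset()]).
#' @param n_animals cohort size.
#' @param seed integer master seed; the full cohort is reproducible from it.
#' @param type `"depth"` or `"surface"`.
#' @param duration per-recording length, s.
#' @param n_channels channels per depth probe (default 16; e.g. 4 to
#'   simulate only the mid-depth channels that feed the group table).
#'   Surface arrays are always 32 channels.
#' @param jitter_sd lognormal sdlog of the per-animal parameter jitter.
#' @return list of per-animal `list(recording, truth)` as returned by
#'   [simulate_recording()].
#' @export
generate_cohort <- function(preset = c("WT", "WBS"), n_animals, seed = 1L,
                            type = c("depth", "surface"), duration = 60,
                            n_channels = 16L, jitter_sd = 0.05) {
  preset <- match.arg(preset)
  type <- match.arg(type)
  if (n_animals < 1) stop("n_animals must be >= 1")
  pars <- cohort_preset(preset)
  jitter_fields <- c("up_mean", "down_mean", "up_cv", "down_cv",
                     "hf_rate_up", "gamma_amp_up")
  lapply(seq_len(n_animals), function(a) {
    sd_a <- child_seed(seed, a)
    p <- with_seed(sd_a, {
      p <- pars
      for (f in jitter_fields)
        p[[f]] <- p[[f]] * stats::rlnorm(1, 0, jitter_sd)
      p
    })
    cfg_args <- c(
      if (type == "depth") {
        list(n_channels = as.integer(n_channels),
             geometry = linear_probe_geometry(as.integer(n_channels), 0.1),
             wave_mode = "none")
      } else {
        grid <- grid_geometry(8L, 4L, 0.55)
        list(n_channels = 32L, geometry = grid, wave_mode = "planar",
             module_assignment = as.integer(grid$positions[, 1] >=
                                              stats::median(grid$positions[, 1])) + 1L)
      },
      list(duration = duration), p)
    sim <- simulate_recording(do.call(synth_config, cfg_args),
                              seed = child_seed(sd_a, 1L),
                              metadata = list(animal = paste0(preset, a),
                                              group = preset, type = type))
    sim
  })
}
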