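test_that("threshold lands in the valley of a bimodal log-MUA mixture", {
  set.seed(21)
  x <- c(rnorm(5000, -2, 0.3), rnorm(5000, 0, 0.3))
  thr <- choose_threshold(x)
  expect_lt(abs(thr - (-1)), 0.15)
  expect_error(choose_threshold(rep(1, 100)), "bistability")
})

test_that("noiseless square-wave log MUA is recovered exactly", {
  step <- 0.001
  # 0.4 s high / 0.85 s low, repeated
  one_cycle <- c(rep(-2, 850), rep(0, 400))
  lm <- rep(one_cycle, 12)
  mua <- make_mua(lm, step = step)
  iv <- detect_states(mua$log_mua[1, ], mua$times, threshold = -1)
  ups <- iv[iv$label == "Up", ]
  ups <- ups[-nrow(ups), ]
  expect_lt(max(abs((ups$end - ups$start) - 0.4)), step + 1e-9)
  downs <- iv[iv$label == "Down", ]
  downs <- downs[2:(nrow(downs) - 1), ]
  expect_lt(max(abs((downs$end - downs$start) - 0.85)), step + 1e-9)
  # alternation and tiling
  expect_true(all(iv$label[-1] != iv$label[-nrow(iv)]))
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
})

test_that("glitches shorter than the refractory minimum are absorbed", {
  step <- 0.001
  lm <- rep(c(rep(-2, 850), rep(0, 400)), 10)
  base <- detect_states(lm, (seq_along(lm) - 0.5) * step, -1,
                        min_up = 0.05, min_down = 0.05)
  glitched <- lm
  glitched[3000:3001] <- 0.5   # 2 ms spike inside a Down state
  after <- detect_states(glitched, (seq_along(lm) - 0.5) * step, -1,
                         min_up = 0.05, min_down = 0.05)
  expect_equal(after, base)
})

test_that("SO metrics reproduce hand-computed frequency and CV values", {
  # strictly periodic 0.4/0.85 -> so_freq exactly 0.8 Hz, zero CVs
  step <- 0.001
  lm <- rep(c(rep(-2, 850), rep(0, 400)), 15)
  mua <- make_mua(lm, step = step)
  seg <- segment_recording(mua, smooth = 0, threshold = -1)
  m <- so_metrics(seg, mua)
  expect_equal(m$so_freq, 0.8, tolerance = 1e-6)
  expect_equal(m$cv_up, 0, tolerance = 1e-6)
  expect_equal(m$cv_down, 0, tolerance = 1e-6)
  expect_equal(m$cv_so, 0, tolerance = 1e-6)
  expect_equal(m$up_fr_rel, exp(2), tolerance = 1e-3)

  # Down durations {0.5, 1.0, 1.5}: population CV = 0.4082/1.0
  lens <- c(500, 1000, 1500)
  lm2 <- c(rep(-2, 700), unlist(lapply(lens, function(l)
    c(rep(0, 300), rep(-2, l)))), rep(0, 300), rep(-2, 700))
  mua2 <- make_mua(lm2, step = step)
  seg2 <- segment_recording(mua2, smooth = 0, threshold = -1)
  m2 <- so_metrics(seg2, mua2)
  expect_equal(m2$cv_down, cv_oracle(c(0.5, 1.0, 1.5)), tolerance = 0.01)
  expect_equal(m2$cv_down, 0.4082, tolerance = 0.01)

  # time rescaling: CVs unchanged, so_freq halved
  mua3 <- make_mua(lm, step = 2 * step)
  seg3 <- segment_recording(mua3, smooth = 0, threshold = -1)
  m3 <- so_metrics(seg3, mua3)
  expect_equal(m3$cv_down, m$cv_down, tolerance = 1e-6)
  expect_equal(m3$so_freq, m$so_freq / 2, tolerance = 1e-6)
})

test_that("upward slope follows the arctangent of the standardized rise", {
  step <- 0.001
  # linear ramp rising one standardized unit over one cycle unit -> 45 deg
  cyc <- 1
  ramp_len <- 1000   # 1 s rise
  lm <- c(rep(0, 1000), seq(0, 1, length.out = ramp_len), rep(1, 1000))
  times <- (seq_along(lm) - 0.5) * step
  a <- upward_slope(lm, times, transitions = 1.5, fit_window = 0.2,
                    cycle_dur = cyc, level_span = 1)
  expect_equal(a, 45, tolerance = 0.5)

  # half the rise per unit time -> atan(0.5) ~ 26.57 deg
  lm2 <- c(rep(0, 1000), seq(0, 0.5, length.out = ramp_len), rep(0.5, 1000))
  a2 <- upward_slope(lm2, times, transitions = 1.5, fit_window = 0.2,
                     cycle_dur = cyc, level_span = 1)
  expect_equal(a2, atan(0.5) * 180 / pi, tolerance = 0.5)

  # instantaneous step approaches the 90 degree limit
  lm3 <- c(rep(0, 1500), rep(1, 1500))
  a3 <- upward_slope(lm3, times, transitions = 1.5, fit_window = 0.01,
                     cycle_dur = 1.25, level_span = 1)
  expect_gt(a3, 85)

  # out-of-range transitions are skipped with a warning; all skipped errors
  expect_warning(
    upward_slope(lm, times, transitions = c(1.5, 10), fit_window = 0.2,
                 cycle_dur = 1, level_span = 1), "skipped")
  expect_error(
    suppressWarnings(upward_slope(lm, times, transitions = 10,
                                  fit_window = 0.2, cycle_dur = 1,
                                  level_span = 1)), "skipped")
})

test_that("Up-state Welch band power recovers a known sinusoid", {
  fs <- 1000
  dur <- 40
  st <- sample_state_sequence(dur, up_cv = 0, down_cv = 0,
                              up_mean = 0.5, down_mean = 0.5)
  ind <- slowwave:::state_indicator(st, fs, dur)
  t <- (seq_len(dur * fs) - 0.5) / fs
  A <- 10
  set.seed(2)
  sig <- A * sin(2 * pi * 40 * t) * ind + rnorm(dur * fs, sd = 0.1)
  rec <- recording(matrix(sig, nrow = 1), fs = fs)
  seg <- structure(list(intervals = list(st)), class = "state_segmentation")
  psd <- up_state_psd(rec, seg, welch_segment = 0.25)
  # expected mean gamma density: A^2/2 spread over the band's bins
  freqs <- seq(0, fs / 2, by = 4)
  nb <- sum(freqs >= 32 & freqs <= 100)
  expect_lt(abs(psd[1, "gamma"] / (A^2 / 2 / (nb * 4)) - 1), 0.15)
  expect_lt(psd[1, "alpha"], 0.05 * psd[1, "gamma"])
  expect_lt(psd[1, "beta"], 0.05 * psd[1, "gamma"])

  # power scales with amplitude squared
  rec2 <- recording(matrix(2 * A * sin(2 * pi * 40 * t) * ind +
                             rnorm(dur * fs, sd = 0.1), nrow = 1), fs = fs)
  psd2 <- up_state_psd(rec2, seg, welch_segment = 0.25)
  expect_lt(abs(psd2[1, "gamma"] / (4 * psd[1, "gamma"]) - 1), 0.10)

  expect_error(up_state_psd(rec, seg, bands = list(g = c(400, 600))),
               "Nyquist")
})

test_that("task-normalized firing rate is 1 at initiation and tracks drops", {
  mua <- make_mua(log(matrix(1, 2, 20000)), step = 0.001, n_channels = 2)
  tc <- task_normalized_fr(mua, t_task_start = 1, window = 2)
  expect_equal(tc$grand, rep(1, length(tc$grand)), tolerance = 1e-9)

  vals <- c(rep(1, 5000), rep(0.5, 15000))
  mua2 <- make_mua(log(rbind(vals, vals)), step = 0.001, n_channels = 2)
  tc2 <- task_normalized_fr(mua2, t_task_start = 1, window = 2)
  expect_equal(tc2$grand[1], 1, tolerance = 1e-9)
  expect_equal(tail(tc2$grand, 1), 0.5, tolerance = 1e-9)

  expect_error(task_normalized_fr(mua, t_task_start = 25, window = 2),
               "cover")
})

test_that("windowed rank tests flag a 20% firing-rate deficit across animals", {
  set.seed(47)
  # 5 + 5 animals; group B drops 20% after task initiation
  course <- function(drop) {
    lvl <- c(rep(1, 2000), rep(1 - drop, 18000)) *
      exp(rnorm(20000, 0, 0.05))
    tc <- task_normalized_fr(make_mua(log(matrix(lvl, 1))), 0, window = 2)
    tc$grand
  }
  a <- t(replicate(5, course(0)))
  b <- t(replicate(5, course(0.2)))
  post <- 3:ncol(a)   # windows fully after initiation
  p <- vapply(post, function(w)
    mann_whitney_u(a[, w], b[, w])$p, numeric(1))
  expect_gt(mean(p < 0.05), 0.5)
})
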