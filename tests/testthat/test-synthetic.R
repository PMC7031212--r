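test_that("state sequences tile the recording with alternating labels", {
  set.seed(7)
  for (i in 1:20) {
    dur <- runif(1, 20, 60)
    st <- sample_state_sequence(dur, up_mean = runif(1, 0.2, 0.6),
                                down_mean = runif(1, 0.5, 1.2),
                                up_cv = runif(1, 0, 0.8),
                                down_cv = runif(1, 0, 0.8))
    expect_equal(st$start[1], 0)
    expect_equal(st$end[nrow(st)], dur)
    expect_true(all(abs(st$start[-1] - st$end[-nrow(st)]) < 1e-12))
    expect_true(all(st$label[-1] != st$label[-nrow(st)]))
    expect_true(all(st$end > st$start))
  }
  expect_error(sample_state_sequence(0.5), "shorter than one")
})

test_that("zero-variance durations give a strictly periodic oscillation", {
  st <- sample_state_sequence(25, up_mean = 0.4, down_mean = 0.85,
                              up_cv = 0, down_cv = 0)
  ups <- st[st$label == "Up", ]
  expect_equal(unique(round(ups$end - ups$start, 9)), 0.4)
  cycle <- diff(ups$start)
  expect_equal(unique(round(cycle, 9)), 1.25)  # SO frequency 0.8 Hz
})

test_that("drawn durations match the configured mean and CV", {
  set.seed(11)
  # 1e4 cycles worth of sequence
  st <- sample_state_sequence(1.25 * 1e4, up_mean = 0.4, down_mean = 0.85,
                              up_cv = 0.5, down_cv = 0.5)
  ups <- st$end[st$label == "Up"] - st$start[st$label == "Up"]
  ups <- ups[-c(1, length(ups))]
  expect_lt(abs(mean(ups) / 0.4 - 1), 0.02)
  expect_lt(abs(cv_oracle(ups) / 0.5 - 1), 0.05)
})

test_that("identical config and seed reproduce identical recordings", {
  cfg <- synth_config(n_channels = 4L, duration = 10, wave_mode = "planar",
                      shared_fraction = 0.3,
                      module_assignment = c(1L, 1L, 2L, 2L))
  a <- simulate_recording(cfg, seed = 123)
  b <- simulate_recording(cfg, seed = 123)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$truth$wave_lags, b$truth$wave_lags)
  c2 <- simulate_recording(cfg, seed = 124)
  expect_false(identical(a$recording$signals, c2$recording$signals))
})

test_that("planar and radial propagation lags follow distance over speed", {
  st <- sample_state_sequence(30, up_cv = 0, down_cv = 0)
  # two electrodes 0.55 mm apart along the propagation direction, 10 mm/s
  geom <- electrode_geometry(cbind(x = c(0, 0.55), y = c(0, 0)))
  cfg <- synth_config(n_channels = 2L, geometry = geom, duration = 30,
                      wave_mode = "planar", wave_speed = 10,
                      wave_directions = 0)
  prop <- apply_propagation(st, geom, cfg)
  expect_equal(unname(prop$lag_matrix[, 2] - prop$lag_matrix[, 1]),
               rep(0.055, nrow(prop$lag_matrix)))
  expect_equal(rowMeans(prop$lag_matrix), rep(0, nrow(prop$lag_matrix)))

  # radial: equal lags on circles around the origin
  geom2 <- electrode_geometry(cbind(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1)))
  cfg2 <- synth_config(n_channels = 4L, geometry = geom2, duration = 30,
                       wave_mode = "radial", wave_speed = 10,
                       wave_origin = c(0, 0))
  prop2 <- apply_propagation(st, geom2, cfg2)
  expect_equal(max(apply(prop2$lag_matrix, 1, function(z) diff(range(z)))), 0)

  expect_error(apply_propagation(st, geom,
                                 synth_config(n_channels = 2L, geometry = geom,
                                              duration = 30,
                                              wave_mode = "none")),
               "none")
})

test_that("community mixing produces the prescribed correlation blocks", {
  set.seed(5)
  n <- 15000
  traces <- matrix(rnorm(32 * n), nrow = 32)
  assign <- rep(1:2, each = 16)

  # f = 0: untouched, off-diagonal correlations near zero
  expect_identical(mix_shared_signal(traces, assign, 0), traces)
  W0 <- correlation_matrix(traces)
  expect_lt(max(abs(W0[upper.tri(W0)])), 0.1)

  # f = 0.5: within-block mean ~0.5, between-block ~0
  mixed <- mix_shared_signal(traces, assign, 0.5)
  W <- correlation_matrix(mixed)
  within <- c(W[1:16, 1:16][upper.tri(W[1:16, 1:16])],
              W[17:32, 17:32][upper.tri(W[17:32, 17:32])])
  between <- W[1:16, 17:32]
  expect_lt(abs(mean(within) - 0.5), 0.05)
  expect_lt(abs(mean(between)), 0.05)

  # single community, f -> 0.99: near-delta correlation histogram
  high <- mix_shared_signal(traces, rep(1L, 32), 0.99)
  Wh <- correlation_matrix(high)
  expect_gt(min(Wh[upper.tri(Wh)]), 0.95)
  expect_lt(functional_complexity(Wh), 0.1)

  expect_error(mix_shared_signal(traces, assign[1:3], 0.5), "assignment")
})

test_that("each generator component matches its analytic variance", {
  base <- list(n_channels = 1L, geometry = linear_probe_geometry(1L, 0.1),
               duration = 60, up_cv = 0.3, down_cv = 0.3, rise_time = 0.005,
               hf_rate_up = 1, hf_rate_down = 1)
  zero <- list(slow_amp = 0, gamma_amp_up = 0, hf_amp = 0, one_over_f_amp = 0)

  one_component <- function(field, value, seed) {
    args <- c(base, modifyList(zero, setNames(list(value), field)))
    sim <- simulate_recording(do.call(synth_config, args), seed = seed)
    sim
  }

  # high band at equal rates: var = hf_amp^2
  sim <- one_component("hf_amp", 30, 1)
  expect_lt(abs(var(as.numeric(sim$recording$signals)) / 900 - 1), 0.05)

  # 1/f background: var = amp^2
  sim <- one_component("one_over_f_amp", 25, 2)
  expect_lt(abs(var(as.numeric(sim$recording$signals)) / 625 - 1), 0.05)

  # gamma: var = A^2/2 * realized Up fraction
  sim <- one_component("gamma_amp_up", 40, 3)
  iv <- sim$truth$state_intervals[[1]]
  p_up <- sum((iv$end - iv$start)[iv$label == "Up"]) / 60
  expect_lt(abs(var(as.numeric(sim$recording$signals)) /
                  (800 * p_up) - 1), 0.05)

  # slow two-level wave: var = amp^2 * p(1-p), smoothing nearly neutral
  sim <- one_component("slow_amp", 100, 4)
  iv <- sim$truth$state_intervals[[1]]
  p_up <- sum((iv$end - iv$start)[iv$label == "Up"]) / 60
  expect_lt(abs(var(as.numeric(sim$recording$signals)) /
                  (1e4 * p_up * (1 - p_up)) - 1), 0.05)
})

test_that("cohorts are reproducible and carry group metadata", {
  a <- generate_cohort("WT", 2, seed = 9, type = "depth", duration = 5)
  b <- generate_cohort("WT", 2, seed = 9, type = "depth", duration = 5)
  expect_identical(a[[1]]$recording$signals, b[[1]]$recording$signals)
  expect_identical(a[[2]]$recording$signals, b[[2]]$recording$signals)
  expect_false(identical(a[[1]]$recording$signals, a[[2]]$recording$signals))
  expect_equal(a[[1]]$recording$metadata$group, "WT")
  expect_error(generate_cohort("WT", 0, seed = 1), "n_animals")
})
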