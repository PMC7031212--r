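test_that("zero-phase Butterworth band filtering passes and stops correctly", {
  fs <- 1000
  t <- (seq_len(10 * fs) - 0.5) / fs
  x <- sin(2 * pi * 40 * t)
  rec <- recording(matrix(x, nrow = 1), fs = fs)

  inband <- preprocess_lfp(rec, fs, band = c(32, 50))$signals[1, ]
  core <- seq(2 * fs, 8 * fs)   # avoid filter edge transients
  # amplitude preserved within 5%
  amp <- sqrt(2 * mean(inband[core]^2))
  expect_lt(abs(amp - 1), 0.05)
  # zero net phase: projection onto quadrature is negligible (< 1 degree)
  phase <- atan2(2 * mean(inband[core] * cos(2 * pi * 40 * t[core])),
                 2 * mean(inband[core] * sin(2 * pi * 40 * t[core])))
  expect_lt(abs(phase) * 180 / pi, 1)

  # out-of-band: >= 40 dB attenuation through the alpha filter
  outband <- preprocess_lfp(rec, fs, band = c(8, 12))$signals[1, ]
  expect_lt(sqrt(mean(outband[core]^2)) / sqrt(mean(x[core]^2)), 0.01)

  # decimation far below Nyquist preserves the waveform
  t5 <- (seq_len(10 * 5000) - 0.5) / 5000
  rec5 <- recording(matrix(sin(2 * pi * 10 * t5), nrow = 1), fs = 5000)
  dec <- preprocess_lfp(rec5, 250)
  expect_equal(dec$fs, 250)
  tt <- (seq(1, length(t5), by = 20) - 0.5) / 5000
  core2 <- seq(250, length(tt) - 250)
  expect_gt(cor(dec$signals[1, core2], sin(2 * pi * 10 * tt[core2])), 0.999)

  expect_error(preprocess_lfp(rec, 100, band = c(32, 60)), "Nyquist")
})

test_that("correlation matrix honours exact duplicate/negation cases", {
  set.seed(17)
  x <- rnorm(2000)
  sig <- rbind(x, x, -x, rnorm(2000))
  W <- correlation_matrix(sig)
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], -1)
  expect_true(isSymmetric(W))
  expect_equal(diag(W), rep(1, 4), ignore_attr = TRUE)
  expect_error(correlation_matrix(rbind(x, rep(1, 2000))), "zero-variance")
})

test_that("distance conversion is 1/W with sub-floor edges absent", {
  W <- matrix(c(1, 1, 0.5, -0.3,
                1, 1, 0.02, 0.8,
                0.5, 0.02, 1, 0.6,
                -0.3, 0.8, 0.6, 1), 4, 4)
  D <- weight_to_distance(W, weight_floor = 0.05)
  expect_equal(D[1, 2], 1)
  expect_equal(D[1, 3], 2)
  expect_equal(D[1, 4], Inf)   # negative correlation: no edge
  expect_equal(D[2, 3], Inf)   # below the floor: no edge
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
})

test_that("Louvain matches exhaustive modularity on two disconnected cliques", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 1
  lv <- louvain_modularity(W, n_restarts = 5, seed = 3)
  # brute force over all 4140 partitions of 8 nodes
  parts <- all_partitions(8)
  qs <- vapply(parts, function(p) modularity_oracle(W, p), numeric(1))
  expect_equal(lv$Q, max(qs), tolerance = 1e-12)
  expect_equal(lv$Q, 0.5)    # two equal disconnected cliques
  expect_equal(length(unique(lv$partition)), 2)
  expect_true(all(lv$partition[1:4] == lv$partition[1]))
  expect_true(all(lv$partition[5:8] == lv$partition[5]))

  # complete uniform graph: no structure, Q ~ 0
  Wu <- matrix(0.5, 8, 8)
  diag(Wu) <- 1
  expect_lte(louvain_modularity(Wu, n_restarts = 5, seed = 3)$Q, 0.05)

  expect_error(louvain_modularity(diag(8), n_restarts = 2, seed = 1),
               "edges")
})

test_that("Louvain recovers a planted two-block partition", {
  planted <- rep(1:2, each = 16)
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    W <- matrix(0.1, 32, 32)
    W[1:16, 1:16] <- 0.6
    W[17:32, 17:32] <- 0.6
    noise <- matrix(runif(32 * 32, -0.05, 0.05), 32, 32)
    W <- W + (noise + t(noise)) / 2
    diag(W) <- 1
    lv <- louvain_modularity(W, n_restarts = 5, seed = s)
    same <- outer(lv$partition, lv$partition, `==`) ==
      outer(planted, planted, `==`)
    if (all(same)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("characteristic path length equals brute-force shortest paths", {
  # complete graph with W = 0.5: direct edges optimal, L = 2
  W <- matrix(0.5, 6, 6)
  diag(W) <- 1
  D <- weight_to_distance(W)
  expect_equal(characteristic_path_length(D)$L, 2)

  # 3-node line: d(1,3) through the middle = 4, L = 8/3
  W3 <- diag(3)
  W3[1, 2] <- W3[2, 1] <- 0.5
  W3[2, 3] <- W3[3, 2] <- 0.5
  pl <- characteristic_path_length(weight_to_distance(W3))
  expect_equal(pl$L, (2 + 4 + 2) / 3)
  expect_equal(pl$unreachable_fraction, 0)

  # oracle equivalence on 100 random graphs up to 10 nodes
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    A <- matrix(runif(n * n, -0.2, 1), n, n)
    W <- (A + t(A)) / 2
    diag(W) <- 1
    D <- weight_to_distance(W)
    got <- tryCatch(characteristic_path_length(D)$L, error = function(e) NA)
    want <- path_length_oracle(D)
    if (is.na(got)) expect_true(is.nan(want)) else expect_equal(got, want)
  }

  expect_error(characteristic_path_length(weight_to_distance(diag(4))),
               "disconnected")
})

test_that("functional complexity follows the deviation-from-uniform formula", {
  # delta distribution -> exactly 0
  Wd <- matrix(0.42, 10, 10)
  diag(Wd) <- 1
  expect_equal(functional_complexity(Wd), 0)

  # exactly uniform occupancy -> exactly 1 (16 nodes: 120 pairs, 6 per bin)
  M <- 20
  vals <- rep((seq_len(M) - 0.5) / M, each = 6)
  Wu <- diag(16)
  Wu[upper.tri(Wu)] <- vals
  Wu <- Wu + t(Wu) - diag(16)
  diag(Wu) <- 1
  expect_equal(functional_complexity(Wu, M), 1)

  # hand-computed two-spike histogram, M = 10: C = 1 - (10/18)*1.6 = 1/9
  W2 <- diag(4)
  W2[upper.tri(W2)] <- c(0.05, 0.05, 0.05, 0.95, 0.95, 0.95)
  W2 <- W2 + t(W2) - diag(4)
  diag(W2) <- 1
  expect_lt(abs(functional_complexity(W2, 10) - 1 / 9), 1e-9)

  # bounds on random matrices
  set.seed(29)
  for (i in 1:1000) {
    A <- matrix(runif(100, -1, 1), 10, 10)
    W <- (A + t(A)) / 2
    diag(W) <- 1
    C <- functional_complexity(W)
    expect_gte(C, 0)
    expect_lte(C, 1)
  }
})

test_that("band sweep localizes a band-limited shared signal", {
  set.seed(37)
  fs <- 1000
  n <- 30 * fs
  common <- bandpass <- signal::butter(4, c(50, 70) / (fs / 2), "pass")
  shared <- signal::filtfilt(bandpass, rnorm(n))
  sig <- matrix(rnorm(8 * n), 8, n)
  sig <- sig + 2 * matrix(rep(shared, each = 8), 8, n)
  rec <- recording(sig, fs = fs)
  sw <- band_sweep(rec, seed = 5)
  expect_equal(sw$band[which.max(sw$median_r)], "midgamma")
  others <- sw$median_r[!sw$band %in% "midgamma"]
  expect_gt(max(sw$median_r), 2 * max(others))
})

test_that("raising the shared fraction raises correlation and lowers L", {
  for (s in 1:10) {
    set.seed(s)
    traces <- matrix(rnorm(8 * 5000), 8, 5000)
    lo <- correlation_matrix(mix_shared_signal(traces, rep(1L, 8), 0.2))
    set.seed(s)
    traces <- matrix(rnorm(8 * 5000), 8, 5000)
    hi <- correlation_matrix(mix_shared_signal(traces, rep(1L, 8), 0.6))
    expect_gt(median(hi[upper.tri(hi)]), median(lo[upper.tri(lo)]))
    expect_lt(characteristic_path_length(weight_to_distance(hi))$L,
              characteristic_path_length(weight_to_distance(lo))$L)
  }
})
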