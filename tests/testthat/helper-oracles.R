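# Independent oracles and small fixture builders used across the suite.

# Brute-force all-pairs shortest paths (Floyd-Warshall) on a distance
# matrix with Inf marking absent edges.
floyd_warshall <- function(D) {
  n <- nrow(D)
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

path_length_oracle <- function(D) {
  sp <- floyd_warshall(D)
  off <- sp[row(sp) != col(sp)]
  mean(off[is.finite(off)])
}

# Newman-Girvan weighted modularity computed directly from the formula.
modularity_oracle <- function(W, membership, weight_floor = 0.05) {
  A <- W
  A[A <= weight_floor] <- 0
  diag(A) <- 0
  s <- sum(A)
  k <- rowSums(A)
  same <- outer(membership, membership, `==`)
  sum((A - outer(k, k) / s) * same) / s
}

# Enumerate all set partitions of n elements as membership vectors
# (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Direct 2D histogram entropy (independent binning implementation).
entropy2d_oracle <- function(x, y, k) {
  cut1 <- function(z) {
    r <- range(z)
    if (r[1] == r[2]) return(factor(rep(1L, length(z)), levels = 1L))
    br <- seq(r[1], r[2], length.out = k + 1L)
    cut(z, br, include.lowest = TRUE, labels = FALSE)
  }
  tab <- table(cut1(x), cut1(y))
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Minimal mua_trace object holding a given log-MUA series.
make_mua <- function(log_mua, step = 0.001, n_channels = 1L) {
  if (!is.matrix(log_mua)) log_mua <- matrix(log_mua, nrow = n_channels,
                                             byrow = TRUE)
  structure(list(
    mua = exp(log_mua), log_mua = log_mua,
    times = (seq_len(ncol(log_mua)) - 0.5) * step,
    band = c(200, 1500), window = step, step = step, averaging = "power",
    channel_ids = paste0("ch", seq_len(nrow(log_mua)))
  ), class = "mua_trace")
}

# Segmentation object built from generator ground-truth intervals.
truth_segmentation <- function(truth) {
  structure(list(intervals = truth$state_intervals,
                 threshold = rep(NA_real_, length(truth$state_intervals)),
                 smooth = 0,
                 channel_ids = paste0("ch", seq_along(truth$state_intervals))),
            class = "state_segmentation")
}

# Population-sd coefficient of variation (matches the package convention).
cv_oracle <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)
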