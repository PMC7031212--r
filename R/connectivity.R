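#' Frequency bands for connectivity analysis
#'
#' Named band edges in Hz: slow oscillation (0.1-1), alpha (8-12), beta
#' (15-32), low gamma (32-50), middle gamma (50-70), high gamma (70-100).
#'
#' @return named list of `(low, high)` pairs.
#' @export
so_bands <- function() {
  list(SO = c(0.1, 1), alpha = c(8, 12), beta = c(15, 32),
       lowgamma = c(32, 50), midgamma = c(50, 70), highgamma = c(70, 100))
}

#' Downsample and optionally band-filter a recording
#'
#' Anti-alias filtered decimation (zero-phase Butterworth low-pass at 80% of
#' the new Nyquist, integer decimation factor), followed, when `band` is
#' given, by a forward-backward (zero net phase) Butterworth bandpass.
#'
#' @param rec an [recording()].
#' @param downsample_to target sampling rate, Hz.
#' @param band optional `(low, high)` band, Hz; must sit below the new
#'   Nyquist.
#' @param order Butterworth order (applied forward-backward, so the
#'   effective attenuation order doubles).
#' @return list with `signals` (channels x samples) and `fs`.
#' @export
preprocess_lfp <- function(rec, downsample_to = 250, band = NULL,
                           order = 4L) {
  validate_recording(rec)
  if (downsample_to > rec$fs) stop("downsample_to exceeds the sampling rate")
  factor <- max(1L, floor(rec$fs / downsample_to))
  new_fs <- rec$fs / factor
  sig <- rec$signals
  if (factor > 1L) {
    lp <- signal::butter(order, 0.8 / factor, type = "low")
    sig <- t(apply(sig, 1L, function(x) signal::filtfilt(lp, x)))
    sig <- sig[, seq(1L, ncol(sig), by = factor), drop = FALSE]
  }
  if (!is.null(band)) {
    if (band[2] >= new_fs / 2)
      stop("band above Nyquist after downsampling")
    bf <- signal::butter(order, band / (new_fs / 2), type = "pass")
    sig <- t(apply(sig, 1L, function(x) signal::filtfilt(bf, x)))
  }
  list(signals = sig, fs = new_fs)
}

#' Pairwise Pearson correlation matrix
#'
#' @param signals channels x samples matrix (or a `preprocess_lfp()` result).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(signals) {
  if (is.list(signals)) signals <- signals$signals
  if (nrow(signals) < 2L) stop("need at least 2 channels")
  v <- apply(signals, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance channel(s): ", paste(which(v == 0), collapse = ", "))
  W <- stats::cor(t(signals))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

#' Compare correlation distributions between two groups
#'
#' Pools upper-triangle correlation values per group and compares the two
#' distributions with a two-sample Kolmogorov-Smirnov test; medians are
#' reported for the usual distribution plots.
#'
#' @param W_a,W_b correlation matrices (or lists of matrices, pooled).
#' @return list with `values_a`, `values_b`, `median_a`, `median_b`,
#'   `ks_D`, `ks_p`.
#' @export
correlation_distribution <- function(W_a, W_b) {
  pool <- function(W) {
    if (!is.list(W)) W <- list(W)
    unlist(lapply(W, function(m) m[upper.tri(m)]))
  }
  a <- pool(W_a)
  b <- pool(W_b)
  if (!length(a) || !length(b)) stop("empty upper triangle")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(values_a = a, values_b = b,
       median_a = stats::median(a), median_b = stats::median(b),
       ks_D = unname(ks$statistic), ks_p = ks$p.value)
}

#' Convert correlation weights to graph distances
#'
#' `D_ij = 1 / W_ij` for correlations above the weight floor; negative, zero
#' or floored correlations make the reciprocal meaningless as a distance, so
#' those edges are absent (`Inf`). The diagonal is 0.
#'
#' @param W correlation matrix.
#' @param weight_floor edges with `W <= weight_floor` are removed
#'   (default 0.05).
#' @return distance matrix, `Inf` marking absent edges.
#' @export
weight_to_distance <- function(W, weight_floor = 0.05) {
  D <- ifelse(W > weight_floor, 1 / W, Inf)
  diag(D) <- 0
  D
}

# Weighted graph from a floored correlation matrix (self-loops removed).
graph_from_w <- function(W, weight_floor = 0.05) {
  A <- W
  A[A <= weight_floor] <- 0
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
}

#' Louvain community detection on a correlation graph
#'
#' Best-of-`n_restarts` Louvain runs on the weighted graph built from the
#' floored correlation matrix; returns the partition with the highest
#' Newman-Girvan weighted modularity. Louvain is stochastic, hence the
#' restarts and the recorded seed.
#'
#' @param W correlation matrix.
#' @param n_restarts number of restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @param weight_floor see [weight_to_distance()].
#' @return list with `partition` (integer labels), `Q` (modularity),
#'   `n_restarts`, `seed`.
#' @export
louvain_modularity <- function(W, n_restarts = 20L, seed = 1L,
                               weight_floor = 0.05) {
  g <- graph_from_w(W, weight_floor)
  if (igraph::ecount(g) == 0L) stop("all-zero off-diagonal: no edges")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g)
      q <- igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight)
      if (is.null(best) || q > best$Q)
        best <- list(partition = as.integer(igraph::membership(cl)), Q = q)
    }
  })
  c(best, list(n_restarts = n_restarts, seed = seed))
}

#' Characteristic path length
#'
#' Mean shortest-path distance (Dijkstra on the finite entries of `D`) over
#' all reachable ordered pairs; the unreachable-pair fraction is reported
#' alongside, since absent edges can disconnect the graph.
#'
#' @param D distance matrix from [weight_to_distance()].
#' @return list with `L`, `unreachable_fraction`.
#' @export
characteristic_path_length <- function(D) {
  n <- nrow(D)
  A <- D
  A[is.infinite(A)] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  sp <- igraph::distances(g, weights = igraph::E(g)$weight,
                          algorithm = "dijkstra")
  off <- sp[row(sp) != col(sp)]
  reach <- is.finite(off)
  if (!any(reach)) stop("fully disconnected graph")
  list(L = mean(off[reach]), unreachable_fraction = mean(!reach))
}

#' Functional complexity of a correlation matrix
#'
#' Measures how broadly the pairwise correlation magnitudes are distributed:
#' with `p_m` the histogram of upper-triangle `|r|` values over `M` equal
#' bins on [0, 1],
#' `C = 1 - (M / (2 (M - 1))) * sum_m |p_m - 1/M|`.
#' A delta distribution (all mass in one bin) gives 0; exactly uniform
#' occupancy gives 1.
#'
#' @param W correlation matrix.
#' @param n_bins number of histogram bins `M` (default 20).
#' @return complexity in [0, 1].
#' @export
functional_complexity <- function(W, n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  r <- abs(W[upper.tri(W)])
  if (!length(r)) stop("empty upper triangle")
  idx <- pmin(floor(r * n_bins) + 1L, n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(r)
  1 - (n_bins / (2 * (n_bins - 1))) * sum(abs(p - 1 / n_bins))
}

#' Connectivity graph metrics for one recording
#'
#' Convenience wrapper: preprocess, correlate, floor, and compute partition,
#' modularity, path length and functional complexity.
#'
#' @param rec an [recording()].
#' @param band optional band, Hz (`NULL` = wideband).
#' @param downsample_to target rate for wideband analysis, Hz; band-filtered
#'   analyses decimate to 4x the band top.
#' @param weight_floor,n_restarts,seed,n_bins stage parameters.
#' @return `connectivity_graph`: list with `W`, `D`, `band`, `partition`,
#'   `Q`, `L`, `unreachable_fraction`, `C`, `median_r`.
#' @export
connectivity_graph <- function(rec, band = NULL, downsample_to = 250,
                               weight_floor = 0.05, n_restarts = 20L,
                               seed = 1L, n_bins = 20L) {
  target <- if (is.null(band)) downsample_to else max(4 * band[2], 20)
  pre <- preprocess_lfp(rec, min(target, rec$fs), band)
  W <- correlation_matrix(pre$signals)
  D <- weight_to_distance(W, weight_floor)
  lv <- louvain_modularity(W, n_restarts, seed, weight_floor)
  pl <- characteristic_path_length(D)
  structure(list(
    W = W, D = D, band = if (is.null(band)) "wideband" else band,
    partition = lv$partition, Q = lv$Q, L = pl$L,
    unreachable_fraction = pl$unreachable_fraction,
    C = functional_complexity(W, n_bins),
    median_r = stats::median(W[upper.tri(W)]),
    weight_floor = weight_floor
  ), class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d nodes, band %s: Q = %.3f, L = %.3f, C = %.3f, median r = %.3f\n",
              nrow(x$W), paste(x$band, collapse = "-"), x$Q, x$L, x$C,
              x$median_r))
  invisible(x)
}

#' Band-by-band connectivity sweep
#'
#' Runs the preprocess-correlate-metrics chain for each band and tabulates
#' modularity and path length per band.
#'
#' @param rec an [recording()].
#' @param bands named list of bands (default [so_bands()]).
#' @param ... passed to [connectivity_graph()].
#' @return data.frame with columns `band`, `Q`, `L`, `C`, `median_r`.
#' @export
band_sweep <- function(rec, bands = so_bands(), ...) {
  rows <- lapply(names(bands), function(nm) {
    cg <- connectivity_graph(rec, band = bands[[nm]], ...)
    data.frame(band = nm, Q = cg$Q, L = cg$L, C = cg$C,
               median_r = cg$median_r)
  })
  do.call(rbind, rows)
}
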