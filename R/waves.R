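#' Cluster Down-to-Up transitions into waves
#'
#' Transitions across channels occurring within `max_span` of a wave's
#' running mean time are merged into one wave (one transition per channel,
#' earliest first); waves detected on fewer than `min_channel_fraction` of
#' the channels are discarded. Per-wave lags are the transition times minus
#' the wave's mean time, so they have zero mean over participating channels;
#' channels without a transition in a wave are `NA` (missing, never imputed
#' as zero here).
#'
#' @param transition_times list of per-channel Down-to-Up transition times, s
#'   (e.g. `lapply(seg$intervals, function(iv) iv$start[iv$label == "Up"])`).
#' @param max_span maximum distance from the wave's running mean, s.
#' @param min_channel_fraction minimum participating-channel fraction.
#' @return `wave_set`: list with `lag_matrix` (waves x channels, s, NA =
#'   missing), `mean_time` (s per wave), `participation` (fraction per wave).
#'   Zero retained waves gives an empty matrix with a warning.
#' @export
cluster_waves <- function(transition_times, max_span = 0.25,
                          min_channel_fraction = 0.5) {
  n_ch <- length(transition_times)
  if (n_ch < 2L) stop("need transitions from at least 2 channels")
  ev <- data.frame(
    time = unlist(transition_times),
    channel = rep(seq_len(n_ch), lengths(transition_times))
  )
  ev <- ev[order(ev$time), , drop = FALSE]
  waves <- list()
  used <- rep(FALSE, nrow(ev))
  for (s in seq_len(nrow(ev))) {
    if (used[s]) next
    members <- s
    used[s] <- TRUE
    chans <- ev$channel[s]
    mean_t <- ev$time[s]
    k <- s
    while (k < nrow(ev)) {
      k <- k + 1L
      if (ev$time[k] - mean_t > max_span) break
      if (used[k] || ev$channel[k] %in% chans) next
      if (abs(ev$time[k] - mean_t) <= max_span) {
        members <- c(members, k)
        used[k] <- TRUE
        chans <- c(chans, ev$channel[k])
        mean_t <- mean(ev$time[members])
      }
    }
    waves[[length(waves) + 1L]] <- members
  }
  # "majority": participation must strictly exceed the fraction
  keep <- vapply(waves, function(m) length(m) / n_ch, numeric(1)) >
    min_channel_fraction
  waves <- waves[keep]
  if (!length(waves)) {
    warning("no wave meets the channel-participation criterion")
    return(structure(list(lag_matrix = matrix(numeric(0), 0, n_ch),
                          mean_time = numeric(0), participation = numeric(0)),
                     class = "wave_set"))
  }
  lag <- matrix(NA_real_, length(waves), n_ch)
  mt <- numeric(length(waves))
  for (w in seq_along(waves)) {
    m <- waves[[w]]
    mt[w] <- mean(ev$time[m])
    lag[w, ev$channel[m]] <- ev$time[m] - mt[w]
  }
  ord <- order(mt)
  structure(list(lag_matrix = lag[ord, , drop = FALSE], mean_time = mt[ord],
                 participation = lengths(waves)[ord] / n_ch),
            class = "wave_set")
}

#' @export
print.wave_set <- function(x, ...) {
  cat(sprintf("<wave_set> %d waves x %d channels, mean participation %.2f\n",
              nrow(x$lag_matrix), ncol(x$lag_matrix),
              if (length(x$participation)) mean(x$participation) else NA))
  invisible(x)
}

# Exact thin-plate spline in 2D: radial basis U(r) = r^2 log r plus an
# affine term, coefficients from the square interpolation system (zero
# smoothing penalty), so the surface passes through every datum and
# reproduces affine functions exactly.
tps_fit <- function(xy, v) {
  n <- nrow(xy)
  if (n < 4L) stop("insufficient support for 2D interpolation: need >= 4 points")
  if (qr(cbind(1, xy))$rank < 3L)
    stop("insufficient support for 2D interpolation: points are collinear")
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  d2 <- as.matrix(stats::dist(xy))^2
  K <- U(d2)
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, c(v, 0, 0, 0))
  list(w = coef[seq_len(n)], a = coef[n + 1:3], xy = xy, U = U)
}

tps_eval <- function(fit, px, py) {
  n <- nrow(fit$xy)
  out <- numeric(length(px))
  for (i in seq_len(n)) {
    r2 <- (px - fit$xy[i, 1])^2 + (py - fit$xy[i, 2])^2
    out <- out + fit$w[i] * fit$U(r2)
  }
  out + fit$a[1] + fit$a[2] * px + fit$a[3] * py
}

#' Interpolate a wave's time-lag field
#'
#' Exact thin-plate-spline interpolation (no smoothing) of the per-channel
#' lags over a regular grid spanning the electrode bounding box; the surface
#' passes through every observed lag to machine precision.
#'
#' @param lags per-channel lags, s (`NA` = channel missing from this wave).
#' @param geometry an [electrode_geometry()] (grid layout).
#' @param grid_resolution grid points per axis.
#' @return `timelag_field`: list with `grid_x`, `grid_y` (mm), `T`
#'   (lag surface, `length(grid_x)` x `length(grid_y)`, s), `fit`,
#'   `electrodes`, `lags`.
#' @export
interpolate_timelag_field <- function(lags, geometry, grid_resolution = 32L) {
  ok <- which(is.finite(lags))
  xy <- geometry$positions[ok, , drop = FALSE]
  fit <- tps_fit(xy, lags[ok])
  gx <- seq(min(geometry$positions[, 1]), max(geometry$positions[, 1]),
            length.out = grid_resolution)
  gy <- seq(min(geometry$positions[, 2]), max(geometry$positions[, 2]),
            length.out = grid_resolution)
  gg <- expand.grid(x = gx, y = gy)
  Tm <- matrix(tps_eval(fit, gg$x, gg$y), length(gx), length(gy))
  structure(list(grid_x = gx, grid_y = gy, T = Tm, fit = fit,
                 electrodes = xy, lags = lags[ok]),
            class = "timelag_field")
}

#' Propagation-speed map from a time-lag field
#'
#' Central-difference gradient of the interpolated lag surface on the
#' interior grid; speed is `V(x, y) = 1 / sqrt(Tx^2 + Ty^2)`. Points where
#' the gradient magnitude falls below `speed_floor` (default 1e-4 s/mm, i.e.
#' speeds above 10 m/s) are masked: speed is unbounded where the wavefront
#' is flat.
#'
#' @param field a `timelag_field`.
#' @param speed_floor minimum |gradient|, s/mm.
#' @return list with `V` (mm/s, NA where masked), `valid_mask`, and `speed`
#'   (median of `V` over the valid interior).
#' @export
speed_map <- function(field, speed_floor = 1e-4) {
  Tm <- field$T
  nx <- length(field$grid_x)
  ny <- length(field$grid_y)
  dx <- mean(diff(field$grid_x))
  dy <- mean(diff(field$grid_y))
  Tx <- Ty <- matrix(NA_real_, nx, ny)
  ix <- 2:(nx - 1)
  iy <- 2:(ny - 1)
  Tx[ix, iy] <- (Tm[ix + 1, iy] - Tm[ix - 1, iy]) / (2 * dx)
  Ty[ix, iy] <- (Tm[ix, iy + 1] - Tm[ix, iy - 1]) / (2 * dy)
  g <- sqrt(Tx^2 + Ty^2)
  valid <- is.finite(g) & g >= speed_floor
  if (!any(valid)) stop("flat lag field: all speed estimates masked")
  V <- matrix(NA_real_, nx, ny)
  V[valid] <- 1 / g[valid]
  list(V = V, valid_mask = valid, speed = stats::median(V[valid]))
}

#' Entropy of wavefront patterns in the PCA plane
#'
#' The lag matrix (waves x channels) is centred and projected onto its first
#' two principal components; the PC1-PC2 plane is partitioned into a
#' `bins` x `bins` occupancy grid spanning the data, and the Shannon entropy
#' (base 2) of the normalized occupancy histogram measures the diversity of
#' propagation patterns: 0 bits when every wave is identical, log2(k) bits
#' for k equally occupied well-separated clusters. The value depends on
#' `bins`, which is reported alongside.
#'
#' @param lag_matrix waves x channels, s. Waves with missing channels are
#'   excluded (`impute = "exclude"`, default) or column-mean imputed
#'   (`impute = "mean"`).
#' @param bins occupancy grid size per axis.
#' @param impute `"exclude"` or `"mean"`.
#' @return list with `entropy` (bits), `bins`, `n_waves`, `occupancy`.
#' @export
wave_pca_entropy <- function(lag_matrix, bins = 8L,
                             impute = c("exclude", "mean")) {
  impute <- match.arg(impute)
  M <- as.matrix(lag_matrix)
  if (impute == "mean") {
    for (j in seq_len(ncol(M))) {
      mj <- mean(M[, j], na.rm = TRUE)
      M[!is.finite(M[, j]), j] <- mj
    }
  } else {
    M <- M[stats::complete.cases(M), , drop = FALSE]
  }
  if (nrow(M) < 10L) stop("need at least 10 complete waves")
  M <- scale(M, center = TRUE, scale = FALSE)
  scores <- M %*% svd(M, nu = 0L, nv = 2L)$v
  occupancy <- bin2d_counts(scores[, 1], scores[, 2], bins)
  p <- occupancy / sum(occupancy)
  p <- p[p > 0]
  list(entropy = -sum(p * log2(p)), bins = bins, n_waves = nrow(M),
       occupancy = occupancy)
}

# K x K occupancy counts over the data extent; a degenerate (zero-range)
# axis collapses to one bin.
bin2d_counts <- function(x, y, k) {
  idx <- function(z) {
    r <- range(z)
    if (r[1] == r[2]) return(rep(1L, length(z)))
    i <- floor((z - r[1]) / (r[2] - r[1]) * k) + 1L
    pmin(i, k)
  }
  counts <- matrix(0L, k, k)
  ij <- cbind(idx(x), idx(y))
  for (r in seq_len(nrow(ij)))
    counts[ij[r, 1], ij[r, 2]] <- counts[ij[r, 1], ij[r, 2]] + 1L
  counts
}

#' Full wave-propagation analysis of a segmented recording
#'
#' Clusters Down-to-Up transitions into waves, interpolates each wave's lag
#' field, derives its speed map, and computes the PCA-plane entropy of the
#' wavefront patterns.
#'
#' @param seg a `state_segmentation`.
#' @param geometry an [electrode_geometry()] (grid layout).
#' @param max_span,min_channel_fraction see [cluster_waves()].
#' @param grid_resolution,speed_floor see [interpolate_timelag_field()],
#'   [speed_map()].
#' @param entropy_bins see [wave_pca_entropy()].
#' @return list with `wave_set`, `speeds` (per-wave median speed, mm/s),
#'   `mean_speed` (experiment average), `entropy` (bits or NA if too few
#'   complete waves).
#' @export
analyze_waves <- function(seg, geometry, max_span = 0.25,
                          min_channel_fraction = 0.5, grid_resolution = 32L,
                          speed_floor = 1e-4, entropy_bins = 8L) {
  tt <- lapply(seg$intervals, function(iv) iv$start[iv$label == "Up"])
  ws <- cluster_waves(tt, max_span, min_channel_fraction)
  speeds <- rep(NA_real_, nrow(ws$lag_matrix))
  for (w in seq_len(nrow(ws$lag_matrix))) {
    speeds[w] <- tryCatch({
      fld <- interpolate_timelag_field(ws$lag_matrix[w, ], geometry,
                                       grid_resolution)
      speed_map(fld, speed_floor)$speed
    }, error = function(e) NA_real_)
  }
  ent <- tryCatch(wave_pca_entropy(ws$lag_matrix, entropy_bins)$entropy,
                  error = function(e) NA_real_)
  list(wave_set = ws, speeds = speeds,
       mean_speed = mean(speeds, na.rm = TRUE), entropy = ent)
}
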