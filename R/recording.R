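#' Multichannel LFP recording
#'
#' Container for an extracellular recording: a channels-by-samples signal
#' matrix in microvolts, its sampling rate, and the electrode geometry needed
#' by the propagation and connectivity stages.
#'
#' @param signals numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channel_ids character or integer labels, one per signal row.
#'   Defaults to `"ch1" ... "chN"`.
#' @param t0 start time of the first sample, seconds.
#' @param geometry optional [electrode_geometry()] matched to `channel_ids`.
#' @param metadata free-form named list (animal id, group label `"WT"`/`"WBS"`,
#'   condition `"anesthetized"`/`"behaving"`, ...).
#'
#' @return An object of class `"so_recording"`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' rec
#' @export
recording <- function(signals, fs, channel_ids = NULL, t0 = 0,
                      geometry = NULL, metadata = list()) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  storage.mode(signals) <- "double"
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(signals)))
  rec <- structure(
    list(signals = signals, fs = fs, channel_ids = as.character(channel_ids),
         t0 = t0, geometry = geometry, metadata = metadata),
    class = "so_recording"
  )
  validate_recording(rec)
  rec
}

#' @export
print.so_recording <- function(x, ...) {
  cat(sprintf("<so_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  if (!is.null(x$geometry))
    cat(sprintf("  geometry: %s, spacing %g mm\n",
                x$geometry$layout, x$geometry$spacing))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validate a recording's invariants
#'
#' Checks matrix shape, sampling rate, channel labelling, finiteness, and
#' geometry/channel consistency. Called by every constructor and loader.
#'
#' @param rec an `so_recording`.
#' @return `rec`, invisibly; stops with an informative error otherwise.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "so_recording")) stop("not an so_recording object")
  if (is.null(rec$fs)) stop("format error: missing field 'fs'")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("invalid 'fs': must be a single positive number")
  if (!is.matrix(rec$signals) || nrow(rec$signals) < 1L ||
      ncol(rec$signals) < 1L)
    stop("'signals' must be a non-empty channels x samples matrix")
  if (length(rec$channel_ids) != nrow(rec$signals))
    stop("number of channel_ids must equal the number of signal rows")
  if (anyDuplicated(rec$channel_ids))
    stop("duplicate channel ids")
  bad <- which(!apply(rec$signals, 1L, function(z) all(is.finite(z))))
  if (length(bad))
    stop("validation error: non-finite samples in channels ",
         paste(rec$channel_ids[bad], collapse = ", "))
  if (!is.null(rec$geometry)) {
    validate_geometry(rec$geometry)
    if (nrow(rec$geometry$positions) != nrow(rec$signals))
      stop("geometry must have one position per channel")
  }
  invisible(rec)
}

#' Electrode array geometry
#'
#' Positions are `(x, y)` coordinates in millimetres; depth probes use
#' `x = 0` with `y` the depth below the surface. Layout is `"linear"` when
#' all electrodes fall on one line, `"grid"` otherwise.
#'
#' @param positions numeric matrix, channels x 2 (columns x, y), millimetres.
#' @param spacing nominal inter-electrode distance, millimetres. If `NULL`,
#'   the median nearest-neighbour distance is used.
#' @param layout `"linear"` or `"grid"`; inferred from the positions when
#'   `NULL`.
#' @param channel_ids optional labels matching the recording's channels.
#' @return An object of class `"electrode_geometry"`.
#' @examples
#' linear_probe_geometry(16, spacing = 0.1)  # 16-channel depth probe
#' grid_geometry(8, 4, spacing = 0.55)       # 32-channel surface array
#' @export
electrode_geometry <- function(positions, spacing = NULL, layout = NULL,
                               channel_ids = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must have two columns (x, y)")
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(positions)))
  if (anyDuplicated(positions))
    stop("electrode positions must be unique")
  if (is.null(layout)) {
    layout <- if (all(positions[, 1] == positions[1, 1]) ||
                  all(positions[, 2] == positions[1, 2])) "linear" else "grid"
  }
  if (is.null(spacing)) {
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    spacing <- stats::median(apply(d, 1L, min))
  }
  geom <- structure(
    list(positions = positions, spacing = spacing, layout = layout,
         channel_ids = as.character(channel_ids)),
    class = "electrode_geometry"
  )
  validate_geometry(geom)
  geom
}

#' @rdname electrode_geometry
#' @param n number of channels along the probe.
#' @export
linear_probe_geometry <- function(n, spacing = 0.1) {
  electrode_geometry(cbind(x = 0, y = spacing * (seq_len(n) - 1L)),
                     spacing = spacing, layout = "linear")
}

#' @rdname electrode_geometry
#' @param nx,ny grid dimensions (channels = nx * ny).
#' @export
grid_geometry <- function(nx, ny, spacing = 0.55) {
  pos <- expand.grid(x = spacing * (seq_len(nx) - 1L),
                     y = spacing * (seq_len(ny) - 1L))
  electrode_geometry(as.matrix(pos), spacing = spacing, layout = "grid")
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("<electrode_geometry> %d electrodes, %s layout, spacing %g mm\n",
              nrow(x$positions), x$layout, x$spacing))
  invisible(x)
}

validate_geometry <- function(geom) {
  if (!inherits(geom, "electrode_geometry")) stop("not an electrode_geometry")
  if (!is.numeric(geom$spacing) || geom$spacing <= 0) stop("spacing must be > 0")
  if (anyDuplicated(geom$positions))
    stop("electrode positions must be unique")
  if (length(geom$channel_ids) != nrow(geom$positions))
    stop("one channel id per electrode position required")
  invisible(geom)
}

#' Save / load a recording container
#'
#' A recording (signals, fs, t0, channel ids, geometry, metadata) is stored
#' in a single serialized container file; the roundtrip is bit-exact for all
#' numeric arrays. `load_recording` re-validates every invariant so that a
#' damaged container is rejected with an error naming the missing field.
#'
#' @param rec a validated `so_recording`.
#' @param path file path (conventionally `.rds`).
#' @return `load_recording` returns the `so_recording`; `save_recording`
#'   returns `path` invisibly.
#' @export
save_recording <- function(rec, path) {
  validate_recording(rec)
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- readRDS(path)
  if (!inherits(rec, "so_recording"))
    stop("format error: not a recording container")
  validate_recording(rec)
  rec
}

#' Read electrode geometry from CSV
#'
#' Expects a header `channel,x,y`. Coordinates are normalized to millimetres:
#' values whose nearest-neighbour spacing exceeds `um_threshold` are assumed
#' to be micrometres and divided by 1000 (electrode pitches in this field are
#' 0.05-1 mm, so the two unit conventions never overlap in practice).
#'
#' @param path CSV file path.
#' @param units `"auto"` (default), `"mm"`, or `"um"`.
#' @param um_threshold spacing (in file units) above which `"auto"` assumes
#'   micrometres; default 5.
#' @return An [electrode_geometry()].
#' @export
load_geometry <- function(path, units = c("auto", "mm", "um"),
                          um_threshold = 5) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "x", "y")
  if (!all(need %in% names(df)))
    stop("geometry CSV must have columns channel,x,y")
  if (anyDuplicated(df$channel)) stop("duplicate channel ids in geometry CSV")
  xy <- cbind(x = suppressWarnings(as.numeric(df$x)),
              y = suppressWarnings(as.numeric(df$y)))
  if (anyNA(xy)) stop("non-numeric coordinate in geometry CSV")
  geom <- electrode_geometry(xy, channel_ids = as.character(df$channel))
  if (units == "um" || (units == "auto" && geom$spacing > um_threshold)) {
    geom <- electrode_geometry(xy / 1000, channel_ids = as.character(df$channel))
  }
  geom
}

#' Write electrode geometry to CSV
#' @param geom an [electrode_geometry()].
#' @param path output CSV path.
#' @export
save_geometry <- function(geom, path) {
  validate_geometry(geom)
  utils::write.csv(
    data.frame(channel = geom$channel_ids,
               x = geom$positions[, 1], y = geom$positions[, 2]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
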