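#' Pipeline configuration
#'
#' All tunables of the analysis stages in one validated list. Values are
#' checked against their documented ranges at construction time, so a typo in
#' a YAML file fails at load, not deep inside a stage.
#'
#' Defaults (units in parentheses):
#' \describe{
#'   \item{mua_window (s)}{Spectrogram window, 0.005. Short enough to resolve
#'     state transitions, long enough for the 200-1500 Hz band.}
#'   \item{mua_step (s)}{Spectrogram step, 0.001.}
#'   \item{mua_band (Hz)}{High-frequency band for the firing-rate estimate,
#'     c(200, 1500).}
#'   \item{mua_log_floor}{Floor applied inside the log, 1e-3.}
#'   \item{detect_smooth (s)}{Gaussian smoothing of log MUA before
#'     thresholding, 0.02.}
#'   \item{min_up, min_down (s)}{Minimum state durations, 0.05 each.}
#'   \item{slope_window (s)}{Window around Down-to-Up crossings for the
#'     transition-slope fit, 0.1.}
#'   \item{welch_segment (s)}{Welch PSD segment for Up-state band power,
#'     0.25 (50\% overlap).}
#'   \item{wave_max_span (s)}{Transitions within this span of a wave's running
#'     mean are merged into it, 0.25.}
#'   \item{wave_min_fraction}{Minimum participating-channel fraction for a
#'     retained wave, 0.5.}
#'   \item{grid_resolution}{Interpolation grid points per axis, 32.}
#'   \item{speed_floor (s/mm)}{Lag-gradient magnitudes below this are masked
#'     in the speed map (1e-4, i.e. speeds above 10 m/s discarded).}
#'   \item{entropy_bins}{Occupancy grid size per PC axis, 8.}
#'   \item{conn_fs (Hz)}{Downsampling target for wideband correlation, 250.}
#'   \item{weight_floor}{Correlations at or below this are treated as absent
#'     graph edges, 0.05.}
#'   \item{butter_order}{Butterworth order (applied forward-backward), 4.}
#'   \item{louvain_restarts}{Louvain restarts, best modularity kept, 20.}
#'   \item{complexity_bins}{Histogram bins for functional complexity, 20.}
#' }
#'
#' @param ... name-value overrides of the defaults.
#' @return A validated list with class `"so_config"`.
#' @examples
#' cfg <- pipeline_config(mua_window = 0.004)
#' cfg$mua_band
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mua_window = 0.005, mua_step = 0.001, mua_band = c(200, 1500),
    mua_log_floor = 1e-3,
    detect_smooth = 0.02, min_up = 0.05, min_down = 0.05,
    slope_window = 0.1, welch_segment = 0.25,
    wave_max_span = 0.25, wave_min_fraction = 0.5,
    grid_resolution = 32L, speed_floor = 1e-4, entropy_bins = 8L,
    conn_fs = 250, weight_floor = 0.05, butter_order = 4L,
    louvain_restarts = 20L, complexity_bins = 20L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "so_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg)
  chk(cfg$mua_window > 0 && cfg$mua_step > 0 &&
        cfg$mua_step <= cfg$mua_window, "mua window/step invalid")
  chk(length(cfg$mua_band) == 2L && cfg$mua_band[1] > 0 &&
        cfg$mua_band[2] > cfg$mua_band[1], "mua_band must be increasing")
  chk(cfg$mua_log_floor > 0, "mua_log_floor must be > 0")
  chk(cfg$min_up > 0 && cfg$min_down > 0, "minimum durations must be > 0")
  chk(cfg$wave_max_span > 0, "wave_max_span must be > 0")
  chk(cfg$wave_min_fraction > 0 && cfg$wave_min_fraction <= 1,
      "wave_min_fraction must be in (0, 1]")
  chk(cfg$grid_resolution >= 4, "grid_resolution must be >= 4")
  chk(cfg$speed_floor > 0, "speed_floor must be > 0")
  chk(cfg$entropy_bins >= 2, "entropy_bins must be >= 2")
  chk(cfg$conn_fs > 0, "conn_fs must be > 0")
  chk(cfg$weight_floor >= 0 && cfg$weight_floor < 1,
      "weight_floor must be in [0, 1)")
  chk(cfg$butter_order >= 1, "butter_order must be >= 1")
  chk(cfg$louvain_restarts >= 1, "louvain_restarts must be >= 1")
  chk(cfg$complexity_bins >= 2, "complexity_bins must be >= 2")
  cfg
}

#' Load a configuration from YAML
#'
#' Fields present in the file override defaults; everything is re-validated.
#'
#' @param path YAML file with a flat mapping of config fields.
#' @return An `so_config` list.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config YAML must be a mapping")
  do.call(pipeline_config, vals)
}
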