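#' Session configuration for the CLAS analysis pipeline
#'
#' Collects every numeric parameter of the online controller, the offline
#' slow-oscillation (SO) and spindle detectors, the spectral estimators and
#' the stimulus-locked averaging in one validated structure. Defaults follow
#' the published protocol: the online detector runs at 200 Hz on a
#' 0.25-4 Hz stream with an adaptive negativity threshold starting at
#' -80 uV that updates every 0.5 s from the preceding 5 s; bursts are paired
#' at a fixed 1075 ms interval, each 50 ms long with 5 ms ramps, followed by
#' a refractory pause of at least 2.5 s; stimulation is limited to the first
#' 4 h and to stable N3 (4 min for the first deep-sleep bout, 2 min for
#' later bouts). Offline SO detection band-passes 0.5-3.5 Hz, keeps negative
#' half-waves of 0.75-2 s and thresholds at 1.25 times the mean trough and
#' trough-to-peak amplitudes. Spindles are detected from a 3-Hz-wide band
#' around individual peak frequencies via a 0.2-s RMS envelope thresholded
#' at 1.5 SD (peak 2.5 SD) for 0.5-3 s, with sub-0.5-s gaps merged.
#' Spectra use Hanning windows of 4096 samples with 50\% overlap.
#'
#' @param ... named overrides for any default field.
#' @return object of class `session_config`: a named list of parameters.
#' @examples
#' cfg <- session_config()
#' cfg$init_threshold_uv
#' session_config(delay_ms = 450)$delay_ms
#' @export
session_config <- function(...) {
  defaults <- list(
    online_fs_hz        = 200,
    so_band_hz          = c(0.25, 4),
    broadband_hz        = c(0.25, 45),
    init_threshold_uv   = -80,
    threshold_update_s  = 0.5,
    threshold_history_s = 5,
    dt_ratio_threshold  = NA_real_,   # individual; must be set before gating
    delay_ms            = NA_real_,   # individual SO delay
    interburst_ms       = 1075,
    burst_ms            = 50,
    ramp_ms             = 5,
    refractory_s        = 2.5,
    trough_hysteresis_uv = 5,
    stim_window_h       = 4,
    n3_stable_first_min = 4,
    n3_stable_later_min = 2,
    online_delta_hz     = c(0.5, 4),
    online_theta_hz     = c(4, 8),
    monitor_channel     = "Fpz",
    offline_so_band_hz  = c(0.5, 3.5),
    halfwave_bounds_s   = c(0.75, 2),
    so_threshold_factor = 1.25,
    slow_spindle_range_hz = c(9, 12),
    fast_spindle_range_hz = c(12, 16),
    spindle_bandwidth_hz  = 3,
    rms_window_s        = 0.2,
    smooth_window_s     = 0.2,
    spindle_thresh_sd   = 1.5,
    spindle_peak_sd     = 2.5,
    spindle_dur_bounds_s = c(0.5, 3),
    merge_gap_s         = 0.5,
    merge_total_max_s   = 3,
    erp_lowpass_hz      = 35,
    erp_fs_hz           = 100,
    erp_window_s        = c(-1, 3),
    baseline_window_s   = c(-0.99, -0.01),
    fft_n               = 4096,
    fft_overlap         = 0.5,
    bands_hz            = list(
      SO           = c(0.5, 1.5),
      delta        = c(1.5, 4),
      SWA          = c(0.5, 4),
      theta        = c(4, 9),
      slow_spindle = c(9.5, 12.5),
      fast_spindle = c(12.5, 15.5)
    ),
    density_epoch_s     = 30
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all config overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  cfg <- structure(defaults, class = "session_config")
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  stop_bad <- function(field, why)
    stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
  band_fields <- c("so_band_hz", "broadband_hz", "online_delta_hz",
                   "online_theta_hz", "offline_so_band_hz",
                   "halfwave_bounds_s", "slow_spindle_range_hz",
                   "fast_spindle_range_hz", "spindle_dur_bounds_s",
                   "erp_window_s", "baseline_window_s")
  for (f in band_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[1] >= v[2])
      stop_bad(f, "must be two finite numbers with low < high")
  }
  for (b in names(cfg$bands_hz)) {
    v <- cfg$bands_hz[[b]]
    if (!is.numeric(v) || length(v) != 2 || v[1] >= v[2])
      stop_bad(paste0("bands_hz$", b), "must be an ordered (low, high) pair")
  }
  pos_fields <- c("online_fs_hz", "threshold_update_s", "threshold_history_s",
                  "interburst_ms", "burst_ms", "stim_window_h",
                  "n3_stable_first_min", "n3_stable_later_min",
                  "so_threshold_factor", "spindle_bandwidth_hz",
                  "rms_window_s", "smooth_window_s", "spindle_thresh_sd",
                  "spindle_peak_sd", "merge_gap_s", "merge_total_max_s",
                  "erp_lowpass_hz", "erp_fs_hz", "fft_n", "density_epoch_s")
  for (f in pos_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_bad(f, "must be a single positive number")
  }
  if (cfg$refractory_s < 0) stop_bad("refractory_s", "must be >= 0")
  if (cfg$trough_hysteresis_uv < 0)
    stop_bad("trough_hysteresis_uv", "must be >= 0")
  if (cfg$ramp_ms < 0) stop_bad("ramp_ms", "must be >= 0")
  if (cfg$fft_overlap < 0 || cfg$fft_overlap >= 1)
    stop_bad("fft_overlap", "must lie in [0, 1)")
  if (!is.na(cfg$init_threshold_uv) && cfg$init_threshold_uv >= 0)
    stop_bad("init_threshold_uv", "must be negative (uV trough criterion)")
  if (!is.character(cfg$monitor_channel) || length(cfg$monitor_channel) != 1)
    stop_bad("monitor_channel", "must be a single channel label")
  invisible(cfg)
}

#' Load a session configuration from a YAML file
#'
#' Absent file argument returns all defaults; a partial file overrides only
#' the named fields. Unknown keys are an error so typos cannot silently
#' leave a parameter at its default.
#'
#' @param path optional path to a YAML (or JSON-compatible) key-value file.
#' @return a validated [session_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(session_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a key-value mapping")
  # yaml reads two-element sequences as vectors already; coerce bands_hz
  if (!is.null(vals$bands_hz)) vals$bands_hz <- lapply(vals$bands_hz, as.numeric)
  do.call(session_config, vals)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  for (f in names(x)) {
    v <- x[[f]]
    if (is.list(v)) {
      cat(sprintf("  %s:\n", f))
      for (b in names(v))
        cat(sprintf("    %-14s [%g, %g]\n", b, v[[b]][1], v[[b]][2]))
    } else {
      cat(sprintf("  %-22s %s\n", f, paste(format(v), collapse = ", ")))
    }
  }
  invisible(x)
}
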