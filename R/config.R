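#' Default analysis configuration
#'
#' Returns the full pipeline configuration as a named nested list. Every
#' stage of the pipeline reads its tunables from this object, so a single
#' config (optionally loaded from YAML with [read_config()]) documents an
#' entire analysis run.
#'
#' Sections and defaults:
#' \describe{
#'   \item{filter}{elliptic bandpass prefilter: `f_lo_hz = 200`,
#'     `f_hi_hz = 3000`, `order = 4`, `ripple_db = 0.1`,
#'     `stopband_db = 40`. Applied forward-backward (zero phase).}
#'   \item{threshold}{amplitude detector: `k = 4.5` (multiples of the
#'     robust noise SD), `dead_time_s = 0.001`, `polarity = "both"`.}
#'   \item{swtteo}{wavelet detector: `wavelet = "sym2"`, `level = 3`,
#'     `smooth_window_samples = 25` (Hamming).}
#'   \item{consensus}{`tolerance_s = 0.001` coincidence window between the
#'     two detectors.}
#'   \item{activity}{`min_spikes_per_min = 10`; electrodes must exceed this
#'     rate (strictly) to count as active.}
#'   \item{logisi}{`bins_per_decade = 10`, `void_threshold = 0.7`,
#'     `max_core_isi_s = 0.1`, `min_spikes = 5`.}
#'   \item{burst}{`merge_gap_s = 0.1`, `rate_definition = "isi"` (spike
#'     frequency in burst uses (n-1)/duration; `"count"` uses n/duration),
#'     `duration_floor_s = 8e-5` (one sample period at 12.5 kHz).}
#'   \item{sttc}{`dt_s = 0.05` coincidence half-window,
#'     `summary = "median"` (or `"mean"`) over electrode pairs.}
#'   \item{corse}{`window_s = 1`, `overlap_frac = 0.5`,
#'     `edge_threshold = 0.7`, `bandpass = TRUE` (compute spectral entropy
#'     on the prefiltered trace).}
#'   \item{pca}{`n_components = 3`, `sd_type = "population"` (or
#'     `"sample"`) for the standard-score normalisation.}
#'   \item{seed}{integer seed used by pipeline stages that draw random
#'     numbers.}
#' }
#'
#' @return A named list of class `mea_config`.
#' @seealso [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$threshold$k
default_config <- function() {
  cfg <- list(
    filter = list(f_lo_hz = 200, f_hi_hz = 3000, order = 4,
                  ripple_db = 0.1, stopband_db = 40),
    threshold = list(k = 4.5, dead_time_s = 0.001, polarity = "both"),
    swtteo = list(wavelet = "sym2", level = 3L, smooth_window_samples = 25L),
    consensus = list(tolerance_s = 0.001),
    activity = list(min_spikes_per_min = 10),
    logisi = list(bins_per_decade = 10, void_threshold = 0.7,
                  max_core_isi_s = 0.1, min_spikes = 5L),
    burst = list(merge_gap_s = 0.1, rate_definition = "isi",
                 duration_floor_s = 8e-5),
    sttc = list(dt_s = 0.05, summary = "median"),
    corse = list(window_s = 1, overlap_frac = 0.5, edge_threshold = 0.7,
                 bandpass = TRUE),
    pca = list(n_components = 3L, sd_type = "population"),
    seed = 1L
  )
  structure(cfg, class = c("mea_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants of a configuration list (positive
#' durations, ordered filter band edges, minimum spike counts) and errors
#' with the offending key on failure.
#'
#' @param config A list as returned by [default_config()].
#' @param fs Optional sampling rate (Hz); when given, the filter band is
#'   checked against the Nyquist frequency.
#' @return `config`, invisibly, classed as `mea_config`.
#' @export
validate_config <- function(config, fs = NULL) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  chk <- function(ok, key) {
    if (!isTRUE(ok)) stop("invalid config value for '", key, "'", call. = FALSE)
  }
  chk(config$filter$f_lo_hz > 0 && config$filter$f_lo_hz < config$filter$f_hi_hz,
      "filter.f_lo_hz < filter.f_hi_hz")
  if (!is.null(fs)) chk(config$filter$f_hi_hz < fs / 2, "filter.f_hi_hz < fs/2")
  chk(config$threshold$k > 0, "threshold.k")
  chk(config$threshold$dead_time_s > 0, "threshold.dead_time_s")
  chk(config$threshold$polarity %in% c("both", "neg"), "threshold.polarity")
  chk(config$consensus$tolerance_s > 0, "consensus.tolerance_s")
  chk(config$activity$min_spikes_per_min >= 0, "activity.min_spikes_per_min")
  chk(config$logisi$min_spikes >= 2, "logisi.min_spikes")
  chk(config$logisi$bins_per_decade >= 2, "logisi.bins_per_decade")
  chk(config$logisi$void_threshold > 0 && config$logisi$void_threshold <= 1,
      "logisi.void_threshold")
  chk(config$logisi$max_core_isi_s > 0, "logisi.max_core_isi_s")
  chk(config$burst$merge_gap_s > 0, "burst.merge_gap_s")
  chk(config$sttc$dt_s > 0, "sttc.dt_s")
  chk(config$corse$window_s > 0, "corse.window_s")
  chk(config$corse$overlap_frac >= 0 && config$corse$overlap_frac < 1,
      "corse.overlap_frac")
  chk(config$pca$n_components >= 1, "pca.n_components")
  structure(config, class = c("mea_config", "list"))
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML mirroring the sections of
#' [default_config()]. Keys absent from the file keep their defaults;
#' unknown keys are an error (a corrupted config never runs silently).
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a validated `mea_config` list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (!section %in% c(names(cfg))) {
      stop("unknown config section '", section, "' in ", path, call. = FALSE)
    }
    if (section == "seed") {
      cfg$seed <- as.integer(user$seed)
      next
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop("unknown config key '", section, ".", key, "' in ", path,
             call. = FALSE)
      }
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  validate_config(cfg)
}

#' @param config Configuration list to serialise.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
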