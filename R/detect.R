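#' Zero-phase elliptic bandpass prefilter
#'
#' Applies an elliptic (Cauer) bandpass forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion and squaring the
#' magnitude response. Defaults: 200--3000 Hz passband, order 4, 0.1 dB
#' passband ripple, 40 dB stopband attenuation.
#'
#' @param trace Numeric vector of voltage samples.
#' @param fs Sampling rate (Hz).
#' @param f_lo,f_hi Passband edges (Hz); `f_lo < f_hi < fs/2` required.
#' @param order Analog prototype order of the elliptic design.
#' @param ripple_db Passband ripple (dB).
#' @param stopband_db Stopband attenuation (dB).
#' @return Filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, fs, f_lo = 200, f_hi = 3000, order = 4,
                            ripple_db = 0.1, stopband_db = 40) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) {
    stop("filter design requires 0 < f_lo < f_hi < fs/2", call. = FALSE)
  }
  filt <- signal::ellip(order, ripple_db, stopband_db,
                        c(f_lo, f_hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(filt, trace))
}

#' Robust noise standard deviation estimate
#'
#' Median absolute deviation estimator `median(|x|) / 0.6745`, which is
#' consistent for the SD of zero-mean Gaussian noise and nearly unaffected
#' by sparse large spikes (unlike the plain SD, which a 1% contamination
#' of 20-sigma events more than doubles).
#'
#' @param trace Numeric vector (at least 1000 samples).
#' @return Estimated noise SD, in the trace's units.
#' @export
estimate_noise_sd <- function(trace) {
  if (length(trace) < 1000) {
    stop("estimate_noise_sd needs at least 1000 samples", call. = FALSE)
  }
  s <- stats::median(abs(trace)) / 0.6745
  if (s == 0) warning("all-zero (or majority-zero) trace: sigma_hat = 0",
                      call. = FALSE)
  s
}

# indices (1-based) of local maxima of v exceeding thr, thinned so kept
# peaks are >= dead_samples apart, larger values winning
local_peaks <- function(v, thr, dead_samples) {
  n <- length(v)
  if (n < 3) return(integer(0))
  core <- 2:(n - 1)
  idx <- core[v[core] > thr & v[core] >= v[core - 1] & v[core] > v[core + 1]]
  if (length(idx) == 0) return(integer(0))
  ord <- idx[order(v[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || all(abs(kept - i) >= dead_samples)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Amplitude-threshold spike candidates
#'
#' Detects local extrema whose magnitude exceeds `k` times the noise SD.
#' With `polarity = "both"` the rectified trace `|x|` is compared against
#' the threshold; `"neg"` uses `-x` (negative deflections only). Candidates
#' closer together than `dead_time_s` are thinned, keeping the larger
#' extremum. Times are `sample / fs` with 0-based samples.
#'
#' @param trace Filtered voltage trace.
#' @param fs Sampling rate (Hz).
#' @param sigma_hat Noise SD estimate (> 0), e.g. from
#'   [estimate_noise_sd()].
#' @param k Threshold multiplier (default 4.5).
#' @param dead_time_s Minimum separation between detections (s).
#' @param polarity `"both"` or `"neg"`.
#' @return Sorted numeric vector of candidate times (s).
#' @export
threshold_detect <- function(trace, fs, sigma_hat, k = 4.5,
                             dead_time_s = 0.001, polarity = "both") {
  stopifnot(sigma_hat > 0)
  v <- switch(polarity, both = abs(trace), neg = -trace,
              stop("polarity must be 'both' or 'neg'", call. = FALSE))
  idx <- local_peaks(v, k * sigma_hat, round(dead_time_s * fs))
  (idx - 1) / fs
}

sym2_filters <- function() {
  lo <- c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025)
  list(lo = lo, hi = rev(lo) * c(-1, 1, -1, 1))
}

# circular convolution of x with kernel h, result aligned so that the
# kernel's centre of mass sits at lag 0 (delay-compensated)
circ_conv <- function(x, h, delay) {
  n <- length(x)
  hp <- numeric(n)
  hp[seq_along(h)] <- h
  y <- Re(stats::fft(stats::fft(x) * stats::fft(hp), inverse = TRUE)) / n
  if (delay > 0) y <- c(y[(delay + 1):n], y[1:delay])
  y
}

#' SWTTEO detection energy
#'
#' Computes the stationary-wavelet-transform Teager-energy signal used by
#' the wavelet spike detector: the trace is decomposed with an undecimated
#' (a trous) wavelet transform, the Teager energy operator
#' `psi(n) = d(n)^2 - d(n-1) d(n+1)` is applied to each level's detail
#' coefficients, the result is rectified, smoothed with a symmetric
#' Hamming window and summed across levels. Transient, high-frequency
#' events such as extracellular spikes concentrate energy; slow
#' oscillations (e.g. 50 Hz mains) do not.
#'
#' @param trace Filtered voltage trace.
#' @param fs Sampling rate (Hz) (kept for interface symmetry; the energy
#'   is per-sample).
#' @param wavelet Wavelet name; `"sym2"` is the only built-in.
#' @param level Decomposition depth (details of levels `1..level` are
#'   used).
#' @param smooth_window Length of the Hamming smoothing window in samples.
#' @return Non-negative energy signal, same length as the input.
#' @export
swtteo_energy <- function(trace, fs, wavelet = "sym2", level = 3,
                          smooth_window = 25) {
  if (!identical(wavelet, "sym2")) {
    stop("only the 'sym2' wavelet is built in", call. = FALSE)
  }
  n0 <- length(trace)
  if (n0 < 2^level * 8) stop("trace too short for level ", level,
                             call. = FALSE)
  # pad to a multiple of 2^level for the undecimated transform
  n <- ceiling(n0 / 2^level) * 2^level
  x <- c(trace, numeric(n - n0))
  filt <- sym2_filters()
  energy <- numeric(n)
  ham <- 0.54 - 0.46 * cos(2 * pi * seq_len(smooth_window) /
                             (smooth_window + 1))
  ham <- ham / sum(ham)
  approx <- x
  for (j in seq_len(level)) {
    up <- 2^(j - 1)
    lo_j <- upsample_filter(filt$lo, up)
    hi_j <- upsample_filter(filt$hi, up)
    delay <- (length(lo_j) - 1) %/% 2
    detail <- circ_conv(approx, hi_j, delay)
    approx <- circ_conv(approx, lo_j, delay)
    psi <- detail^2
    psi[2:(n - 1)] <- detail[2:(n - 1)]^2 - detail[1:(n - 2)] * detail[3:n]
    psi <- pmax(psi, 0)
    sm <- stats::filter(psi, ham, sides = 2)
    sm[is.na(sm)] <- 0
    energy <- energy + as.numeric(sm)
  }
  energy[seq_len(n0)]
}

upsample_filter <- function(h, up) {
  if (up == 1) return(h)
  out <- numeric(length(h) * up - (up - 1))
  out[seq(1, length(out), by = up)] <- h
  out
}

#' Select spike candidates from an SWTTEO energy signal
#'
#' Returns the times of the `n_candidates` largest local maxima of the
#' energy signal, enforcing a dead time between selections. The number of
#' candidates is supplied by the amplitude-threshold detector, coupling
#' the two methods; fewer times are returned when the energy signal has
#' fewer isolated maxima.
#'
#' @param energy Energy signal from [swtteo_energy()].
#' @param fs Sampling rate (Hz).
#' @param n_candidates Number of candidates to extract (>= 0).
#' @param dead_time_s Minimum separation between selections (s).
#' @return Sorted numeric vector of candidate times (s).
#' @export
swtteo_select <- function(energy, fs, n_candidates, dead_time_s = 0.001) {
  stopifnot(n_candidates >= 0)
  if (n_candidates == 0) return(numeric(0))
  n <- length(energy)
  if (n < 3) return(numeric(0))
  core <- 2:(n - 1)
  idx <- core[energy[core] > 0 & energy[core] >= energy[core - 1] &
                energy[core] > energy[core + 1]]
  if (length(idx) == 0) return(numeric(0))
  ord <- idx[order(energy[idx], decreasing = TRUE)]
  dead <- round(dead_time_s * fs)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == n_candidates) break
    if (length(kept) == 0 || all(abs(kept - i) >= dead)) kept <- c(kept, i)
  }
  (sort(kept) - 1) / fs
}

#' Consensus between threshold and SWTTEO detections
#'
#' Greedy one-to-one matching in time order: a threshold-detector time is
#' kept if and only if an as-yet-unmatched SWTTEO time lies within
#' `tolerance_s` of it. Kept spikes take the threshold-detector timestamp.
#' Only events found by both methods survive, which suppresses each
#' detector's isolated false positives.
#'
#' @param threshold_times,swtteo_times Sorted numeric vectors (s).
#' @param tolerance_s Coincidence tolerance (s).
#' @return Sorted vector of consensus spike times (s).
#' @export
consensus_spikes <- function(threshold_times, swtteo_times,
                             tolerance_s = 0.001) {
  n_a <- length(threshold_times)
  n_b <- length(swtteo_times)
  if (n_a == 0 || n_b == 0) return(numeric(0))
  kept <- logical(n_a)
  j <- 1L
  for (i in seq_len(n_a)) {
    t <- threshold_times[i]
    while (j <= n_b && swtteo_times[j] < t - tolerance_s) j <- j + 1L
    if (j <= n_b && abs(swtteo_times[j] - t) <= tolerance_s) {
      kept[i] <- TRUE
      j <- j + 1L  # each SWTTEO time matches at most one threshold time
    }
  }
  threshold_times[kept]
}

#' Consensus spike detection on a raw recording
#'
#' Runs the full detection chain on every electrode of a recording:
#' zero-phase elliptic bandpass (200--3000 Hz), robust noise SD estimate
#' on the filtered trace, amplitude-threshold detection at
#' `k = 4.5` times the noise SD, SWTTEO energy detection fed with the
#' threshold detector's candidate count, and the consensus intersection.
#'
#' @param recording An [mea_recording()].
#' @param config A configuration from [default_config()].
#' @return A list of class `mea_detection`: `spikes` (a [spike_table()] of
#'   consensus spikes), `per_electrode` (tibble with candidate counts per
#'   stage and `sigma_hat`), and `config`.
#' @export
#' @examples
#' truth <- simulate_trains(network_params(n_electrodes = 2, duration_s = 10,
#'                                         burst_rate_per_min = 6,
#'                                         tonic_rate_hz = 1), seed = 7)
#' rec <- synthesize_raw(truth, waveform_model(noise_sd_uv = 3), seed = 7)
#' det <- detect_spikes(rec, default_config())
#' det$per_electrode
detect_spikes <- function(recording, config = default_config()) {
  stopifnot(inherits(recording, "mea_recording"))
  validate_config(config, fs = recording$fs)
  fs <- recording$fs
  dur <- ncol(recording$traces) / fs
  res <- purrr::map(seq_along(recording$electrode_ids), function(e) {
    tr <- bandpass_filter(recording$traces[e, ], fs,
                          f_lo = config$filter$f_lo_hz,
                          f_hi = config$filter$f_hi_hz,
                          order = config$filter$order,
                          ripple_db = config$filter$ripple_db,
                          stopband_db = config$filter$stopband_db)
    sigma <- estimate_noise_sd(tr)
    if (sigma <= 0) {
      t_thr <- numeric(0)
    } else {
      t_thr <- threshold_detect(tr, fs, sigma, k = config$threshold$k,
                                dead_time_s = config$threshold$dead_time_s,
                                polarity = config$threshold$polarity)
    }
    if (length(t_thr) > 0) {
      energy <- swtteo_energy(tr, fs, wavelet = config$swtteo$wavelet,
                              level = config$swtteo$level,
                              smooth_window =
                                config$swtteo$smooth_window_samples)
      t_swt <- swtteo_select(energy, fs, n_candidates = length(t_thr),
                             dead_time_s = config$threshold$dead_time_s)
    } else {
      t_swt <- numeric(0)
    }
    t_cons <- consensus_spikes(t_thr, t_swt,
                               tolerance_s = config$consensus$tolerance_s)
    list(times = t_cons, sigma = sigma, n_thr = length(t_thr),
         n_swt = length(t_swt), n_cons = length(t_cons))
  })
  spikes <- purrr::map2(res, recording$electrode_ids, function(r, id) {
    tibble::tibble(well_id = recording$well_id, electrode_id = id,
                   time_s = round(r$times, 6))
  })
  per_electrode <- tibble::tibble(
    well_id = recording$well_id,
    electrode_id = recording$electrode_ids,
    n_threshold_candidates = purrr::map_int(res, "n_thr"),
    n_swtteo_candidates = purrr::map_int(res, "n_swt"),
    n_consensus = purrr::map_int(res, "n_cons"),
    sigma_hat = purrr::map_dbl(res, "sigma"))
  structure(list(spikes = spike_table(dplyr::bind_rows(spikes),
                                      duration_s = dur),
                 per_electrode = per_electrode, config = config),
            class = "mea_detection")
}

#' Active-electrode rule
#'
#' An electrode is active when it fires strictly more than
#' `min_spikes_per_min` spikes per minute (default 10); only active
#' electrodes enter downstream analysis. An electrode at exactly the
#' boundary rate is inactive.
#'
#' @param spikes A [spike_table()].
#' @param min_spikes_per_min Activity threshold (spikes/min).
#' @param n_total Total electrodes per well used for the percentage
#'   denominator; defaults to the number of electrodes present in the
#'   table. Supply the plate's electrode count (16 or 64) when silent
#'   electrodes are absent from the table.
#' @return A tibble with one row per (well, electrode) present in the
#'   table: `n_spikes`, `rate_per_min`, `active`, plus the per-well
#'   percentage of active electrodes in `pct_active`.
#' @export
active_electrodes <- function(spikes, min_spikes_per_min = 10,
                              n_total = NULL) {
  dur_min <- spike_duration(spikes) / 60
  out <- tibble::as_tibble(spikes) |>
    dplyr::count(.data$well_id, .data$electrode_id, name = "n_spikes") |>
    dplyr::mutate(rate_per_min = .data$n_spikes / dur_min,
                  active = .data$rate_per_min > min_spikes_per_min)
  out <- out |>
    dplyr::group_by(.data$well_id) |>
    dplyr::mutate(pct_active = 100 * sum(.data$active) /
                    (n_total %||% dplyr::n())) |>
    dplyr::ungroup()
  out
}
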