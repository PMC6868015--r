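#' Network simulation parameters and phenotype presets
#'
#' `network_params()` bundles the generative parameters of the synthetic
#' MEA model; `preset()` returns parameter sets calibrated to the two
#' activity phenotypes the package is designed around, at their activity
#' peak:
#'
#' \describe{
#'   \item{`"hPSC_peak"`}{human pluripotent stem cell derived cortical
#'     network at peak activity: 11 network bursts/min, 0.7 s bursts,
#'     intra-burst rate 34/0.7 = 48.6 Hz (about 34 spikes per burst),
#'     pronounced tonic spiking between bursts (0.6 Hz), burst-onset
#'     jitter 20 ms across electrodes.}
#'   \item{`"rat_peak"`}{embryonic rat cortical network at peak activity:
#'     15 bursts/min, 0.3 s bursts, intra-burst rate 100 Hz (about 30
#'     spikes per burst), sparse tonic background (0.3 Hz), tighter
#'     burst-onset jitter 10 ms.}
#' }
#'
#' @param n_electrodes Electrodes per well (1..64).
#' @param duration_s Recording length (s).
#' @param burst_rate_per_min Network-burst onset rate (bursts/min).
#' @param burst_duration_s Burst length (s).
#' @param intra_burst_rate_hz Within-burst firing rate per electrode (Hz).
#' @param participation Probability that an electrode takes part in a
#'   given network burst.
#' @param jitter_s SD of the per-electrode burst-onset offset (s).
#' @param tonic_rate_hz Background Poisson rate per electrode (Hz).
#' @param pct_in_bursts_target Informative label: the percentage of spikes
#'   expected inside bursts under these parameters (not used by the
#'   generator).
#' @return A named list of class `network_params`.
#' @export
#' @examples
#' preset("rat_peak")$burst_rate_per_min
network_params <- function(n_electrodes = 16, duration_s = 600,
                           burst_rate_per_min = 11, burst_duration_s = 0.7,
                           intra_burst_rate_hz = 34 / 0.7,
                           participation = 0.95, jitter_s = 0.02,
                           tonic_rate_hz = 0.6,
                           pct_in_bursts_target = NA_real_) {
  p <- list(n_electrodes = as.integer(n_electrodes), duration_s = duration_s,
            burst_rate_per_min = burst_rate_per_min,
            burst_duration_s = burst_duration_s,
            intra_burst_rate_hz = intra_burst_rate_hz,
            participation = participation, jitter_s = jitter_s,
            tonic_rate_hz = tonic_rate_hz,
            pct_in_bursts_target = pct_in_bursts_target)
  stopifnot(p$n_electrodes >= 1, p$n_electrodes <= 64, p$duration_s > 0,
            p$burst_rate_per_min >= 0, p$burst_duration_s > 0,
            p$intra_burst_rate_hz >= 0, p$participation >= 0,
            p$participation <= 1, p$jitter_s >= 0, p$tonic_rate_hz >= 0)
  if (p$burst_rate_per_min > 0 &&
      p$burst_duration_s >= 60 / p$burst_rate_per_min) {
    stop("burst_duration_s must be shorter than the mean inter-burst period",
         call. = FALSE)
  }
  structure(p, class = c("network_params", "list"))
}

#' @param kind Preset name, `"hPSC_peak"` or `"rat_peak"`.
#' @rdname network_params
#' @export
preset <- function(kind) {
  switch(kind,
    hPSC_peak = network_params(
      burst_rate_per_min = 11, burst_duration_s = 0.7,
      intra_burst_rate_hz = 34 / 0.7, participation = 0.95,
      jitter_s = 0.02, tonic_rate_hz = 0.6, pct_in_bursts_target = 90),
    rat_peak = network_params(
      burst_rate_per_min = 15, burst_duration_s = 0.3,
      intra_burst_rate_hz = 100, participation = 0.95,
      jitter_s = 0.01, tonic_rate_hz = 0.3, pct_in_bursts_target = 96),
    stop("unknown preset '", kind,
         "'; valid kinds: hPSC_peak, rat_peak", call. = FALSE))
}

#' Simulate ground-truth spike trains for one well
#'
#' Generative model: network-burst onsets follow a renewal process with
#' exponential inter-onset gaps plus a hard dead time of
#' `burst_duration_s + 0.4` s (so bursts are distinct, non-overlapping
#' events), with mean onset rate exactly `burst_rate_per_min`; each
#' electrode joins a given burst
#' with probability `participation`, its onset shifted by a
#' Normal(0, `jitter_s`) offset; within a burst the electrode fires as a
#' homogeneous Poisson process at `intra_burst_rate_hz` for
#' `burst_duration_s`; an independent tonic Poisson background at
#' `tonic_rate_hz` runs throughout. Trains are sorted and thinned to a
#' 1 ms refractory period. The per-electrode burst windows actually
#' generated (with their spike counts) are recorded as ground truth.
#'
#' @param params A [network_params()] list.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param well_id Well label for the emitted tables.
#' @return A list of class `mea_ground_truth` with elements `spikes`
#'   (a [spike_table()]), `bursts` (tibble `well_id`, `electrode_id`,
#'   `t_start_s`, `t_end_s`, `n_spikes`), `params` and `seed`.
#' @export
simulate_trains <- function(params, seed = 1L, well_id = "W1") {
  stopifnot(inherits(params, "network_params"), params$duration_s >= 10)
  expected <- params$n_electrodes * params$duration_s *
    (params$tonic_rate_hz + params$burst_rate_per_min / 60 *
       params$participation * params$intra_burst_rate_hz *
       params$burst_duration_s)
  if (expected > 1e7) {
    stop("parameters imply > 1e7 expected spikes; refusing to simulate",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  dur <- params$duration_s
  electrode_ids <- sprintf("E%02d", seq_len(params$n_electrodes))

  # network-burst onsets: renewal process with a hard dead time so
  # generated bursts are distinct, non-overlapping events, with the mean
  # inter-onset interval equal to the requested rate
  net_onsets <- numeric(0)
  if (params$burst_rate_per_min > 0) {
    rate <- params$burst_rate_per_min / 60
    min_gap <- params$burst_duration_s + 0.4
    if (1 / rate <= min_gap) {
      stop("burst rate too high for non-overlapping bursts of this duration",
           call. = FALSE)
    }
    theta <- 1 / rate - min_gap
    n_exp <- ceiling(rate * dur * 1.5 + 20)
    gaps <- min_gap + stats::rexp(n_exp, 1 / theta)
    onsets <- stats::runif(1, 0, 1 / rate) + cumsum(c(0, gaps))
    net_onsets <- onsets[onsets < dur]
  }
  n_net_bursts <- length(net_onsets)

  spikes <- vector("list", params$n_electrodes)
  bursts <- vector("list", params$n_electrodes)
  for (e in seq_len(params$n_electrodes)) {
    t_tonic <- stats::runif(stats::rpois(1, params$tonic_rate_hz * dur),
                            0, dur)
    t_burst <- numeric(0)
    eb <- list()
    if (n_net_bursts > 0) {
      joins <- stats::runif(n_net_bursts) < params$participation
      for (b in which(joins)) {
        onset <- net_onsets[b] + stats::rnorm(1, 0, params$jitter_s)
        n_sp <- stats::rpois(1, params$intra_burst_rate_hz *
                               params$burst_duration_s)
        if (n_sp == 0) next
        tt <- sort(stats::runif(n_sp, onset, onset + params$burst_duration_s))
        tt <- tt[tt >= 0 & tt < dur]
        if (length(tt) == 0) next
        t_burst <- c(t_burst, tt)
        eb[[length(eb) + 1]] <- c(max(onset, 0),
                                  min(onset + params$burst_duration_s, dur),
                                  length(tt))
      }
    }
    tt <- sort(c(t_tonic, t_burst))
    tt <- enforce_refractory(tt, 0.001)
    spikes[[e]] <- tibble::tibble(well_id = well_id,
                                  electrode_id = electrode_ids[e],
                                  time_s = round(tt, 6))
    if (length(eb) > 0) {
      m <- do.call(rbind, eb)
      bursts[[e]] <- tibble::tibble(well_id = well_id,
                                    electrode_id = electrode_ids[e],
                                    t_start_s = m[, 1], t_end_s = m[, 2],
                                    n_spikes = as.integer(m[, 3]))
    }
  }
  out_spikes <- spike_table(dplyr::bind_rows(spikes), duration_s = dur)
  out_bursts <- dplyr::bind_rows(bursts)
  if (nrow(out_bursts) == 0) {
    out_bursts <- tibble::tibble(well_id = character(),
                                 electrode_id = character(),
                                 t_start_s = numeric(), t_end_s = numeric(),
                                 n_spikes = integer())
  } else {
    out_bursts <- dplyr::arrange(out_bursts, .data$electrode_id,
                                 .data$t_start_s)
  }
  structure(list(spikes = out_spikes, bursts = out_bursts, params = params,
                 seed = as.integer(seed)),
            class = "mea_ground_truth")
}

enforce_refractory <- function(t, refractory_s) {
  if (length(t) < 2) return(t)
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  t[keep]
}

#' Extracellular waveform model for raw-trace synthesis
#'
#' Describes how a spike train is rendered into a voltage trace: a biphasic
#' template with unit negative peak, log-normal peak amplitudes, additive
#' white Gaussian noise and an optional 50 Hz mains component.
#'
#' @param amplitude_uv Mean negative-peak amplitude in microvolts.
#' @param amplitude_cv Coefficient of variation of the (log-normal)
#'   amplitude distribution.
#' @param noise_sd_uv Gaussian noise SD in microvolts.
#' @param line_noise_uv Amplitude of an optional 50 Hz sinusoid (0 = none).
#' @param template Numeric vector, odd length, spanning at most 2 ms at the
#'   target sampling rate, scaled so its minimum is -1. Default: a biphasic
#'   shape (sharp negative trough, slower positive overshoot) over 1.6 ms.
#' @param fs Sampling rate the default template is built for (Hz).
#' @return A list of class `waveform_model`.
#' @export
waveform_model <- function(amplitude_uv = 40, amplitude_cv = 0.2,
                           noise_sd_uv = 5, line_noise_uv = 0,
                           template = NULL, fs = 12500) {
  if (is.null(template)) template <- biphasic_template(fs)
  stopifnot(amplitude_uv > 0, noise_sd_uv >= 0, amplitude_cv >= 0,
            length(template) %% 2 == 1,
            length(template) <= ceiling(0.002 * fs) * 2 + 1)
  template <- template / abs(min(template))
  structure(list(template = template, amplitude_uv = amplitude_uv,
                 amplitude_cv = amplitude_cv, noise_sd_uv = noise_sd_uv,
                 line_noise_uv = line_noise_uv),
            class = "waveform_model")
}

# biphasic extracellular shape: narrow negative trough followed by a
# broader positive overshoot; ~1.6 ms support, unit negative peak
biphasic_template <- function(fs = 12500) {
  half <- round(0.0008 * fs)
  t <- (-half:half) / fs
  w <- -exp(-(t / 1.5e-4)^2 / 2) + 0.35 * exp(-((t - 3.5e-4) / 3e-4)^2 / 2)
  w / abs(min(w))
}

#' Render ground-truth spike trains into a raw voltage recording
#'
#' Each true spike inserts the waveform template, scaled by a log-normal
#' amplitude draw and aligned so the template's negative peak falls on the
#' spike's sample; white Gaussian noise (and optionally a 50 Hz sinusoid)
#' is added. Spikes closer to the trace edge than the template half-width
#' are clipped, with a warning.
#'
#' @param truth A `mea_ground_truth` from [simulate_trains()].
#' @param wf A [waveform_model()].
#' @param fs Sampling rate (Hz), default 12500.
#' @param seed Integer seed for amplitudes and noise.
#' @return An [mea_recording()] with one row per electrode in
#'   `truth$spikes` (electrodes with no spikes included).
#' @export
synthesize_raw <- function(truth, wf = waveform_model(), fs = 12500,
                           seed = 1L) {
  stopifnot(inherits(truth, "mea_ground_truth"),
            inherits(wf, "waveform_model"))
  set.seed(as.integer(seed))
  dur <- spike_duration(truth$spikes)
  n_samp <- round(dur * fs)
  electrode_ids <- sprintf("E%02d", seq_len(truth$params$n_electrodes))
  tmpl <- wf$template
  half <- (length(tmpl) - 1L) %/% 2L
  peak_off <- which.min(tmpl) - 1L  # samples from template start to trough
  sdlog <- sqrt(log(1 + wf$amplitude_cv^2))
  meanlog <- log(wf$amplitude_uv) - sdlog^2 / 2

  traces <- matrix(0, nrow = length(electrode_ids), ncol = n_samp)
  n_clipped <- 0L
  for (e in seq_along(electrode_ids)) {
    tr <- numeric(n_samp)
    tt <- truth$spikes$time_s[truth$spikes$electrode_id == electrode_ids[e]]
    if (length(tt) > 0) {
      amp <- stats::rlnorm(length(tt), meanlog, sdlog)
      centre <- round(tt * fs) + 1L  # 0-based time -> 1-based sample
      for (i in seq_along(tt)) {
        lo <- centre[i] - peak_off
        hi <- lo + length(tmpl) - 1L
        s_lo <- max(lo, 1L)
        s_hi <- min(hi, n_samp)
        if (s_lo > lo || s_hi < hi) n_clipped <- n_clipped + 1L
        if (s_lo > s_hi) next
        tr[s_lo:s_hi] <- tr[s_lo:s_hi] +
          amp[i] * tmpl[(s_lo - lo + 1L):(s_hi - lo + 1L)]
      }
    }
    if (wf$noise_sd_uv > 0) {
      tr <- tr + stats::rnorm(n_samp, 0, wf$noise_sd_uv)
    }
    if (wf$line_noise_uv > 0) {
      tr <- tr + wf$line_noise_uv * sin(2 * pi * 50 * (0:(n_samp - 1)) / fs)
    }
    traces[e, ] <- tr
  }
  if (n_clipped > 0) {
    warning(n_clipped, " spike(s) clipped at trace edges", call. = FALSE)
  }
  wid <- if (nrow(truth$spikes) > 0) truth$spikes$well_id[1] else "W1"
  mea_recording(traces, fs = fs, electrode_ids = electrode_ids,
                well_id = wid)
}
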