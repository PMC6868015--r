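#' Spike time tiling coefficient
#'
#' Firing-rate-robust pairwise synchrony between two spike trains
#' observed on `[0, duration]`. With `T_X` the fraction of the recording
#' tiled by `[x - dt, x + dt]` around train X's spikes and `P_X` the
#' fraction of X's spikes lying within `dt` of any spike of the other
#' train,
#' `STTC = 1/2 [ (P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A) ]`.
#' A term whose denominator is zero is dropped (the value is the mean of
#' the remaining terms); if both trains are empty, or a train is empty,
#' the coefficient is undefined (`NA`).
#'
#' @param train_a,train_b Sorted spike times in `[0, duration]` (s).
#' @param dt Coincidence half-window (s), default 0.05.
#' @param duration Observation window length (s).
#' @return STTC in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' sttc(c(5), c(8), dt = 0.5, duration = 10)  # -0.1
sttc <- function(train_a, train_b, dt = 0.05, duration) {
  stopifnot(duration > 0, dt > 0, dt < duration / 2)
  if (length(train_a) == 0 || length(train_b) == 0) return(NA_real_)
  t_a <- tiled_fraction(train_a, dt, duration)
  t_b <- tiled_fraction(train_b, dt, duration)
  p_a <- prop_within(train_a, train_b, dt)
  p_b <- prop_within(train_b, train_a, dt)
  terms <- c()
  if (1 - p_a * t_b != 0) terms <- c(terms, (p_a - t_b) / (1 - p_a * t_b))
  if (1 - p_b * t_a != 0) terms <- c(terms, (p_b - t_a) / (1 - p_b * t_a))
  if (length(terms) == 0) return(NA_real_)
  mean(terms)
}

# fraction of [0, duration] covered by the union of [t - dt, t + dt]
tiled_fraction <- function(train, dt, duration) {
  starts <- pmax(train - dt, 0)
  ends <- pmin(train + dt, duration)
  n <- length(train)
  total <- sum(ends - starts)
  if (n > 1) {
    overlap <- pmax(0, ends[-n] - starts[-1])
    total <- total - sum(overlap)
  }
  total / duration
}

# fraction of x's spikes within dt of at least one spike of y
prop_within <- function(x, y, dt) {
  idx <- findInterval(x, y)
  d_prev <- ifelse(idx >= 1, x - y[pmax(idx, 1)], Inf)
  d_next <- ifelse(idx < length(y), y[pmin(idx + 1, length(y))] - x, Inf)
  mean(pmin(d_prev, d_next) <= dt)
}

#' Pairwise STTC for a well
#'
#' Computes the STTC for every unordered electrode pair in a spike table
#' (one well at a time) and a per-well summary (median over pairs by
#' default, mean by configuration).
#'
#' @param spikes A [spike_table()]; filter to active electrodes first if
#'   the active-electrode rule should apply (see [active_electrodes()]).
#' @param dt Coincidence half-window (s).
#' @param summary `"median"` or `"mean"` over pairs.
#' @return A list: `pairs` (tibble `well_id`, `electrode_a`,
#'   `electrode_b`, `sttc`, with `electrode_a < electrode_b`) and
#'   `well_summary` (tibble `well_id`, `sttc`; `NA` when a well has fewer
#'   than two electrodes).
#' @export
sttc_matrix <- function(spikes, dt = 0.05, summary = "median") {
  dur <- spike_duration(spikes)
  wells <- split(tibble::as_tibble(spikes), spikes$well_id)
  pair_rows <- list()
  sum_rows <- list()
  for (w in names(wells)) {
    trains <- split(wells[[w]]$time_s, wells[[w]]$electrode_id)
    ids <- sort(names(trains))
    if (length(ids) < 2) {
      sum_rows[[w]] <- tibble::tibble(well_id = w, sttc = NA_real_)
      next
    }
    cmb <- utils::combn(ids, 2)
    vals <- vapply(seq_len(ncol(cmb)), function(i) {
      sttc(trains[[cmb[1, i]]], trains[[cmb[2, i]]], dt = dt,
           duration = dur)
    }, numeric(1))
    pair_rows[[w]] <- tibble::tibble(well_id = w, electrode_a = cmb[1, ],
                                     electrode_b = cmb[2, ], sttc = vals)
    agg <- if (summary == "mean") mean else stats::median
    sum_rows[[w]] <- tibble::tibble(well_id = w,
                                    sttc = agg(vals, na.rm = TRUE))
  }
  list(pairs = dplyr::bind_rows(pair_rows),
       well_summary = dplyr::bind_rows(sum_rows))
}

#' Spectral entropy time series of a trace
#'
#' Slides a window of `window_s` seconds (Hann-tapered, overlapping by
#' `overlap_frac`) along the trace; in each window the periodogram is
#' restricted to `band`, normalised to a probability distribution, and
#' its Shannon entropy is divided by `log(N_f)` so the series lies in
#' `[0, 1]` (0 = pure tone, 1 = flat spectrum). A window with zero power
#' is assigned entropy 1 (maximal uncertainty).
#'
#' @param trace Voltage trace.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s); `window_s * fs >= 64` required.
#' @param overlap_frac Fractional overlap between consecutive windows.
#' @param band Frequency band `(f_lo, f_hi)` in Hz kept in the spectrum.
#' @return Numeric vector of per-window entropies.
#' @export
spectral_entropy_series <- function(trace, fs, window_s = 1,
                                    overlap_frac = 0.5,
                                    band = c(200, 3000)) {
  win <- round(window_s * fs)
  if (win < 64) stop("window_s * fs must be at least 64 samples",
                     call. = FALSE)
  step <- max(1, round(win * (1 - overlap_frac)))
  n <- length(trace)
  if (n < win) stop("trace shorter than one window", call. = FALSE)
  starts <- seq(1, n - win + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  freqs <- (seq_len(win %/% 2 + 1) - 1) * fs / win
  keep <- freqs > band[1] & freqs <= band[2]
  nf <- sum(keep)
  if (nf < 2) stop("band too narrow for the window length", call. = FALSE)
  vapply(starts, function(s) {
    seg <- trace[s:(s + win - 1)] * taper
    pw <- Mod(stats::fft(seg)[seq_len(win %/% 2 + 1)])^2
    pw <- pw[keep]
    tot <- sum(pw)
    if (tot <= 0) return(1)
    p <- pw / tot
    p <- p[p > 0]
    -sum(p * log(p)) / log(nf)
  }, numeric(1))
}

#' Correlated spectral entropy (CorSE) between two channels
#'
#' Functional-connectivity strength: the magnitude of the Pearson
#' correlation between the two channels' spectral-entropy time series.
#' Channels whose spectral content changes together (e.g. shared network
#' bursts) score near 1; unrelated channels score near 0. Undefined
#' (`NA`) when either entropy series is constant.
#'
#' @param trace_a,trace_b Equal-length voltage traces.
#' @param fs Sampling rate (Hz).
#' @param window_s,overlap_frac,band Passed to
#'   [spectral_entropy_series()].
#' @return CorSE in `[0, 1]`, or `NA`.
#' @export
corse <- function(trace_a, trace_b, fs, window_s = 1, overlap_frac = 0.5,
                  band = c(200, 3000)) {
  stopifnot(length(trace_a) == length(trace_b))
  se_a <- spectral_entropy_series(trace_a, fs, window_s, overlap_frac, band)
  se_b <- spectral_entropy_series(trace_b, fs, window_s, overlap_frac, band)
  if (length(se_a) < 10) stop("need at least 10 analysis windows",
                              call. = FALSE)
  corse_from_series(se_a, se_b)
}

corse_from_series <- function(se_a, se_b) {
  if (stats::sd(se_a) == 0 || stats::sd(se_b) == 0) return(NA_real_)
  abs(stats::cor(se_a, se_b))
}

#' Pairwise CorSE for a recording
#'
#' Computes each electrode's spectral-entropy series once (optionally on
#' the bandpass-filtered trace) and correlates all unordered pairs.
#'
#' @param recording An [mea_recording()].
#' @param config Configuration from [default_config()].
#' @return A tibble `well_id`, `electrode_a`, `electrode_b`, `corse`
#'   (`electrode_a < electrode_b`).
#' @export
corse_matrix <- function(recording, config = default_config()) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$fs
  band <- c(config$filter$f_lo_hz, config$filter$f_hi_hz)
  series <- lapply(seq_along(recording$electrode_ids), function(e) {
    tr <- recording$traces[e, ]
    if (isTRUE(config$corse$bandpass)) {
      tr <- bandpass_filter(tr, fs, f_lo = band[1], f_hi = band[2],
                            order = config$filter$order,
                            ripple_db = config$filter$ripple_db,
                            stopband_db = config$filter$stopband_db)
    }
    spectral_entropy_series(tr, fs, window_s = config$corse$window_s,
                            overlap_frac = config$corse$overlap_frac,
                            band = band)
  })
  ids <- recording$electrode_ids
  ord <- order(ids)
  cmb <- utils::combn(ord, 2)
  tibble::tibble(
    well_id = recording$well_id,
    electrode_a = ids[cmb[1, ]],
    electrode_b = ids[cmb[2, ]],
    corse = vapply(seq_len(ncol(cmb)), function(i) {
      corse_from_series(series[[cmb[1, i]]], series[[cmb[2, i]]])
    }, numeric(1)))
}

#' Combined connectivity result for a well
#'
#' Joins STTC (from consensus spike trains) and CorSE (from raw traces,
#' when available) into one pair table plus well summaries.
#'
#' @param spikes A [spike_table()] (active electrodes recommended).
#' @param recording Optional [mea_recording()] for CorSE; `NA` CorSE
#'   values are emitted when absent.
#' @param config Configuration from [default_config()].
#' @return A list of class `mea_connectivity`: `pairs` (tibble `well_id`,
#'   `electrode_a`, `electrode_b`, `corse`, `sttc`), `well_avg_corse`,
#'   `well_sttc` (tibbles) and `edge_threshold`.
#' @export
connectivity <- function(spikes, recording = NULL,
                         config = default_config()) {
  st <- sttc_matrix(spikes, dt = config$sttc$dt_s,
                    summary = config$sttc$summary)
  pairs <- st$pairs
  if (!is.null(recording)) {
    co <- corse_matrix(recording, config)
    pairs <- dplyr::full_join(co, pairs,
                              by = c("well_id", "electrode_a",
                                     "electrode_b"))
  } else {
    pairs <- dplyr::mutate(pairs, corse = NA_real_)
  }
  pairs <- pairs |>
    dplyr::select("well_id", "electrode_a", "electrode_b", "corse",
                  "sttc") |>
    dplyr::arrange(.data$well_id, .data$electrode_a, .data$electrode_b)
  avg <- pairs |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(avg_corse = if (all(is.na(.data$corse))) NA_real_
                     else mean(.data$corse, na.rm = TRUE),
                     .groups = "drop")
  structure(list(pairs = pairs, well_avg_corse = avg,
                 well_sttc = st$well_summary,
                 edge_threshold = config$corse$edge_threshold),
            class = "mea_connectivity")
}

#' Thresholded connectivity map
#'
#' Lists the electrode pairs whose CorSE strength exceeds the edge
#' threshold (default 0.7), i.e. the most robustly connected network
#' participants, in deterministic `electrode_a < electrode_b` order.
#'
#' @param result An `mea_connectivity` from [connectivity()], or a pair
#'   tibble with a `corse` column.
#' @param edge_threshold Strength cutoff (exclusive).
#' @return A tibble of edges with their strengths.
#' @export
connectivity_map <- function(result, edge_threshold = 0.7) {
  pairs <- if (inherits(result, "mea_connectivity")) result$pairs else result
  pairs |>
    dplyr::filter(!is.na(.data$corse), .data$corse > edge_threshold) |>
    dplyr::arrange(.data$well_id, .data$electrode_a, .data$electrode_b)
}

#' Well-average CorSE
#'
#' Mean CorSE over all defined unordered electrode pairs of each well —
#' the overall connectivity strength of the network.
#'
#' @param result An `mea_connectivity` or a pair tibble with `corse`.
#' @return A tibble `well_id`, `avg_corse` (`NA` when no pair is
#'   defined).
#' @export
average_corse <- function(result) {
  pairs <- if (inherits(result, "mea_connectivity")) result$pairs else result
  pairs |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(avg_corse = if (all(is.na(.data$corse))) NA_real_
                     else mean(.data$corse, na.rm = TRUE),
                     .groups = "drop")
}
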