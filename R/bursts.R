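#' logISI burst-defining ISI threshold
#'
#' Implements the logISI histogram method: inter-spike intervals are
#' binned on a log10 axis (`bins_per_decade` bins per decade), smoothed,
#' and scanned for peaks. If a peak exists below `max_core_isi` (the
#' intra-burst peak), the histogram minimum between it and each later peak
#' is scored with the void parameter
#' `v = 1 - h_min / sqrt(h_peak1 * h_peak2)`; the minimum with the
#' largest void `>= void_threshold` defines the burst threshold `ISITh`.
#' `NULL` is returned when the train has no intra-burst peak or no
#' sufficiently deep valley (a non-bursting electrode).
#'
#' @param train Sorted spike times (s).
#' @param bins_per_decade Histogram resolution on the log10 ISI axis.
#' @param void_threshold Minimum void parameter to accept a valley.
#' @param max_core_isi Upper ISI bound for the intra-burst peak (s).
#' @param min_spikes Minimum spikes for the electrode to be considered.
#' @return `ISITh` in seconds, or `NULL`.
#' @export
logisi_threshold <- function(train, bins_per_decade = 10,
                             void_threshold = 0.7, max_core_isi = 0.1,
                             min_spikes = 5) {
  if (length(train) < max(min_spikes, 3)) return(NULL)
  isi <- diff(train)
  isi <- isi[isi > 0]
  if (length(isi) < 2) return(NULL)
  lx <- log10(isi)
  lo <- floor(min(lx) * bins_per_decade) / bins_per_decade
  hi <- ceiling(max(lx) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  breaks <- seq(lo, hi, by = 1 / bins_per_decade)
  if (length(breaks) < 4) return(NULL)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  centres <- h$mids
  counts <- h$counts
  # lowess smoothing over roughly a 5-bin span
  f <- min(1, max(5 / length(counts), 0.05))
  sm <- stats::lowess(centres, counts, f = f)$y
  sm <- pmax(sm, 0)
  pk <- find_hist_peaks(sm)
  if (length(pk) < 2) return(NULL)
  # small histogram ripples must not pass as an intra-burst mode: the
  # intra-burst peak has to carry at least 10% of the tallest peak
  intra <- pk[centres[pk] < log10(max_core_isi) &
                sm[pk] >= 0.1 * max(sm[pk])]
  if (length(intra) == 0) return(NULL)
  p1 <- intra[which.max(sm[intra])]
  later <- pk[pk > p1]
  if (length(later) == 0) return(NULL)
  for (p2 in later) {
    seg <- (p1 + 1):(p2 - 1)
    if (length(seg) == 0) next
    mn <- min(sm[seg])
    v <- 1 - mn / sqrt(sm[p1] * sm[p2])
    if (v >= void_threshold) {
      # flat minimal region: its middle bin is the deterministic tie-break
      flat <- seg[sm[seg] <= mn + 1e-12]
      return(10^centres[flat[ceiling(length(flat) / 2)]])
    }
  }
  NULL
}

# local maxima of a (smoothed) histogram, plateau-tolerant
find_hist_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  core <- 2:(n - 1)
  idx <- core[y[core] > 0 & y[core] >= y[core - 1] & y[core] > y[core + 1]]
  # also allow a peak in the first/last bin (common for tight bursts)
  if (y[1] > y[2]) idx <- c(1L, idx)
  if (y[n] > y[n - 1]) idx <- c(idx, n)
  sort(unique(idx))
}

#' Detect bursts in a single spike train
#'
#' Given a burst-defining threshold `ISITh`, bursts are maximal runs of
#' spikes whose consecutive ISIs stay within the threshold. When
#' `ISITh` exceeds `max_core_isi` (100 ms), burst cores are first built
#' from runs with ISI <= `max_core_isi` and then extended at both edges
#' across ISIs <= `ISITh` (cores bridged by such ISIs merge). Runs with
#' fewer than `min_spikes` spikes (default 5) are discarded. Burst bounds
#' are the first and last member spike times.
#'
#' @param train Sorted spike times (s).
#' @param isi_threshold `ISITh` in seconds (> 0).
#' @param min_spikes Minimum spikes per burst.
#' @param max_core_isi Core ISI bound (s).
#' @return A tibble `t_start_s`, `t_end_s`, `n_spikes` (zero rows when no
#'   burst qualifies).
#' @export
detect_bursts <- function(train, isi_threshold, min_spikes = 5,
                          max_core_isi = 0.1) {
  stopifnot(isi_threshold > 0)
  empty <- tibble::tibble(t_start_s = numeric(), t_end_s = numeric(),
                          n_spikes = integer())
  n <- length(train)
  if (n < min_spikes) return(empty)
  isi <- diff(train)
  within <- isi <= isi_threshold
  runs <- isi_runs(within)
  if (isi_threshold > max_core_isi && nrow(runs) > 0) {
    # a run only counts as a burst if it contains a core ISI; edge
    # extension across ISIs <= ISITh is implied by run maximality
    has_core <- vapply(seq_len(nrow(runs)), function(r) {
      any(isi[runs$from[r]:runs$to[r]] <= max_core_isi)
    }, logical(1))
    runs <- runs[has_core, , drop = FALSE]
  }
  if (nrow(runs) == 0) return(empty)
  out <- tibble::tibble(
    t_start_s = train[runs$from],
    t_end_s = train[runs$to + 1L],
    n_spikes = as.integer(runs$to - runs$from + 2L))
  out[out$n_spikes >= min_spikes, , drop = FALSE]
}

# maximal runs of TRUE in a logical ISI vector; from/to are ISI indices
isi_runs <- function(within) {
  r <- rle(within)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from = starts[keep], to = ends[keep])
}

#' Merge bursts separated by short gaps
#'
#' When the computed ISI threshold is below `merge_gap` (100 ms),
#' consecutive bursts whose separation (next start minus previous end) is
#' shorter than `merge_gap` are unioned, summing their spike counts.
#' `merge_gap` thus acts as the minimum time required between distinct
#' bursts. With `ISITh >= merge_gap` the rule is inactive. The operation
#' is idempotent.
#'
#' @param bursts Tibble `t_start_s`, `t_end_s`, `n_spikes`, sorted and
#'   non-overlapping.
#' @param isi_threshold The `ISITh` that produced the bursts (s).
#' @param merge_gap Minimum inter-burst separation (s).
#' @return A tibble of the same shape.
#' @export
merge_bursts <- function(bursts, isi_threshold, merge_gap = 0.1) {
  if (nrow(bursts) < 2 || isi_threshold >= merge_gap) return(bursts)
  start <- bursts$t_start_s
  end <- bursts$t_end_s
  nsp <- as.integer(bursts$n_spikes)
  o_start <- start[1]
  o_end <- end[1]
  o_n <- nsp[1]
  res <- list()
  for (i in 2:nrow(bursts)) {
    if (start[i] - o_end < merge_gap) {
      o_end <- end[i]
      o_n <- o_n + nsp[i]
    } else {
      res[[length(res) + 1]] <- c(o_start, o_end, o_n)
      o_start <- start[i]
      o_end <- end[i]
      o_n <- nsp[i]
    }
  }
  res[[length(res) + 1]] <- c(o_start, o_end, o_n)
  m <- do.call(rbind, res)
  tibble::tibble(t_start_s = m[, 1], t_end_s = m[, 2],
                 n_spikes = as.integer(m[, 3]))
}

#' Burst detection across a spike table
#'
#' Runs [logisi_threshold()], [detect_bursts()] and [merge_bursts()] on
#' every (well, electrode) train of a spike table. Electrodes for which
#' the logISI method finds no threshold are treated as non-bursting and
#' contribute no bursts.
#'
#' @param spikes A [spike_table()].
#' @param config Configuration from [default_config()].
#' @return A list of class `mea_bursts`: `bursts` (tibble `well_id`,
#'   `electrode_id`, `t_start_s`, `t_end_s`, `n_spikes`) and `thresholds`
#'   (tibble `well_id`, `electrode_id`, `isi_threshold_s`, `NA` for
#'   non-bursting electrodes), plus the recording `duration_s`.
#' @export
#' @examples
#' tr <- as.vector(outer(seq(0, 0.025, by = 0.005), seq(0, 19), "+"))
#' spikes <- spike_table(data.frame(well_id = "W1", electrode_id = "E01",
#'                                  time_s = tr), duration_s = 20)
#' fb <- find_bursts(spikes)
#' nrow(fb$bursts)
find_bursts <- function(spikes, config = default_config()) {
  cfg <- config$logisi
  dur <- spike_duration(spikes)
  groups <- tibble::as_tibble(spikes) |>
    dplyr::group_by(.data$well_id, .data$electrode_id) |>
    dplyr::group_split()
  thr_rows <- vector("list", length(groups))
  burst_rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    train <- g$time_s
    isith <- logisi_threshold(train, bins_per_decade = cfg$bins_per_decade,
                              void_threshold = cfg$void_threshold,
                              max_core_isi = cfg$max_core_isi_s,
                              min_spikes = cfg$min_spikes)
    thr_rows[[i]] <- tibble::tibble(well_id = g$well_id[1],
                                    electrode_id = g$electrode_id[1],
                                    isi_threshold_s = isith %||% NA_real_)
    if (is.null(isith)) next
    b <- detect_bursts(train, isith, min_spikes = cfg$min_spikes,
                       max_core_isi = cfg$max_core_isi_s)
    b <- merge_bursts(b, isith, merge_gap = config$burst$merge_gap_s)
    if (nrow(b) > 0) {
      burst_rows[[i]] <- tibble::tibble(well_id = g$well_id[1],
                                        electrode_id = g$electrode_id[1], b)
    }
  }
  bursts <- dplyr::bind_rows(burst_rows)
  if (nrow(bursts) == 0) {
    bursts <- tibble::tibble(well_id = character(),
                             electrode_id = character(),
                             t_start_s = numeric(), t_end_s = numeric(),
                             n_spikes = integer())
  }
  structure(list(bursts = bursts, thresholds = dplyr::bind_rows(thr_rows),
                 duration_s = dur),
            class = "mea_bursts")
}

#' Electrode-level burst features
#'
#' For each bursting electrode: bursts per minute, median burst duration,
#' median spikes per burst, median spike frequency in burst (by default
#' the ISI-based rate `(n_spikes - 1) / duration`), and the percentage of
#' the electrode's spikes that fall inside bursts. Non-bursting
#' electrodes are excluded (they have no rows).
#'
#' @param bursts An `mea_bursts` result from [find_bursts()], or a burst
#'   tibble.
#' @param spikes The [spike_table()] the bursts came from (needed for
#'   total spike counts).
#' @param rate_definition `"isi"` for `(n-1)/duration` or `"count"` for
#'   `n/duration`.
#' @param duration_floor_s Lower bound applied to burst durations before
#'   dividing (guards a degenerate zero-length burst).
#' @return A tibble with one row per bursting electrode.
#' @export
burst_features <- function(bursts, spikes, rate_definition = "isi",
                           duration_floor_s = 8e-5) {
  b <- if (inherits(bursts, "mea_bursts")) bursts$bursts else bursts
  dur <- if (inherits(bursts, "mea_bursts")) bursts$duration_s
         else spike_duration(spikes)
  if (nrow(b) == 0) {
    return(tibble::tibble(well_id = character(), electrode_id = character(),
                          burst_rate_per_min = numeric(),
                          burst_duration_s = numeric(),
                          spikes_in_burst = numeric(),
                          spike_freq_in_burst_hz = numeric(),
                          pct_spikes_in_bursts = numeric()))
  }
  totals <- tibble::as_tibble(spikes) |>
    dplyr::count(.data$well_id, .data$electrode_id, name = "n_total")
  b |>
    dplyr::mutate(
      dur_b = pmax(.data$t_end_s - .data$t_start_s, duration_floor_s),
      freq = if (rate_definition == "isi") (.data$n_spikes - 1) / .data$dur_b
             else .data$n_spikes / .data$dur_b) |>
    dplyr::group_by(.data$well_id, .data$electrode_id) |>
    dplyr::summarise(
      burst_rate_per_min = 60 * dplyr::n() / dur,
      burst_duration_s = stats::median(.data$dur_b),
      spikes_in_burst = stats::median(.data$n_spikes),
      spike_freq_in_burst_hz = stats::median(.data$freq),
      n_in_bursts = sum(.data$n_spikes),
      .groups = "drop") |>
    dplyr::left_join(totals, by = c("well_id", "electrode_id")) |>
    dplyr::mutate(pct_spikes_in_bursts = 100 * .data$n_in_bursts /
                    .data$n_total) |>
    dplyr::select(-"n_in_bursts", -"n_total")
}

#' Well-level burst features
#'
#' Aggregates [burst_features()] to one row per well by taking the median
#' across bursting electrodes of each feature. Wells with no bursting
#' electrode are absent from the result.
#'
#' @param electrode_features Tibble from [burst_features()].
#' @return A tibble with one row per well.
#' @export
well_burst_features <- function(electrode_features) {
  electrode_features |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(dplyr::across(
      c("burst_rate_per_min", "burst_duration_s", "spikes_in_burst",
        "spike_freq_in_burst_hz", "pct_spikes_in_bursts"),
      stats::median),
      n_bursting_electrodes = dplyr::n(), .groups = "drop")
}
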