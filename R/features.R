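#' Mean firing rate over active electrodes
#'
#' @param spikes A [spike_table()].
#' @param active Optional tibble from [active_electrodes()]; when given,
#'   only electrodes with `active == TRUE` contribute. Electrodes listed
#'   as active but absent from the spike table count as 0 Hz.
#' @return A tibble `well_id`, `mfr_hz` (mean over active electrodes of
#'   spike count / duration); wells with no active electrode are absent.
#' @export
mean_firing_rate <- function(spikes, active = NULL) {
  dur <- spike_duration(spikes)
  counts <- tibble::as_tibble(spikes) |>
    dplyr::count(.data$well_id, .data$electrode_id, name = "n_spikes")
  if (!is.null(active)) {
    act <- dplyr::filter(active, .data$active)
    counts <- act |>
      dplyr::select("well_id", "electrode_id") |>
      dplyr::left_join(counts, by = c("well_id", "electrode_id")) |>
      dplyr::mutate(n_spikes = dplyr::coalesce(.data$n_spikes, 0L))
  }
  counts |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(mfr_hz = mean(.data$n_spikes / dur), .groups = "drop")
}

#' Assemble the 7-feature activity vector per well
#'
#' Runs the burst and synchrony summaries needed for the canonical
#' 7-feature vector (MFR, burst rate, burst duration, spike frequency in
#' burst, spikes in burst, percentage of spikes in bursts, STTC) for one
#' spike table / timepoint. The active-electrode rule is applied before
#' MFR and STTC.
#'
#' @param spikes A [spike_table()].
#' @param timepoint Label attached to every row (e.g. `"day24"`).
#' @param config Configuration from [default_config()].
#' @return A tibble with columns `well_id`, `timepoint` and the seven
#'   features; wells missing a feature (e.g. no bursting electrode) carry
#'   `NA` there.
#' @export
well_features <- function(spikes, timepoint = "t0",
                          config = default_config()) {
  act <- active_electrodes(spikes,
                           min_spikes_per_min =
                             config$activity$min_spikes_per_min)
  keep <- dplyr::filter(act, .data$active)
  sp_act <- tibble::as_tibble(spikes) |>
    dplyr::semi_join(keep, by = c("well_id", "electrode_id"))
  sp_act <- as_spike_table(sp_act, spike_duration(spikes))
  wells <- unique(spikes$well_id)
  if (nrow(sp_act) == 0) {
    return(tibble::tibble(well_id = wells, timepoint = timepoint,
                          mfr_hz = NA_real_, burst_rate_per_min = NA_real_,
                          burst_duration_s = NA_real_,
                          spike_freq_in_burst_hz = NA_real_,
                          spikes_in_burst = NA_real_,
                          pct_spikes_in_bursts = NA_real_,
                          sttc = NA_real_))
  }
  mfr <- mean_firing_rate(sp_act, active = act)
  bursts <- find_bursts(sp_act, config)
  bf <- burst_features(bursts, sp_act,
                       rate_definition = config$burst$rate_definition,
                       duration_floor_s = config$burst$duration_floor_s)
  wf <- well_burst_features(bf)
  st <- sttc_matrix(sp_act, dt = config$sttc$dt_s,
                    summary = config$sttc$summary)
  tibble::tibble(well_id = wells, timepoint = timepoint) |>
    dplyr::left_join(mfr, by = "well_id") |>
    dplyr::left_join(dplyr::select(wf, "well_id", "burst_rate_per_min",
                                   "burst_duration_s",
                                   "spike_freq_in_burst_hz",
                                   "spikes_in_burst",
                                   "pct_spikes_in_bursts"),
                     by = "well_id") |>
    dplyr::left_join(st$well_summary, by = "well_id") |>
    dplyr::select(dplyr::all_of(feature_csv_columns()))
}

#' Build the samples-by-features matrix for PCA
#'
#' Binds per-timepoint feature tables into one matrix with the canonical
#' column order, dropping (with a message) any (well, timepoint) sample
#' with a missing feature.
#'
#' @param features A tibble with the columns of [well_features()]
#'   (several timepoints may be row-bound), optionally with extra label
#'   columns (e.g. `group`) that are carried through.
#' @return A list: `matrix` (numeric, rows named `well_id@timepoint`),
#'   `labels` (tibble of the retained rows' label columns).
#' @export
build_feature_matrix <- function(features) {
  cols <- feature_columns()
  miss <- setdiff(c("well_id", "timepoint", cols), names(features))
  if (length(miss) > 0) {
    stop("feature table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(features[cols])
  if (any(!complete)) {
    dropped <- features[!complete, c("well_id", "timepoint")]
    message("dropping ", sum(!complete),
            " sample(s) with missing features: ",
            paste(paste0(dropped$well_id, "@", dropped$timepoint),
                  collapse = ", "))
  }
  kept <- features[complete, , drop = FALSE]
  if (nrow(kept) == 0) stop("no complete feature vectors to analyse",
                            call. = FALSE)
  m <- as.matrix(kept[cols])
  rownames(m) <- paste0(kept$well_id, "@", kept$timepoint)
  list(matrix = m,
       labels = kept[setdiff(names(kept), cols)])
}

#' Standard-score normalisation
#'
#' Centres each column to mean 0 and scales to SD 1. The SD is the
#' population SD (divide by n) by default, the conventional definition of
#' the standard score; `sd_type = "sample"` divides by n - 1.
#'
#' @param m Numeric matrix (samples x features).
#' @param sd_type `"population"` or `"sample"`.
#' @return The z-scored matrix.
#' @export
zscore <- function(m, sd_type = "population") {
  m <- as.matrix(m)
  mu <- colMeans(m)
  centred <- sweep(m, 2, mu)
  denom <- if (sd_type == "sample") nrow(m) - 1 else nrow(m)
  sdv <- sqrt(colSums(centred^2) / denom)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    stop("zero-variance feature(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(centred, 2, sdv, "/")
}

#' Principal component analysis of the feature matrix
#'
#' Eigendecomposition of the sample covariance of a (z-scored) matrix.
#' Components are sorted by decreasing variance; each component's sign is
#' fixed so its largest-magnitude loading is positive, making scores
#' reproducible. All components are retained in the result (so explained
#' percentages sum to 100); `n_components` records how many are meant for
#' plotting and downstream separation scores.
#'
#' @param m Numeric matrix, typically from [zscore()].
#' @param n_components Number of leading components of interest.
#' @param labels Optional tibble of per-row labels carried into the
#'   scores.
#' @return An object of class `mea_pca`: `scores` (tibble with `PC1..PCk`
#'   and label columns), `loadings` (features x components matrix),
#'   `explained_pct` (all components), `n_components`.
#' @export
pca_project <- function(m, n_components = 3, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  cv <- stats::cov(m)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rank <- sum(vals > max(vals) * 1e-12)
  if (rank < n_components) {
    warning("requested ", n_components, " components but matrix rank is ",
            rank, "; returning ", rank, call. = FALSE)
    n_components <- rank
  }
  explained <- 100 * vals / sum(vals)
  scores <- m %*% vecs
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(vecs) <- colnames(m)
  colnames(vecs) <- colnames(scores)
  scores_tbl <- tibble::as_tibble(scores)
  scores_tbl <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(m) %||%
                     as.character(seq_len(nrow(m)))),
    scores_tbl)
  if (!is.null(labels)) scores_tbl <- dplyr::bind_cols(scores_tbl, labels)
  structure(list(scores = scores_tbl, loadings = vecs,
                 explained_pct = explained,
                 n_components = as.integer(n_components)),
            class = "mea_pca")
}

#' Group separation in PC space
#'
#' Mean silhouette coefficient of a labelled grouping in the first `k`
#' principal-component coordinates: 1 for perfectly separated compact
#' groups, near 0 for arbitrary labels, negative for misassigned ones.
#' Singleton groups contribute a coefficient of 0 (the silhouette
#' convention).
#'
#' @param pca An `mea_pca` from [pca_project()], or a numeric score
#'   matrix.
#' @param labels Group label per sample (>= 2 distinct values).
#' @param k Number of leading components to use.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
group_separation <- function(pca, labels, k = 3) {
  scores <- if (inherits(pca, "mea_pca")) {
    as.matrix(pca$scores[paste0("PC", seq_len(min(k, pca$n_components)))])
  } else {
    as.matrix(pca)[, seq_len(min(k, ncol(as.matrix(pca)))), drop = FALSE]
  }
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) {
    stop("group_separation needs at least two distinct labels",
         call. = FALSE)
  }
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Percent change from baseline
#'
#' Pharmacology summary: `100 * (treatment - baseline) / baseline`, e.g.
#' the percentage change in spike rate after drug application relative to
#' the same well's baseline recording. Non-positive baselines give `NA`
#' with a warning.
#'
#' @param baseline,treatment Numeric vectors (recycled as usual).
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(2, 3)   # +50
#' percent_change(2, 0)   # -100 (complete silencing)
percent_change <- function(baseline, treatment) {
  out <- 100 * (treatment - baseline) / baseline
  bad <- !is.na(baseline) & baseline <= 0
  if (any(bad)) {
    warning(sum(bad), " baseline value(s) <= 0: percent change undefined",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}
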