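#' Run the full analysis pipeline
#'
#' End-to-end orchestration for one or more wells: consensus spike
#' detection (when raw recordings are supplied), the active-electrode
#' rule, logISI burst detection, STTC and CorSE connectivity, the
#' 7-feature table, and — when at least two complete (well, timepoint)
#' samples exist — PCA. All stage outputs are written as CSV under
#' `outdir` together with a JSON run manifest recording the configuration
#' snapshot, seed, input/output content hashes and per-stage record
#' counts, so a run can be audited and reproduced byte for byte.
#'
#' @param raw A single [mea_recording()], a list of them, or a named list
#'   `timepoint -> list(recordings)`; detection is run on these. Omit to
#'   start from spike tables.
#' @param spikes A [spike_table()] or named list `timepoint ->
#'   spike_table`; used directly when `raw` is `NULL` (detection is
#'   skipped).
#' @param config Configuration from [default_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and used for any
#'   stage randomness.
#' @return A list of class `mea_run`: `spikes`, `active`, `bursts`
#'   (tibble), `connectivity` (pair tibble), `features`, `pca` (or
#'   `NULL`), `manifest`.
#' @export
run_pipeline <- function(raw = NULL, spikes = NULL,
                         config = default_config(), outdir = tempfile(),
                         seed = config$seed %||% 1L) {
  if (is.null(raw) && is.null(spikes)) {
    stop("supply raw recordings or a spike table", call. = FALSE)
  }
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))

  # normalise inputs to: list(timepoint -> list of per-well spike tables)
  detection_reports <- list()
  if (!is.null(raw)) {
    if (inherits(raw, "mea_recording")) raw <- list(t0 = list(raw))
    if (length(raw) > 0 && inherits(raw[[1]], "mea_recording")) {
      raw <- list(t0 = raw)
    }
    spike_sets <- purrr::imap(raw, function(recs, tp) {
      dets <- purrr::map(recs, detect_spikes, config = config)
      detection_reports[[tp]] <<- dplyr::bind_rows(
        purrr::map(dets, "per_electrode"))
      durs <- purrr::map_dbl(dets, function(d) spike_duration(d$spikes))
      as_spike_table(dplyr::bind_rows(purrr::map(dets, function(d)
        tibble::as_tibble(d$spikes))), max(durs))
    })
  } else {
    if (inherits(spikes, "mea_spikes")) spike_sets <- list(t0 = spikes)
    else spike_sets <- spikes
  }

  all_spikes <- list()
  all_active <- list()
  all_bursts <- list()
  all_pairs <- list()
  all_features <- list()
  for (tp in names(spike_sets)) {
    sp <- spike_sets[[tp]]
    act <- active_electrodes(sp, config$activity$min_spikes_per_min)
    sp_act <- tibble::as_tibble(sp) |>
      dplyr::semi_join(dplyr::filter(act, .data$active),
                       by = c("well_id", "electrode_id"))
    sp_act <- as_spike_table(sp_act, spike_duration(sp))
    fb <- find_bursts(sp_act, config)
    conn <- connectivity(sp_act, recording = NULL, config = config)
    feats <- well_features(sp, timepoint = tp, config = config)
    all_spikes[[tp]] <- tibble::as_tibble(sp) |>
      dplyr::mutate(timepoint = tp)
    all_active[[tp]] <- dplyr::mutate(act, timepoint = tp)
    all_bursts[[tp]] <- dplyr::mutate(fb$bursts, timepoint = tp)
    all_pairs[[tp]] <- dplyr::mutate(conn$pairs, timepoint = tp)
    all_features[[tp]] <- feats
  }
  features <- dplyr::bind_rows(all_features)

  pca <- NULL
  complete <- stats::complete.cases(features[feature_columns()])
  if (sum(complete) >= 3) {
    fm <- build_feature_matrix(features)
    z <- zscore(fm$matrix, sd_type = config$pca$sd_type)
    pca <- pca_project(z, n_components = config$pca$n_components,
                       labels = fm$labels)
  }

  # stage outputs
  paths <- list(
    spikes = file.path(outdir, "spikes.csv"),
    bursts = file.path(outdir, "bursts.csv"),
    connectivity = file.path(outdir, "connectivity.csv"),
    features = file.path(outdir, "features.csv"))
  spikes_out <- dplyr::bind_rows(all_spikes)
  write_spike_table(spikes_out[c("well_id", "electrode_id", "time_s")],
                    paths$spikes)
  bursts_out <- dplyr::bind_rows(all_bursts)
  write_burst_table(bursts_out, paths$bursts)
  pairs_out <- dplyr::bind_rows(all_pairs)
  write_connectivity_table(pairs_out, paths$connectivity)
  write_feature_table(features, paths$features)
  if (!is.null(pca)) {
    paths$pca_scores <- file.path(outdir, "pca_scores.csv")
    utils::write.csv(pca$scores, paths$pca_scores, row.names = FALSE,
                     quote = FALSE)
    paths$pca_variance <- file.path(outdir, "pca_variance.csv")
    utils::write.csv(
      data.frame(component = paste0("PC",
                                    seq_along(pca$explained_pct)),
                 explained_pct = pca$explained_pct),
      paths$pca_variance, row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    config = unclass(config),
    counts = list(
      spikes = nrow(spikes_out), bursts = nrow(bursts_out),
      connectivity_pairs = nrow(pairs_out),
      feature_rows = nrow(features),
      pca_samples = if (is.null(pca)) 0L else nrow(pca$scores)),
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(spikes = spikes_out,
                 active = dplyr::bind_rows(all_active),
                 bursts = bursts_out, connectivity = pairs_out,
                 features = features, pca = pca,
                 detection = if (length(detection_reports) > 0)
                   dplyr::bind_rows(detection_reports) else NULL,
                 manifest = manifest, outdir = outdir),
            class = "mea_run")
}

#' Simulate a two-phenotype plate experiment
#'
#' Convenience wrapper used throughout the package's validation: for each
#' phenotype preset, simulates `n_wells` wells at `n_timepoints`
#' timepoints (fresh seeds per well/timepoint derived from `seed`) and
#' computes the 7-feature table with group labels, ready for
#' [build_feature_matrix()] and [pca_project()].
#'
#' @param presets Named list of [network_params()] (names become group
#'   labels).
#' @param n_wells Wells per group.
#' @param n_timepoints Timepoints per well.
#' @param duration_s Recording length per sample (s).
#' @param n_electrodes Electrodes per well.
#' @param seed Base integer seed.
#' @param config Configuration from [default_config()].
#' @return A feature tibble with an extra `group` column.
#' @export
simulate_plate_features <- function(presets = list(hPSC = preset("hPSC_peak"),
                                                   rat = preset("rat_peak")),
                                    n_wells = 12, n_timepoints = 3,
                                    duration_s = 600, n_electrodes = 16,
                                    seed = 1L,
                                    config = default_config()) {
  rows <- list()
  counter <- 0L
  for (g in names(presets)) {
    par <- presets[[g]]
    par$duration_s <- duration_s
    par$n_electrodes <- as.integer(n_electrodes)
    for (w in seq_len(n_wells)) {
      for (tp in seq_len(n_timepoints)) {
        counter <- counter + 1L
        seed_i <- (as.integer(seed) %% 100000L) * 10000L + counter
        truth <- simulate_trains(par, seed = seed_i,
                                 well_id = sprintf("%s_W%02d", g, w))
        f <- well_features(truth$spikes,
                           timepoint = sprintf("t%d", tp), config = config)
        f$group <- g
        rows[[length(rows) + 1L]] <- f
      }
    }
  }
  dplyr::bind_rows(rows)
}
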