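#' Tidy a PCA result
#'
#' Returns the loadings in long form: one row per (feature, component)
#' with the loading value, in the style of broom tidiers.
#'
#' @param x An `mea_pca` from [pca_project()].
#' @param ... Unused.
#' @return A tibble `feature`, `component`, `loading`.
#' @export
tidy.mea_pca <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    feature = rep(rownames(l), times = ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l))
}

#' @rdname tidy.mea_pca
#' @return `glance()` returns a one-row tibble with the number of
#'   samples, components of interest, and the variance explained by the
#'   first three components.
#' @export
glance.mea_pca <- function(x, ...) {
  e <- x$explained_pct
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = x$n_components,
    pc1_pct = e[1],
    pc2_pct = if (length(e) >= 2) e[2] else NA_real_,
    pc3_pct = if (length(e) >= 3) e[3] else NA_real_,
    total_first3_pct = sum(e[seq_len(min(3, length(e)))]))
}

#' Tidy a detection result
#'
#' One row per electrode with the candidate counts of both detectors, the
#' consensus count and the noise SD estimate.
#'
#' @param x An `mea_detection` from [detect_spikes()].
#' @param ... Unused.
#' @export
tidy.mea_detection <- function(x, ...) x$per_electrode

#' @rdname tidy.mea_detection
#' @export
glance.mea_detection <- function(x, ...) {
  tibble::tibble(
    n_electrodes = nrow(x$per_electrode),
    n_spikes = nrow(x$spikes),
    median_sigma_hat = stats::median(x$per_electrode$sigma_hat),
    duration_s = spike_duration(x$spikes))
}

#' Tidy a burst result
#'
#' @param x An `mea_bursts` from [find_bursts()].
#' @param ... Unused.
#' @return The burst tibble joined with each electrode's ISI threshold.
#' @export
tidy.mea_bursts <- function(x, ...) {
  dplyr::left_join(x$bursts, x$thresholds,
                   by = c("well_id", "electrode_id"))
}

#' @rdname tidy.mea_bursts
#' @export
glance.mea_bursts <- function(x, ...) {
  tibble::tibble(
    n_bursts = nrow(x$bursts),
    n_bursting_electrodes = nrow(unique(x$bursts[c("well_id",
                                                   "electrode_id")])),
    n_electrodes = nrow(x$thresholds),
    duration_s = x$duration_s)
}

#' Plot PCA scores
#'
#' Scatter of the first two principal components, coloured by a label
#' column when present (`group` by default), with explained-variance
#' percentages in the axis titles.
#'
#' @param object An `mea_pca` from [pca_project()].
#' @param colour Name of a label column in `object$scores` to colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mea_pca <- function(object, colour = "group", ...) {
  df <- object$scores
  e <- object$explained_pct
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = sprintf("PC1 (%.1f%%)", e[1]),
                    y = sprintf("PC2 (%.1f%%)", e[2])) +
    ggplot2::theme_minimal()
}

#' Raster plot of a spike table
#'
#' Classic MEA raster: one row per electrode, a tick per spike, faceted
#' by well, with detected bursts overlaid as horizontal segments when
#' supplied.
#'
#' @param spikes A [spike_table()].
#' @param bursts Optional burst tibble (e.g. `find_bursts(spikes)$bursts`).
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, bursts = NULL) {
  df <- tibble::as_tibble(spikes)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$electrode_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::facet_wrap(~well_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(bursts) && nrow(bursts) > 0) {
    p <- p + ggplot2::geom_segment(
      data = bursts,
      ggplot2::aes(x = .data$t_start_s, xend = .data$t_end_s,
                   y = .data$electrode_id, yend = .data$electrode_id),
      colour = "forestgreen", linewidth = 1.5, alpha = 0.6)
  }
  p
}

#' Plot a thresholded connectivity map
#'
#' Electrodes on a circle, with an edge for every pair whose CorSE
#' exceeds the threshold; edge opacity encodes strength.
#'
#' @param result An `mea_connectivity` from [connectivity()] or an edge
#'   tibble from [connectivity_map()].
#' @param edge_threshold Strength cutoff (used when `result` is a full
#'   connectivity object).
#' @return A ggplot object.
#' @export
plot_connectivity_map <- function(result, edge_threshold = 0.7) {
  edges <- if (inherits(result, "mea_connectivity")) {
    connectivity_map(result, edge_threshold)
  } else result
  ids <- sort(unique(c(edges$electrode_a, edges$electrode_b)))
  theta <- seq(0, 2 * pi, length.out = length(ids) + 1)[seq_along(ids)]
  pos <- tibble::tibble(id = ids, x = cos(theta), y = sin(theta))
  edges <- edges |>
    dplyr::left_join(pos, by = c(electrode_a = "id")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    dplyr::left_join(pos, by = c(electrode_b = "id")) |>
    dplyr::rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       alpha = .data$corse)) +
    ggplot2::geom_point(data = pos, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$id), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
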