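#' Build a spike table
#'
#' A spike table is the package's central container: a tibble with columns
#' `well_id`, `electrode_id` and `time_s` (seconds from recording start,
#' 0-based), carrying the recording duration as an attribute. Spike times
#' are kept at 1 microsecond resolution and must be strictly increasing
#' within each electrode.
#'
#' @param x A data frame with columns `well_id`, `electrode_id`, `time_s`.
#' @param duration_s Recording length in seconds (default 600, a standard
#'   10-minute session).
#' @return A tibble of class `mea_spikes`, sorted by (well, electrode, time).
#' @export
#' @examples
#' spikes <- spike_table(
#'   data.frame(well_id = "W1", electrode_id = "E01",
#'              time_s = c(0.1, 0.25, 0.9)),
#'   duration_s = 10)
#' spike_duration(spikes)
spike_table <- function(x, duration_s = 600) {
  stopifnot(is.data.frame(x))
  need <- c("well_id", "electrode_id", "time_s")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("spike table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    stop("duration_s must be a single positive number", call. = FALSE)
  }
  out <- tibble::as_tibble(x[need])
  out$well_id <- as.character(out$well_id)
  out$electrode_id <- as.character(out$electrode_id)
  out$time_s <- round(as.numeric(out$time_s), 6)
  out <- dplyr::arrange(out, .data$well_id, .data$electrode_id, .data$time_s)
  validate_spike_table(out, duration_s)
  structure(out, duration_s = duration_s,
            class = c("mea_spikes", class(tibble::tibble())))
}

validate_spike_table <- function(x, duration_s) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$time_s < 0) || any(x$time_s > duration_s)) {
    stop("spike times must lie in [0, duration]", call. = FALSE)
  }
  bad <- x |>
    dplyr::group_by(.data$well_id, .data$electrode_id) |>
    dplyr::summarise(ok = all(diff(.data$time_s) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("non-monotone spike times for electrode(s): ",
         paste(paste(bad$well_id, bad$electrode_id, sep = "/"),
               collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' @rdname spike_table
#' @param spikes A `mea_spikes` table.
#' @export
spike_duration <- function(spikes) {
  d <- attr(spikes, "duration_s")
  if (is.null(d)) stop("not a spike table: missing duration attribute",
                       call. = FALSE)
  d
}

#' Construct a raw MEA recording
#'
#' Holds one well's multichannel extracellular voltage traces: an
#' electrodes-by-samples matrix in microvolts together with the sampling
#' rate and electrode identities.
#'
#' @param traces Numeric matrix, one row per electrode (microvolts).
#' @param fs Sampling rate in Hz.
#' @param electrode_ids Character vector of unique electrode labels, one
#'   per row of `traces`.
#' @param well_id Well label.
#' @param t0 Recording start time in seconds (default 0).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(traces, fs, electrode_ids = NULL, well_id = "W1",
                          t0 = 0) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  storage.mode(traces) <- "double"
  n <- nrow(traces)
  if (is.null(electrode_ids)) electrode_ids <- sprintf("E%02d", seq_len(n))
  if (ncol(traces) < 1) stop("traces must have at least one sample",
                             call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (n < 1 || n > 64) stop("electrode count must be in 1..64", call. = FALSE)
  electrode_ids <- as.character(electrode_ids)
  if (length(electrode_ids) != n || anyDuplicated(electrode_ids) > 0) {
    stop("electrode_ids must be unique and match the number of trace rows",
         call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), electrode_ids = electrode_ids,
         traces = traces, fs = as.numeric(fs), t0 = as.numeric(t0)),
    class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> well %s: %d electrodes x %d samples @ %g Hz (%.1f s)\n",
              x$well_id, nrow(x$traces), ncol(x$traces), x$fs,
              ncol(x$traces) / x$fs))
  invisible(x)
}

#' @export
print.mea_spikes <- function(x, ...) {
  cat(sprintf("# Spike table: %d spikes, %d electrode(s), duration %g s\n",
              nrow(x), nrow(unique(x[c("well_id", "electrode_id")])),
              attr(x, "duration_s")))
  NextMethod()
}

# restore class/attribute after dplyr operations used internally
as_spike_table <- function(df, duration_s) {
  structure(tibble::as_tibble(df), duration_s = duration_s,
            class = c("mea_spikes", class(tibble::tibble())))
}
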