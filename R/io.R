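#' Read and write raw MEA recordings
#'
#' Raw multichannel voltage traces are stored in a single self-describing
#' file: one JSON header line (magic `MEARAW1`) holding `fs_hz`,
#' `units = "uV"`, `well_id`, `electrode_ids`, `n_samples` and `t0_s`,
#' followed by the trace matrix as little-endian float32, one electrode row
#' after another. Values therefore round-trip exactly at float32 precision.
#'
#' @param path File path.
#' @return `read_raw_recording()` returns an [mea_recording()];
#'   `write_raw_recording()` returns `path` invisibly.
#' @export
read_raw_recording <- function(path) {
  if (!file.exists(path)) stop("raw file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readLines(con, n = 1, warn = FALSE)
  if (!startsWith(header, "MEARAW1 ")) {
    stop("not a raw recording file (missing MEARAW1 header): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^MEARAW1 ", "", header))
  for (field in c("fs_hz", "units", "well_id", "electrode_ids", "n_samples")) {
    if (is.null(meta[[field]])) {
      stop("raw file header is missing '", field, "': ", path, call. = FALSE)
    }
  }
  if (!identical(meta$units, "uV")) {
    stop("raw file units must be 'uV', found '", meta$units, "'",
         call. = FALSE)
  }
  n_el <- length(meta$electrode_ids)
  n_samp <- as.integer(meta$n_samples)
  vals <- readBin(con, "numeric", n = n_el * n_samp + 1, size = 4,
                  endian = "little")
  if (length(vals) != n_el * n_samp) {
    stop("raw file payload has wrong length (ragged or truncated traces): ",
         path, call. = FALSE)
  }
  traces <- matrix(vals, nrow = n_el, ncol = n_samp, byrow = TRUE)
  mea_recording(traces, fs = meta$fs_hz,
                electrode_ids = as.character(meta$electrode_ids),
                well_id = meta$well_id,
                t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

#' @param recording An [mea_recording()].
#' @param overwrite Allow replacing an existing file (default `TRUE`).
#' @rdname read_raw_recording
#' @export
write_raw_recording <- function(recording, path, overwrite = TRUE) {
  stopifnot(inherits(recording, "mea_recording"))
  if (file.exists(path) && !overwrite) {
    stop("file exists and overwrite = FALSE: ", path, call. = FALSE)
  }
  meta <- list(fs_hz = recording$fs, units = "uV",
               well_id = recording$well_id,
               electrode_ids = recording$electrode_ids,
               n_samples = ncol(recording$traces), t0_s = recording$t0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("MEARAW1 ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con, sep = "\n")
  writeBin(as.vector(t(recording$traces)), con, size = 4, endian = "little")
  invisible(path)
}

csv_write <- function(lines, path) {
  con <- file(path, "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read and write spike tables as CSV
#'
#' The on-disk dialect is a UTF-8, LF-terminated CSV with header
#' `well_id,electrode_id,time_s`, rows sorted by (well, electrode, time),
#' and times printed with exactly 6 decimals (1 microsecond, lossless for a
#' 12.5 kHz sample clock). Reading validates monotonicity per electrode and
#' never repairs a malformed file.
#'
#' @param path File path.
#' @param duration_s Recording duration in seconds (the CSV stores spike
#'   times only).
#' @return `read_spike_table()` returns a [spike_table()];
#'   `write_spike_table()` returns `path` invisibly.
#' @export
read_spike_table <- function(path, duration_s = 600) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric"))
  need <- c("well_id", "electrode_id", "time_s")
  if (!identical(names(df), need)) {
    stop("spike CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  # sortedness within electrode is part of the format: check before the
  # constructor re-sorts
  if (nrow(df) > 1) {
    grp <- paste(df$well_id, df$electrode_id, sep = "\r")
    for (g in unique(grp)) {
      t <- df$time_s[grp == g]
      if (any(diff(t) <= 0)) {
        stop("spike CSV has out-of-order or duplicate times for electrode ",
             gsub("\r", "/", g), call. = FALSE)
      }
    }
  }
  spike_table(df, duration_s = duration_s)
}

#' @param spikes A [spike_table()].
#' @rdname read_spike_table
#' @export
write_spike_table <- function(spikes, path) {
  lines <- c("well_id,electrode_id,time_s",
             sprintf("%s,%s,%.6f", spikes$well_id, spikes$electrode_id,
                     spikes$time_s))
  csv_write(lines, path)
}

#' Read and write burst tables as CSV
#'
#' Header `well_id,electrode_id,t_start_s,t_end_s,n_spikes`; times carry
#' 6 decimals. Burst intervals are closed on the member spikes
#' (`t_start`/`t_end` are the first/last spike of the burst).
#'
#' @param path File path.
#' @param bursts A tibble as produced by [find_bursts()].
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_burst_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric", "numeric", "integer"))
  need <- c("well_id", "electrode_id", "t_start_s", "t_end_s", "n_spikes")
  if (!identical(names(df), need)) {
    stop("burst CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_burst_table
#' @export
write_burst_table <- function(bursts, path) {
  lines <- c("well_id,electrode_id,t_start_s,t_end_s,n_spikes",
             sprintf("%s,%s,%.6f,%.6f,%d", bursts$well_id,
                     bursts$electrode_id, bursts$t_start_s, bursts$t_end_s,
                     as.integer(bursts$n_spikes)))
  csv_write(lines, path)
}

#' Read and write connectivity pair tables as CSV
#'
#' Header `well_id,electrode_a,electrode_b,corse,sttc`, one row per
#' unordered electrode pair with `electrode_a < electrode_b`
#' lexicographically. Undefined values are written as `NA`.
#'
#' @param path File path.
#' @param pairs A tibble as produced by [connectivity()].
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_connectivity_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "character", "numeric",
                                             "numeric"))
  need <- c("well_id", "electrode_a", "electrode_b", "corse", "sttc")
  if (!identical(names(df), need)) {
    stop("connectivity CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_connectivity_table
#' @export
write_connectivity_table <- function(pairs, path) {
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  lines <- c("well_id,electrode_a,electrode_b,corse,sttc",
             sprintf("%s,%s,%s,%s,%s", pairs$well_id, pairs$electrode_a,
                     pairs$electrode_b, num(pairs$corse), num(pairs$sttc)))
  csv_write(lines, path)
}

#' Read and write well feature tables as CSV
#'
#' Header `well_id,timepoint,mfr_hz,burst_rate_per_min,burst_duration_s,`
#' `spike_freq_in_burst_hz,spikes_in_burst,pct_spikes_in_bursts,sttc`:
#' one row per (well, timepoint) with the seven activity features used for
#' PCA.
#'
#' @param path File path.
#' @param features A tibble as produced by [well_features()].
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             rep("numeric", 7)))
  if (!identical(names(df), feature_csv_columns())) {
    stop("feature CSV must have header ",
         paste(feature_csv_columns(), collapse = ","), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(features, path) {
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  cols <- feature_columns()
  parts <- c(list(features$well_id, features$timepoint),
             lapply(features[cols], num))
  body <- do.call(paste, c(parts, sep = ","))
  lines <- c(paste(feature_csv_columns(), collapse = ","), body)
  csv_write(lines, path)
}

feature_columns <- function() {
  c("mfr_hz", "burst_rate_per_min", "burst_duration_s",
    "spike_freq_in_burst_hz", "spikes_in_burst", "pct_spikes_in_bursts",
    "sttc")
}

feature_csv_columns <- function() c("well_id", "timepoint", feature_columns())
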