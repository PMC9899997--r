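#' @importFrom data.table fread fwrite data.table as.data.table
NULL

# Cell formatting for delimited output: 17 significant digits (lossless
# float round-trip), "NaN" for an explicit missing sample, "" for a tick on
# which the stream has no sample at all.
fmt_cells <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NaN"
  out
}

trace_order <- c("HbO_norm", "HHb_norm", "tHb_norm", "HbDiff_norm",
                 "HbO_short", "HHb_short", "tHb_short", "HbDiff_short",
                 "HbO_pure", "HHb_pure", "tHb_pure", "HbDiff_pure", "rSO2")

two_file_paths <- function(path) {
  stem <- sub("\\.csv$", "", path)
  c(abp = paste0(stem, "_abp.csv"), nirs = paste0(stem, "_nirs.csv"))
}

#' Write a multi-channel recording to delimited text
#'
#' Two dialects are supported. `"merged"` (default) writes a single CSV whose
#' rows sit on the union of the ABP and NIRS time grids: the `time` column is
#' wall-clock seconds, each stream's cells are filled only on its own ticks
#' (empty cell = no sample on that tick), and an explicit missing sample is
#' written as `NaN`. `"two-file"` writes one file per device
#' (`<stem>_abp.csv`, `<stem>_nirs.csv`), each on its own uniform grid.
#' Both dialects round-trip losslessly through [read_recording].
#'
#' @param record A [cvr_record].
#' @param path Output path (`.csv`); in two-file mode used as the stem.
#' @param mode `"merged"` or `"two-file"`.
#' @param minimal If `TRUE`, omit tHb/HbDiff columns that can be re-derived
#'   from HbO/HHb of the same kind (they are reconstructed on read via
#'   [derive_traces]). Default keeps every trace.
#' @return Invisibly, the path(s) written.
#' @export
write_recording <- function(record, path, mode = c("merged", "two-file"),
                            minimal = FALSE) {
  stopifnot(inherits(record, "cvr_record"))
  mode <- match.arg(mode)
  nirs_cols <- list()
  for (ch in record$channels) {
    keep <- intersect(trace_order, names(ch$traces))
    if (minimal)
      keep <- keep[!(keep %in% c("tHb_norm", "HbDiff_norm", "tHb_short",
                                 "HbDiff_short", "tHb_pure", "HbDiff_pure"))]
    for (tr in keep)
      nirs_cols[[paste0(ch$channel_id, "_", tr)]] <- ch$traces[[tr]]
  }
  lens <- vapply(nirs_cols, length, integer(1))
  if (length(lens) && length(unique(lens)) != 1L)
    stop("inconsistent NIRS trace lengths across channels", call. = FALSE)

  if (mode == "two-file") {
    paths <- two_file_paths(path)
    dt_a <- data.table(time = sprintf("%.17g", ts_times(record$abp)),
                       abp = fmt_cells(record$abp$values))
    fwrite(dt_a, paths[["abp"]], quote = FALSE)
    t_n <- if (length(nirs_cols)) ts_times(nirs_cols[[1L]]) else numeric(0)
    dt_n <- c(list(time = sprintf("%.17g", t_n)),
              lapply(nirs_cols, function(s) fmt_cells(s$values)))
    fwrite(as.data.table(dt_n), paths[["nirs"]], quote = FALSE)
    return(invisible(paths))
  }

  t_abp <- ts_times(record$abp)
  t_nirs <- if (length(nirs_cols)) ts_times(nirs_cols[[1L]]) else numeric(0)
  k_abp <- time_key(t_abp); k_nirs <- time_key(t_nirs)
  keys <- sort(unique(c(k_abp, k_nirs)))
  t_all <- c(t_abp, t_nirs)[match(keys, c(k_abp, k_nirs))]
  blank <- function() character(length(keys))
  cols <- list(time = sprintf("%.17g", t_all), abp = blank())
  cols$abp[match(k_abp, keys)] <- fmt_cells(record$abp$values)
  i_n <- match(k_nirs, keys)
  for (nm in names(nirs_cols)) {
    col <- blank(); col[i_n] <- fmt_cells(nirs_cols[[nm]]$values)
    cols[[nm]] <- col
  }
  fwrite(as.data.table(cols), path, quote = FALSE)
  invisible(path)
}

parse_stream_col <- function(cells, times, label, units, quality_env) {
  present <- nzchar(cells)
  if (!any(present))
    return(NULL)
  v <- suppressWarnings(as.numeric(cells[present]))
  bad <- is.na(v) & !(cells[present] %in% c("NaN", "nan", "NAN"))
  quality_env$missing[label] <- sum(is.na(v))
  quality_env$unparseable[label] <- sum(bad)
  v[is.na(v)] <- NA_real_
  t <- times[present]
  if (length(t) > 1L) {
    d <- diff(t)
    period <- stats::median(d)
    if (any(abs(d - period) > period * 1e-3))
      stop(sprintf("format error: column '%s' is not on a uniform time grid",
                   label), call. = FALSE)
    rate <- 1 / period
  } else rate <- 1
  cvr_ts(v, rate, t[1L], label, units)
}

#' Read a multi-channel recording from delimited text
#'
#' Accepts either dialect written by [write_recording]: a merged CSV
#' (detected by an `abp` column next to `time`) or a two-file pair, in which
#' case `path` is the stem or either member. Column names follow
#' `<channel>_<HbO|HHb|tHb|HbDiff>_<norm|short|pure>` or `<channel>_rSO2`.
#' Every unparseable numeric cell becomes a missing-value marker and is
#' counted in the record's quality report (`meta$quality`).
#'
#' @param path Path to a merged recording CSV or a two-file stem.
#' @return A [cvr_record]; `meta$quality` holds per-column counts of missing
#'   markers and of unparseable cells.
#' @export
read_recording <- function(path) {
  paths <- two_file_paths(path)
  if (!file.exists(path) && file.exists(paths[["abp"]]))
    return(read_recording_two_file(paths))
  if (grepl("_(abp|nirs)\\.csv$", path)) {
    stem_paths <- two_file_paths(sub("_(abp|nirs)\\.csv$", ".csv", path))
    return(read_recording_two_file(stem_paths))
  }
  if (!file.exists(path))
    stop("recording file not found: ", path, call. = FALSE)
  dt <- fread(path, colClasses = "character", na.strings = NULL)
  if (!identical(names(dt)[1L], "time") || !("abp" %in% names(dt)))
    stop("format error: merged recording must start with a 'time' column and contain an 'abp' column",
         call. = FALSE)
  assemble_record(dt, abp_col = "abp")
}

read_recording_two_file <- function(paths) {
  for (p in paths) if (!file.exists(p))
    stop("recording file not found: ", p, call. = FALSE)
  dt_a <- fread(paths[["abp"]], colClasses = "character", na.strings = NULL)
  dt_n <- fread(paths[["nirs"]], colClasses = "character", na.strings = NULL)
  if (!identical(names(dt_a)[1L], "time") || !("abp" %in% names(dt_a)))
    stop("format error: ABP file must have 'time' and 'abp' columns",
         call. = FALSE)
  if (!identical(names(dt_n)[1L], "time"))
    stop("format error: NIRS file must start with a 'time' column",
         call. = FALSE)
  rec_a <- assemble_record(dt_a, abp_col = "abp")
  rec_n <- assemble_record(dt_n, abp_col = NULL)
  q <- mapply(function(a, b) c(a, b), rec_a$meta$quality, rec_n$meta$quality,
              SIMPLIFY = FALSE)
  cvr_record(rec_a$abp, rec_n$channels, meta = list(quality = q, aligned = FALSE))
}

assemble_record <- function(dt, abp_col = "abp") {
  times <- suppressWarnings(as.numeric(dt[["time"]]))
  if (anyNA(times))
    stop("format error: unparseable timestamp at data row ",
         which(is.na(times))[1L], call. = FALSE)
  if (length(times) > 1L) {
    nonmono <- which(diff(times) <= 0)
    if (length(nonmono))
      stop("format error: non-monotone timestamp at data row ",
           nonmono[1L] + 1L, call. = FALSE)
  }
  qe <- new.env()
  qe$missing <- integer(0); qe$unparseable <- integer(0)
  abp <- NULL
  if (!is.null(abp_col))
    abp <- parse_stream_col(dt[[abp_col]], times, "abp", "mmHg", qe)
  if (is.null(abp)) abp <- cvr_ts(numeric(0), 1, 0, "abp", "mmHg")

  rx_trace <- "^(.+)_(HbO|HHb|tHb|HbDiff)_(norm|short|pure)$"
  rx_rso2 <- "^(.+)_rSO2$"
  channels <- list()
  for (nm in setdiff(names(dt), c("time", abp_col))) {
    if (grepl(rx_trace, nm)) {
      ch_id <- sub(rx_trace, "\\1", nm)
      tr <- paste0(sub(rx_trace, "\\2", nm), "_", sub(rx_trace, "\\3", nm))
      units <- "a.u."
    } else if (grepl(rx_rso2, nm)) {
      ch_id <- sub(rx_rso2, "\\1", nm); tr <- "rSO2"; units <- "%"
    } else {
      warning("ignoring unrecognised column '", nm, "'")
      next
    }
    s <- parse_stream_col(dt[[nm]], times, nm, units, qe)
    if (is.null(s)) next
    if (is.null(channels[[ch_id]])) channels[[ch_id]] <- list()
    channels[[ch_id]][[tr]] <- s
  }
  channels <- lapply(names(channels), function(id) cvr_channel(id, channels[[id]]))
  names(channels) <- vapply(channels, function(ch) ch$channel_id, character(1))
  cvr_record(abp, channels,
             meta = list(quality = list(missing = qe$missing,
                                        unparseable = qe$unparseable),
                         aligned = FALSE))
}

#' Align NIRS and ABP streams onto a common timeline
#'
#' Applies the fixed inter-device delay correction: every NIRS trace's
#' timestamps are shifted forward by `nirs_delay` seconds (the NIRS stream
#' leads the lagging pressure-device output), rounded to a whole number of
#' samples -- 805 samples at 250 Hz, 322 at 100 Hz for the default 3.22 s --
#' with any sub-sample residual recorded in `meta$delay_residual`. Both
#' streams are then trimmed to their common overlap interval; no samples are
#' resampled or interpolated, and each stream keeps its native rate.
#'
#' @param record A [cvr_record] (unaligned).
#' @param nirs_delay Delay to add to the NIRS stream, seconds (default 3.22).
#' @param decim_window Minimum required overlap, seconds (default 10, one
#'   decimation window).
#' @return The aligned [cvr_record]; `meta` gains `aligned`, `delay_applied`,
#'   `delay_residual`, `origin` (common start, the decimation anchor) and
#'   `common_end`.
#' @export
align_streams <- function(record, nirs_delay = 3.22, decim_window = 10) {
  stopifnot(inherits(record, "cvr_record"))
  if (!is.numeric(nirs_delay) || length(nirs_delay) != 1L || !is.finite(nirs_delay))
    stop("nirs_delay must be a single finite number", call. = FALSE)
  channels <- record$channels
  residual <- 0
  nirs_start <- -Inf; nirs_end <- Inf
  for (i in seq_along(channels)) {
    for (j in seq_along(channels[[i]]$traces)) {
      s <- channels[[i]]$traces[[j]]
      k <- round(nirs_delay * s$rate)
      shift <- k / s$rate
      residual <- nirs_delay - shift
      s$start <- s$start + shift
      channels[[i]]$traces[[j]] <- s
      nirs_start <- max(nirs_start, s$start)
      nirs_end <- min(nirs_end, ts_end(s))
    }
  }
  t0 <- max(record$abp$start, if (is.finite(nirs_start)) nirs_start else record$abp$start)
  t1 <- min(ts_end(record$abp), nirs_end)
  if (!is.finite(t1 - t0) || t1 - t0 < decim_window)
    stop("alignment error: stream overlap (", format(max(0, t1 - t0)),
         " s) is shorter than one decimation window (", decim_window, " s)",
         call. = FALSE)
  abp <- ts_window(record$abp, t0, t1)
  for (i in seq_along(channels))
    channels[[i]]$traces <- lapply(channels[[i]]$traces, ts_window, from = t0, to = t1)
  meta <- record$meta
  meta$aligned <- TRUE
  meta$delay_applied <- nirs_delay
  meta$delay_residual <- residual
  meta$origin <- t0
  meta$common_end <- t1
  cvr_record(abp, channels, meta)
}

#' Write CVR index series to CSV
#'
#' One `time` column (window right-edge timestamps, seconds) plus one column
#' per (channel, index type), named `<channel>_<type>`. Missing index values
#' are written as empty cells, never as zeros.
#'
#' @param indices A `cvr_indices` object or list of `cvr_index` series
#'   sharing one timestamp grid.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_index_csv <- function(indices, path) {
  if (inherits(indices, "cvr_indices")) indices <- unclass(indices)$series
  if (!length(indices))
    stop("contract error: empty index list", call. = FALSE)
  t0 <- indices[[1L]]$timestamps
  for (s in indices)
    if (!identical(time_key(s$timestamps), time_key(t0)))
      stop("contract error: index series are not on a common timestamp grid",
           call. = FALSE)
  cols <- list(time = sprintf("%.17g", t0))
  for (s in indices) {
    cells <- sprintf("%.17g", s$values)
    cells[is.na(s$values)] <- ""
    cols[[paste0(s$channel_id, "_", s$index_type)]] <- cells
  }
  fwrite(as.data.table(cols), path, quote = FALSE)
  invisible(path)
}

#' Read CVR index series from CSV
#'
#' Inverse of [write_index_csv]; empty cells become missing values.
#'
#' @param path Index CSV path.
#' @return A `cvr_indices` collection.
#' @export
read_index_csv <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  dt <- fread(path, colClasses = "character", na.strings = NULL)
  if (!identical(names(dt)[1L], "time"))
    stop("format error: index CSV must start with a 'time' column", call. = FALSE)
  t <- as.numeric(dt[["time"]])
  rx <- "^(.+)_(HbOx|HHbx|tHbx|HbDiffx|COx)$"
  series <- list()
  for (nm in setdiff(names(dt), "time")) {
    if (!grepl(rx, nm)) { warning("ignoring unrecognised column '", nm, "'"); next }
    v <- suppressWarnings(as.numeric(dt[[nm]]))
    series[[nm]] <- cvr_index(channel_id = sub(rx, "\\1", nm),
                              index_type = sub(rx, "\\2", nm),
                              timestamps = t, values = v)
  }
  cvr_indices(series)
}
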