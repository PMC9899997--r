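#' Engine configuration for CVR index computation
#'
#' Parameters of the two-stage index construction: non-overlapping
#' moving-average decimation followed by sliding-window Pearson correlation.
#' The defaults reproduce the standard pressure-reactivity construction:
#' 10-s means, correlations over 30 consecutive means (a 300-s window),
#' updated every decimated sample (every 10 s).
#'
#' @param decim_window Decimation window length, seconds (default 10).
#' @param corr_window Correlation window length, in decimated samples
#'   (default 30; minimum 3).
#' @param update_step Hop between successive correlation windows, in
#'   decimated samples (default 1).
#' @param min_valid_fraction_per_mean Minimum fraction of valid raw samples
#'   for a 10-s mean to be emitted (default 0.5).
#' @param min_valid_means_per_window Minimum count of jointly valid mean
#'   pairs for an index value to be emitted (default `corr_window`, i.e.
#'   all 30).
#' @param index_types Which indices to compute; any subset of
#'   `c("HbOx", "HHbx", "tHbx", "HbDiffx", "COx")` (default all five).
#' @return An object of class `cvr_engine_config`.
#' @export
engine_config <- function(decim_window = 10, corr_window = 30,
                          update_step = 1,
                          min_valid_fraction_per_mean = 0.5,
                          min_valid_means_per_window = corr_window,
                          index_types = c("HbOx", "HHbx", "tHbx",
                                          "HbDiffx", "COx")) {
  if (!is.numeric(decim_window) || length(decim_window) != 1L || decim_window <= 0)
    stop("invalid engine config: decim_window must be positive", call. = FALSE)
  if (!is.numeric(corr_window) || length(corr_window) != 1L || corr_window < 3)
    stop("invalid engine config: corr_window must be >= 3", call. = FALSE)
  if (!is.numeric(update_step) || length(update_step) != 1L || update_step < 1)
    stop("invalid engine config: update_step must be >= 1", call. = FALSE)
  if (min_valid_fraction_per_mean < 0 || min_valid_fraction_per_mean > 1)
    stop("invalid engine config: min_valid_fraction_per_mean must lie in [0, 1]",
         call. = FALSE)
  index_types <- match.arg(index_types, several.ok = TRUE)
  structure(list(decim_window = decim_window,
                 corr_window = as.integer(corr_window),
                 update_step = as.integer(update_step),
                 min_valid_fraction_per_mean = min_valid_fraction_per_mean,
                 min_valid_means_per_window = as.integer(min_valid_means_per_window),
                 index_types = index_types),
            class = "cvr_engine_config")
}

#' Non-overlapping moving-average decimation
#'
#' Reduces a raw trace to one arithmetic mean per complete non-overlapping
#' wall-clock window. This is the slow-wave isolation step: a 10-s mean
#' annihilates any sinusoid completing a whole number of cycles per window
#' (cardiac pulsation, 0.1 Hz Mayer waves) while passing the 0.005-0.05 Hz
#' vasogenic band nearly untouched. A window's mean is missing if fewer than
#' `min_valid` of its expected samples are valid; an incomplete trailing
#' window is dropped. Output timestamps are window right edges.
#'
#' @param series A [cvr_ts].
#' @param window Window length in seconds (default 10; must span at least
#'   2 sample periods).
#' @param origin Wall-clock anchor of the first window (default the series
#'   start). Windows cover `[origin + m*window, origin + (m+1)*window)`.
#' @param min_valid Minimum valid fraction per window (default 0.5).
#' @return A [cvr_ts] at rate `1/window` whose first sample is stamped
#'   `origin + window`.
#' @export
decimate <- function(series, window = 10, origin = series$start,
                     min_valid = 0.5) {
  stopifnot(inherits(series, "cvr_ts"))
  if (!is.numeric(window) || length(window) != 1L || window < 2 / series$rate)
    stop("config error: decimation window must span at least 2 sample periods",
         call. = FALSE)
  t <- ts_times(series)
  eps <- 1 / (2 * series$rate) * 1e-6
  keep <- t >= origin - eps
  t <- t[keep]; v <- series$values[keep]
  if (!length(t))
    return(cvr_ts(numeric(0), 1 / window, origin + window, series$label, series$units))
  grp <- floor((t - origin) / window + eps)
  n_expected <- round(window * series$rate)
  n_win <- floor((max(t) - origin + 1 / series$rate + eps) / window)
  if (n_win < 1L)
    return(cvr_ts(numeric(0), 1 / window, origin + window, series$label, series$units))
  out <- rep(NA_real_, n_win)
  complete <- grp < n_win
  grp <- grp[complete]; v <- v[complete]
  valid <- !is.na(v)
  sums <- rowsum(ifelse(valid, v, 0), grp)
  counts <- rowsum(as.numeric(valid), grp)
  at <- as.integer(rownames(sums)) + 1L
  ok <- counts[, 1L] >= min_valid * n_expected & counts[, 1L] > 0
  out[at[ok]] <- sums[ok, 1L] / counts[ok, 1L]
  cvr_ts(out, 1 / window, origin + window, series$label, series$units)
}

#' Pearson product-moment correlation with the engine's contract
#'
#' Two-pass (mean-centred) computation over jointly valid pairs. Returns
#' missing -- never an error -- when fewer than 3 joint pairs exist or when
#' either input has zero variance over those pairs (a flatlined or clamped
#' signal is physiologically meaningful, not exceptional). The result is
#' clamped to \[-1, +1\].
#'
#' @param x,y Numeric vectors of equal length; `NA`s allowed.
#' @return A single correlation in \[-1, +1\], or `NA`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (all(x == x[1L]) || all(y == y[1L])) return(NA_real_)
  xc <- x - sum(x) / n
  yc <- y - sum(y) / n
  sxx <- sum(xc * xc); syy <- sum(yc * yc)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  r <- sum(xc * yc) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' One CVR index series
#'
#' Container for a single channel's single index type: sliding-window
#' correlations in \[-1, +1\] (or missing) stamped at the right edge of each
#' correlation window.
#'
#' @param channel_id Channel identifier.
#' @param index_type One of `"HbOx"`, `"HHbx"`, `"tHbx"`, `"HbDiffx"`,
#'   `"COx"`.
#' @param timestamps Numeric vector, seconds.
#' @param values Numeric vector in \[-1, +1\] with `NA` gaps.
#' @return An object of class `cvr_index`.
#' @export
cvr_index <- function(channel_id, index_type, timestamps, values) {
  index_type <- match.arg(index_type, c("HbOx", "HHbx", "tHbx", "HbDiffx", "COx"))
  if (length(timestamps) != length(values))
    stop("timestamps and values must have equal length", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) && (any(v < -1 - 1e-12) || any(v > 1 + 1e-12)))
    stop("index values must lie in [-1, +1]", call. = FALSE)
  structure(list(channel_id = channel_id, index_type = index_type,
                 timestamps = as.numeric(timestamps),
                 values = as.numeric(values)),
            class = "cvr_index")
}

#' @export
print.cvr_index <- function(x, ...) {
  cat(sprintf("<cvr_index> %s %s: %d values (%d missing), mean %.3f\n",
              x$channel_id, x$index_type, length(x$values),
              sum(is.na(x$values)),
              if (all(is.na(x$values))) NA_real_ else mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Sliding correlation index between a decimated surrogate and decimated ABP
#'
#' For each window position advancing by `update_step`, emits the Pearson
#' correlation of the last `corr_window` decimated means of the surrogate
#' against those of ABP. The first value is emitted once `corr_window` means
#' exist. A window whose count of jointly valid mean pairs falls below
#' `min_valid_means_per_window` emits missing (windows spanning recording
#' gaps are skipped, not shortened, by default).
#'
#' @param surrogate,abp Decimated [cvr_ts] objects on a shared decimated
#'   timeline (only their overlapping timestamps are used).
#' @param cfg An [engine_config].
#' @return A [cvr_index]; empty (with a warning) if the shared timeline is
#'   shorter than `corr_window`.
#' @export
sliding_index <- function(surrogate, abp, cfg = engine_config()) {
  stopifnot(inherits(surrogate, "cvr_ts"), inherits(abp, "cvr_ts"),
            inherits(cfg, "cvr_engine_config"))
  ks <- time_key(ts_times(surrogate)); ka <- time_key(ts_times(abp))
  common <- intersect(ks, ka)
  x <- surrogate$values[match(common, ks)]
  y <- abp$values[match(common, ka)]
  t <- ts_times(surrogate)[match(common, ks)]
  w <- cfg$corr_window
  idx_type <- trace_to_index(surrogate$label)
  n <- length(x)
  if (n < w) {
    warning("overlap (", n, " decimated samples) shorter than the ",
            w, "-sample correlation window; empty index series")
    return(cvr_index(surrogate$label, idx_type, numeric(0), numeric(0)))
  }
  ends <- seq(w, n, by = cfg$update_step)
  vals <- rep(NA_real_, length(ends))
  for (i in seq_along(ends)) {
    j <- (ends[i] - w + 1L):ends[i]
    if (sum(!is.na(x[j]) & !is.na(y[j])) < cfg$min_valid_means_per_window)
      next
    vals[i] <- pearson_cor(x[j], y[j])
  }
  cvr_index(surrogate$label, idx_type, t[ends], vals)
}

index_trace_map <- c(HbOx = "HbO_pure", HHbx = "HHb_pure", tHbx = "tHb_pure",
                     HbDiffx = "HbDiff_pure", COx = "rSO2")

trace_to_index <- function(label) {
  for (ix in names(index_trace_map))
    if (grepl(paste0("(^|_)", sub("_pure", "", index_trace_map[ix]), "(_pure)?$"),
              label))
      return(ix)
  "tHbx"
}

#' Compute all CVR indices of a recording
#'
#' The full engine: decimates the niABP trace and every channel's pure
#' cerebral surrogate over identical wall-clock windows anchored at the
#' aligned record's origin, then computes the sliding correlation of each
#' surrogate against ABP ([sliding_index]). Five indices per channel by
#' default: HbOx (HbO vs niABP), HHbx (HHb), tHbx (tHb), HbDiffx (HbDiff)
#' and COx (rSO2).
#'
#' @param record A preprocessed, aligned [cvr_record].
#' @param cfg An [engine_config].
#' @return A `cvr_indices` collection with one [cvr_index] per
#'   (channel, index type); an index whose surrogate trace is absent is
#'   skipped with a per-channel warning.
#' @seealso [align_streams], [preprocess_record], [write_index_csv]
#' @examples
#' cfg <- sim_config(duration = 400, coupling = c(ch1 = 1), scalp_fraction = 0,
#'                   sensor_noise_sd = 0, nirs_rate = 50)
#' rec <- simulate_recording(cfg)
#' rec <- align_streams(rec)
#' rec <- preprocess_record(rec, quiet = TRUE)
#' idx <- compute_cvr(rec)
#' summary(idx)
#' @export
compute_cvr <- function(record, cfg = engine_config()) {
  stopifnot(inherits(record, "cvr_record"), inherits(cfg, "cvr_engine_config"))
  origin <- if (!is.null(record$meta$origin)) record$meta$origin
            else record$abp$start
  abp_dec <- decimate(record$abp, cfg$decim_window, origin,
                      cfg$min_valid_fraction_per_mean)
  series <- list()
  for (ch in record$channels) {
    for (ix in cfg$index_types) {
      tr <- index_trace_map[[ix]]
      s <- ch$traces[[tr]]
      if (is.null(s)) {
        warning("channel '", ch$channel_id, "': trace ", tr,
                " unavailable; skipping ", ix)
        next
      }
      s_dec <- decimate(s, cfg$decim_window, origin,
                        cfg$min_valid_fraction_per_mean)
      si <- sliding_index(s_dec, abp_dec, cfg)
      si$channel_id <- ch$channel_id
      si$index_type <- ix
      series[[paste0(ch$channel_id, "_", ix)]] <- si
    }
  }
  cvr_indices(series, cfg = cfg)
}

#' Collection of CVR index series
#'
#' The result object of [compute_cvr]: a set of [cvr_index] series with the
#' engine configuration that produced them.
#'
#' @param series Named list of [cvr_index] objects.
#' @param cfg The [engine_config] used (optional).
#' @return An object of class `cvr_indices`.
#' @export
cvr_indices <- function(series, cfg = NULL) {
  stopifnot(all(vapply(series, inherits, logical(1), what = "cvr_index")))
  structure(list(series = series, cfg = cfg), class = "cvr_indices")
}

#' @export
print.cvr_indices <- function(x, ...) {
  chs <- unique(vapply(x$series, function(s) s$channel_id, character(1)))
  types <- unique(vapply(x$series, function(s) s$index_type, character(1)))
  cat(sprintf("<cvr_indices> %d series: %d channel(s) x {%s}\n",
              length(x$series), length(chs), paste(types, collapse = ", ")))
  if (length(x$series)) {
    n <- length(x$series[[1L]]$values)
    cat(sprintf("  %d window(s) per series", n))
    if (n) cat(sprintf(", t = [%g, %g] s", min(x$series[[1L]]$timestamps),
                       max(x$series[[1L]]$timestamps)))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.cvr_indices <- function(object, ...) {
  rows <- lapply(object$series, function(s) {
    data.frame(channel = s$channel_id, index = s$index_type,
               n = length(s$values), n_missing = sum(is.na(s$values)),
               mean = if (all(is.na(s$values))) NA_real_
                      else mean(s$values, na.rm = TRUE),
               min = if (all(is.na(s$values))) NA_real_
                     else min(s$values, na.rm = TRUE),
               max = if (all(is.na(s$values))) NA_real_
                     else max(s$values, na.rm = TRUE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("summary.cvr_indices", "data.frame")
  out
}

#' @export
as.data.frame.cvr_indices <- function(x, ...) {
  do.call(rbind, c(lapply(unname(x$series), function(s) {
    data.frame(time = s$timestamps, channel = s$channel_id,
               index = s$index_type, value = s$values)
  }), list(make.row.names = FALSE)))
}

#' @export
plot.cvr_indices <- function(x, index_type = "tHbx", ...) {
  sel <- Filter(function(s) s$index_type == index_type, x$series)
  if (!length(sel)) stop("no series of index type ", index_type, call. = FALSE)
  t <- sel[[1L]]$timestamps
  m <- vapply(sel, function(s) s$values, numeric(length(t)))
  graphics::matplot(t, m, type = "l", lty = 1, ylim = c(-1, 1),
                    xlab = "time [s]", ylab = index_type, ...)
  graphics::abline(h = 0, col = "gray")
  graphics::legend("topright", legend = vapply(sel, function(s) s$channel_id,
                                               character(1)),
                   col = seq_along(sel), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
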