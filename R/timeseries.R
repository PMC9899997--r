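#' Uniformly sampled physiological time series
#'
#' The basic container for every raw and derived trace in the pipeline: a
#' vector of values on a uniform time grid `start + (k-1)/rate`, with missing
#' samples represented as `NA` (explicit markers, never dropped).
#'
#' @param values Numeric vector; `NA` marks a missing sample.
#' @param rate Sampling rate in Hz (> 0).
#' @param start Time of the first sample, in seconds.
#' @param label Short name of the signal (e.g. `"abp"`, `"ch1_HbO_pure"`).
#' @param units Physical units (e.g. `"mmHg"`, `"a.u."`, `"%"`).
#' @return An object of class `cvr_ts`.
#' @examples
#' x <- cvr_ts(sin(2 * pi * 0.02 * (0:999) / 10), rate = 10, label = "demo")
#' head(ts_times(x))
#' @export
cvr_ts <- function(values, rate, start = 0, label = "", units = "") {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number", call. = FALSE)
  if (!is.numeric(start) || length(start) != 1L || !is.finite(start))
    stop("start must be a single finite number", call. = FALSE)
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         start = as.numeric(start), label = as.character(label),
         units = as.character(units)),
    class = "cvr_ts"
  )
}

#' @export
length.cvr_ts <- function(x) length(x$values)

#' Sample timestamps of a series
#'
#' @param x A [cvr_ts] object.
#' @return Numeric vector of timestamps in seconds, one per sample.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "cvr_ts"))
  if (length(x$values) == 0L) return(numeric(0))
  x$start + (seq_along(x$values) - 1) / x$rate
}

#' End time of a series
#'
#' Time of the last sample (not the start of the next): `start + (n-1)/rate`.
#' @param x A [cvr_ts] object.
#' @return A single numeric time in seconds; `-Inf` for an empty series.
#' @export
ts_end <- function(x) {
  stopifnot(inherits(x, "cvr_ts"))
  n <- length(x$values)
  if (n == 0L) return(-Inf)
  x$start + (n - 1) / x$rate
}

#' Trim a series to a wall-clock interval
#'
#' Keeps the samples whose timestamps fall in `[from, to]` (half-open at
#' neither end; a small grid tolerance absorbs float jitter). No resampling:
#' samples are only dropped, never created.
#'
#' @param x A [cvr_ts] object.
#' @param from,to Interval bounds in seconds.
#' @return A [cvr_ts] on the same grid, possibly empty.
#' @export
ts_window <- function(x, from = -Inf, to = Inf) {
  stopifnot(inherits(x, "cvr_ts"))
  tol <- 1 / (2 * x$rate) * 1e-6
  t <- ts_times(x)
  keep <- t >= from - tol & t <= to + tol
  i <- which(keep)
  if (length(i) == 0L)
    return(cvr_ts(numeric(0), x$rate, x$start, x$label, x$units))
  cvr_ts(x$values[i], x$rate, t[i[1L]], x$label, x$units)
}

#' @export
print.cvr_ts <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<cvr_ts> %s%s: %d samples @ %g Hz, t = [%g, %g] s, %d missing\n",
              x$label, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              n, x$rate, x$start, ts_end(x), sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.cvr_ts <- function(x, ...) {
  data.frame(time = ts_times(x), value = x$values)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards. All simulator randomness funnels through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Integer key for matching wall-clock timestamps across streams (microsecond
# resolution; robust to float noise well below any sampling period used here).
time_key <- function(t) as.integer(round(t * 1e5))
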