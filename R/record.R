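#' Per-channel bundle of NIRS traces
#'
#' Holds every trace belonging to one transmitter-receiver channel: the
#' normal (30 mm) channel traces, the short (10 mm) scalp-reference traces,
#' and -- once preprocessing has run -- the pure cerebral traces and rSO2.
#' Trace names follow `<quantity>_<kind>`: quantities `HbO`, `HHb`, `tHb`,
#' `HbDiff`; kinds `norm`, `short`, `pure`; plus `rSO2` (in percent).
#'
#' @param channel_id Unique channel identifier.
#' @param traces Named list of [cvr_ts] objects.
#' @return An object of class `cvr_channel`.
#' @export
cvr_channel <- function(channel_id, traces = list()) {
  stopifnot(is.character(channel_id), length(channel_id) == 1L,
            nzchar(channel_id))
  ok <- vapply(traces, inherits, logical(1), what = "cvr_ts")
  if (length(traces) && (!all(ok) || is.null(names(traces)) ||
                         any(!nzchar(names(traces)))))
    stop("traces must be a named list of cvr_ts objects", call. = FALSE)
  structure(list(channel_id = channel_id, traces = traces),
            class = "cvr_channel")
}

#' @export
print.cvr_channel <- function(x, ...) {
  cat(sprintf("<cvr_channel> %s: traces %s\n", x$channel_id,
              paste(names(x$traces), collapse = ", ")))
  invisible(x)
}

#' Multi-channel recording
#'
#' The full acquisition: one niABP trace plus a set of NIRS channels, with
#' acquisition metadata (applied delay correction, alignment origin, quality
#' counts). All member series share a wall-clock timeline after
#' [align_streams].
#'
#' @param abp A [cvr_ts] niABP trace (mmHg).
#' @param channels Named list of [cvr_channel]; names are the channel ids.
#' @param meta List of acquisition descriptors.
#' @return An object of class `cvr_record`.
#' @export
cvr_record <- function(abp, channels = list(), meta = list()) {
  stopifnot(inherits(abp, "cvr_ts"))
  ids <- vapply(channels, function(ch) ch$channel_id, character(1))
  if (length(ids) && anyDuplicated(ids))
    stop("channel ids must be unique", call. = FALSE)
  if (length(channels)) names(channels) <- ids
  structure(list(abp = abp, channels = channels, meta = meta),
            class = "cvr_record")
}

#' @export
print.cvr_record <- function(x, ...) {
  cat(sprintf("<cvr_record> %d channel(s), ABP %d samples @ %g Hz\n",
              length(x$channels), length(x$abp), x$abp$rate))
  if (length(x$channels)) {
    ch1 <- x$channels[[1L]]
    cat(sprintf("  channels: %s\n  traces per channel: %s\n",
                paste(names(x$channels), collapse = ", "),
                paste(names(ch1$traces), collapse = ", ")))
  }
  if (isTRUE(x$meta$aligned))
    cat(sprintf("  aligned: delay %.3f s applied (residual %.4f s), overlap [%g, %g] s\n",
                x$meta$delay_applied, x$meta$delay_residual,
                x$meta$origin, x$meta$common_end))
  invisible(x)
}
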