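#' Short-channel subtraction
#'
#' Removes scalp contamination from a normal (30 mm) channel trace by
#' subtracting the short (10 mm) reference trace, which samples only
#' extracerebral tissue: `pure = normal - scale * short`, elementwise. The
#' result is missing wherever either input is missing.
#'
#' @param normal,short [cvr_ts] traces on the same timeline (same rate,
#'   start and length).
#' @param scale Subtraction gain (default 1.0: unit-gain subtraction; no
#'   regression coefficient is fitted).
#' @return A [cvr_ts] of the pure cerebral trace.
#' @export
subtract_short <- function(normal, short, scale = 1.0) {
  stopifnot(inherits(normal, "cvr_ts"), inherits(short, "cvr_ts"))
  if (normal$rate != short$rate || length(normal) != length(short) ||
      abs(normal$start - short$start) > 1 / (2 * normal$rate) * 1e-3)
    stop("contract error: normal and short traces are not on the same timeline",
         call. = FALSE)
  cvr_ts(normal$values - scale * short$values, normal$rate, normal$start,
         sub("_norm$", "_pure", normal$label), normal$units)
}

#' Derive tHb, HbDiff and rSO2 from pure hemoglobin traces
#'
#' Fills the derived traces of a channel from its pure cerebral HbO and HHb:
#' `tHb = HbO + HHb`, `HbDiff = HbO - HHb` (exact identities), and
#' `rSO2 = 100 * numerator / tHb` in percent. Samples where `tHb <= 0` give
#' a missing rSO2 (the ratio is undefined); any missing input sample makes
#' every derived sample missing. Traces already present on the channel
#' (e.g. device-computed) are kept as-is; derivation only fills gaps.
#'
#' @param ch A [cvr_channel] with `HbO_pure` and `HHb_pure` traces.
#' @param rso2_numerator `"HHb"` (default, the deoxyhemoglobin ratio
#'   convention used by the acquisition software) or `"HbO"` (the
#'   conventional oxygen-saturation numerator). See the package vignette for
#'   why both exist.
#' @return The channel with `tHb_pure`, `HbDiff_pure` and `rSO2` filled.
#' @export
derive_traces <- function(ch, rso2_numerator = c("HHb", "HbO")) {
  stopifnot(inherits(ch, "cvr_channel"))
  rso2_numerator <- match.arg(rso2_numerator)
  hbo <- ch$traces$HbO_pure; hhb <- ch$traces$HHb_pure
  if (is.null(hbo) || is.null(hhb))
    stop("derive_traces needs HbO_pure and HHb_pure on channel '",
         ch$channel_id, "'", call. = FALSE)
  mk <- function(v, tr, units = "a.u.")
    cvr_ts(v, hbo$rate, hbo$start, paste0(ch$channel_id, "_", tr), units)
  if (is.null(ch$traces$tHb_pure))
    ch$traces$tHb_pure <- mk(hbo$values + hhb$values, "tHb_pure")
  if (is.null(ch$traces$HbDiff_pure))
    ch$traces$HbDiff_pure <- mk(hbo$values - hhb$values, "HbDiff_pure")
  if (is.null(ch$traces$rSO2)) {
    thb <- hbo$values + hhb$values
    num <- if (rso2_numerator == "HHb") hhb$values else hbo$values
    r <- 100 * num / thb
    r[!is.na(thb) & thb <= 0] <- NA_real_
    ch$traces$rSO2 <- mk(r, "rSO2", "%")
  }
  ch
}

#' Preprocess a full recording to pure cerebral traces
#'
#' For every channel: subtract the short-channel traces from the normal
#' ones ([subtract_short]) unless device-computed pure traces are already
#' present, then fill tHb, HbDiff and rSO2 ([derive_traces]).
#'
#' @param record A [cvr_record] (typically after [align_streams]).
#' @param short_scale Subtraction gain passed to [subtract_short].
#' @param rso2_numerator Passed to [derive_traces].
#' @param quiet Suppress the one-time note about the rSO2 numerator
#'   convention.
#' @return The record with pure traces filled on every channel.
#' @export
preprocess_record <- function(record, short_scale = 1.0,
                              rso2_numerator = c("HHb", "HbO"),
                              quiet = FALSE) {
  stopifnot(inherits(record, "cvr_record"))
  rso2_numerator <- match.arg(rso2_numerator)
  if (!quiet && rso2_numerator == "HHb")
    message("note: rSO2 computed as 100*HHb/tHb (acquisition-software ",
            "convention); set rso2_numerator = \"HbO\" for the conventional ",
            "saturation ratio")
  for (i in seq_along(record$channels)) {
    ch <- record$channels[[i]]
    for (q in c("HbO", "HHb")) {
      pure <- paste0(q, "_pure")
      if (is.null(ch$traces[[pure]])) {
        norm <- ch$traces[[paste0(q, "_norm")]]
        short <- ch$traces[[paste0(q, "_short")]]
        if (is.null(norm))
          stop("channel '", ch$channel_id, "' has neither ", pure, " nor ",
               q, "_norm", call. = FALSE)
        ch$traces[[pure]] <- if (is.null(short)) {
          s <- norm; s$label <- sub("_norm$", "_pure", s$label); s
        } else subtract_short(norm, short, short_scale)
      }
    }
    ch <- derive_traces(ch, rso2_numerator)
    record$channels[[i]] <- ch
  }
  record$meta$preprocessed <- TRUE
  record$meta$short_scale <- short_scale
  record$meta$rso2_numerator <- rso2_numerator
  record
}
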