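#' Simulation configuration for coupled ABP/NIRS recordings
#'
#' Defines a synthetic recording session: a non-invasive arterial blood
#' pressure (niABP) stream built from physiologically placed sinusoids
#' (cardiac, respiratory, Mayer, slow vasogenic) plus white sensor noise, and
#' per-channel NIRS hemoglobin streams whose slow-wave content is coupled to
#' the ABP slow waves by a known reactivity parameter. The coupling is the
#' recoverable ground truth for the downstream correlation indices: +1 is a
#' fully pressure-passive (impaired) channel, 0 a fully decoupled (intact)
#' one, -1 a fully counter-phase channel.
#'
#' The ABP record is delayed by `nirs_delay_true` seconds relative to the
#' physiology (the finger-cuff device's output lag), while NIRS records at
#' true physiological time; the pipeline's fixed delay correction
#' (see [align_streams]) compensates this, leaving a small known residual.
#'
#' @param duration Recording length in seconds.
#' @param abp_rate,nirs_rate Sampling rates in Hz (defaults 100 and 250).
#' @param abp_mean Mean arterial pressure in mmHg (default 90).
#' @param cardiac_freq,cardiac_amp Cardiac component (default 1.1 Hz, 20 mmHg).
#' @param resp_freq,resp_amp Respiratory component (default 0.25 Hz, 3 mmHg).
#' @param mayer_freq,mayer_amp Mayer-wave component (default 0.1 Hz, 3 mmHg).
#' @param slow_freqs,slow_amps Slow vasogenic components; all frequencies must
#'   lie in the 0.005-0.05 Hz autoregulatory band (defaults 0.01/0.02/0.04 Hz
#'   at 3/5/2 mmHg).
#' @param coupling Numeric vector in \[-1, +1\], one reactivity coupling per
#'   simulated channel; its length sets the channel count.
#' @param scalp_fraction Fraction in \[0, 1\] of the scalp process mixed into
#'   both the normal and the short channel.
#' @param sensor_noise_sd White-noise standard deviation added to every
#'   stream, in that stream's units.
#' @param nirs_delay_true True inter-device delay in seconds (default 3.24,
#'   the measured mean output lag of the pressure device).
#' @param hbo_base,hhb_base Cerebral hemoglobin baselines in arbitrary
#'   concentration units (defaults 30 and 15; the indices are
#'   scale-invariant, only the rSO2 ratio depends on the split).
#' @param scalp_hbo_base,scalp_hhb_base Extracerebral (scalp-tissue)
#'   baselines, seen by both the normal and the short channel (defaults 8
#'   and 4); short-channel subtraction cancels them exactly.
#' @param hbo_slow_amp,hhb_slow_amp Amplitude of the cerebral slow-wave
#'   modulation on HbO and HHb (defaults +1.0 and -0.4 a.u.: a pressure rise
#'   raises HbO and lowers HHb, so tHb follows pressure with amplitude 0.6).
#' @param scalp_amp Amplitude of the extracerebral (scalp) process in a.u.
#' @param impulse_time Optional physiological time (s) at which a sharp
#'   impulse is injected into every stream; used to measure alignment residuals
#'   by cross-timing. `NULL` for none.
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#' @return An object of class `cvr_sim_config` (validated list).
#' @seealso [generate_abp], [generate_nirs_channel], [simulate_recording]
#' @export
sim_config <- function(duration = 600,
                       abp_rate = 100, nirs_rate = 250,
                       abp_mean = 90,
                       cardiac_freq = 1.1, cardiac_amp = 20,
                       resp_freq = 0.25, resp_amp = 3,
                       mayer_freq = 0.1, mayer_amp = 3,
                       slow_freqs = c(0.01, 0.02, 0.04),
                       slow_amps = c(3, 5, 2),
                       coupling = rep(1, 8),
                       scalp_fraction = 0.2,
                       sensor_noise_sd = 0.5,
                       nirs_delay_true = 3.24,
                       hbo_base = 30, hhb_base = 15,
                       scalp_hbo_base = 8, scalp_hhb_base = 4,
                       hbo_slow_amp = 1.0, hhb_slow_amp = -0.4,
                       scalp_amp = 1.0,
                       impulse_time = NULL,
                       seed = 1L) {
  cfg <- list(duration = duration, abp_rate = abp_rate, nirs_rate = nirs_rate,
              abp_mean = abp_mean,
              cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
              resp_freq = resp_freq, resp_amp = resp_amp,
              mayer_freq = mayer_freq, mayer_amp = mayer_amp,
              slow_freqs = as.numeric(slow_freqs),
              slow_amps = as.numeric(slow_amps),
              coupling = stats::setNames(as.numeric(coupling), names(coupling)),
              scalp_fraction = scalp_fraction,
              sensor_noise_sd = sensor_noise_sd,
              nirs_delay_true = nirs_delay_true,
              hbo_base = hbo_base, hhb_base = hhb_base,
              scalp_hbo_base = scalp_hbo_base, scalp_hhb_base = scalp_hhb_base,
              hbo_slow_amp = hbo_slow_amp, hhb_slow_amp = hhb_slow_amp,
              scalp_amp = scalp_amp,
              impulse_time = impulse_time,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "cvr_sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  pos1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad(field, "must be a single positive number")
  }
  pos1("duration"); pos1("abp_rate"); pos1("nirs_rate")
  for (f in c("cardiac_amp", "resp_amp", "mayer_amp", "scalp_fraction",
              "sensor_noise_sd", "scalp_amp"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] < 0)
      bad(f, "must be a single nonnegative number")
  if (cfg$scalp_fraction > 1) bad("scalp_fraction", "must lie in [0, 1]")
  if (length(cfg$slow_freqs) != length(cfg$slow_amps))
    bad("slow_amps", "must match slow_freqs in length")
  if (length(cfg$slow_freqs) &&
      (any(cfg$slow_freqs < 0.005) || any(cfg$slow_freqs > 0.05)))
    bad("slow_freqs", "must lie within the 0.005-0.05 Hz slow-wave band")
  if (length(cfg$coupling) == 0L || any(!is.finite(cfg$coupling)) ||
      any(cfg$coupling < -1) || any(cfg$coupling > 1))
    bad("coupling", "values must lie in [-1, +1]")
  if (!is.finite(cfg$nirs_delay_true) || cfg$nirs_delay_true < 0)
    bad("nirs_delay_true", "must be nonnegative")
  invisible(cfg)
}

# Deterministic sub-seed for a named stream within a scenario seed, kept
# below 2^31. Ensures e.g. the ABP noise draw does not move when a channel
# is added.
sub_seed <- function(seed, what) {
  h <- sum(utf8ToChar_int(what) * seq_along(utf8ToChar_int(what)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
utf8ToChar_int <- function(s) as.integer(charToRaw(s))

# Sum of the configured ABP sinusoids at physiological times t (deterministic
# part, zero-mean). Phases are fixed at zero: the slow components are the
# coupling carrier and must be identical across streams.
abp_components <- function(cfg, t, which = c("all", "slow", "fast")) {
  which <- match.arg(which)
  out <- numeric(length(t))
  if (which %in% c("all", "fast")) {
    out <- out + cfg$cardiac_amp * sin(2 * pi * cfg$cardiac_freq * t) +
      cfg$resp_amp * sin(2 * pi * cfg$resp_freq * t) +
      cfg$mayer_amp * sin(2 * pi * cfg$mayer_freq * t)
  }
  if (which %in% c("all", "slow") && length(cfg$slow_freqs)) {
    for (i in seq_along(cfg$slow_freqs))
      out <- out + cfg$slow_amps[i] * sin(2 * pi * cfg$slow_freqs[i] * t)
  }
  out
}

# RMS amplitude of the slow-wave carrier (sum of independent sinusoids):
# used to present the coupling modulation in unit-variance form.
slow_sd <- function(freqs, amps) {
  if (length(amps) == 0L || sum(amps^2) == 0) return(1)
  sqrt(sum(amps^2) / 2)
}

# A zero-mean band-limited random process: sinusoids at the given
# frequencies with random phases, normalised to unit RMS.
band_process <- function(t, freqs, seed) {
  phases <- with_seed(seed, stats::runif(length(freqs), 0, 2 * pi))
  out <- numeric(length(t))
  for (i in seq_along(freqs))
    out <- out + sin(2 * pi * freqs[i] * t + phases[i])
  out / slow_sd(freqs, rep(1, length(freqs)))
}

# Frequencies used for per-channel independent cerebral slow activity and for
# the shared scalp process. Same 0.005-0.05 Hz band as the coupling carrier
# (independent activity is still vasogenic), scalp additionally carries a
# Mayer-range component (skin perfusion).
INDEP_SLOW_FREQS <- c(0.007, 0.013, 0.027, 0.044)
SCALP_FREQS <- c(0.011, 0.033, 0.09)

#' Generate a synthetic niABP stream
#'
#' The record equals `abp_mean` plus the configured cardiac, respiratory,
#' Mayer and slow vasogenic sinusoids plus white noise, sampled at
#' `abp_rate`. The record is delayed by `nirs_delay_true`: the sample at
#' record time `t` holds the physiological pressure at `t - nirs_delay_true`,
#' emulating the pressure device's output lag.
#'
#' @param config A [sim_config] object.
#' @return A [cvr_ts] of length `round(duration * abp_rate)` labelled
#'   `"abp"`, in mmHg, starting at time 0.
#' @export
generate_abp <- function(config) {
  stopifnot(inherits(config, "cvr_sim_config"))
  validate_sim_config(config)
  n <- round(config$duration * config$abp_rate)
  t_rec <- (seq_len(n) - 1) / config$abp_rate
  t_phys <- t_rec - config$nirs_delay_true
  v <- config$abp_mean + abp_components(config, t_phys, "all")
  if (config$sensor_noise_sd > 0)
    v <- v + with_seed(sub_seed(config$seed, "abp_noise"),
                       stats::rnorm(n, 0, config$sensor_noise_sd))
  if (!is.null(config$impulse_time)) {
    i <- round((config$impulse_time + config$nirs_delay_true) *
                 config$abp_rate) + 1L
    if (i >= 1L && i <= n) v[i] <- v[i] + 50
  }
  cvr_ts(v, config$abp_rate, 0, "abp", "mmHg")
}

#' Generate one synthetic NIRS channel bundle
#'
#' Builds normal- and short-channel HbO/HHb traces at `nirs_rate`. The
#' normal channel's cerebral slow-wave modulation is
#' `coupling * s(t) + (1 - |coupling|) * u(t)`, where `s` is the ABP slow
#' carrier rescaled to unit RMS and `u` an independent unit-RMS slow process
#' drawn per channel; the modulation enters HbO with amplitude
#' `hbo_slow_amp` and HHb with `hhb_slow_amp`. Both normal and short channels
#' carry the identical scalp process scaled by `scalp_fraction`; the short
#' channel has no cerebral component. tHb and HbDiff are formed exactly as
#' HbO + HHb and HbO - HHb. NIRS records at true physiological time, so its
#' content leads the delayed ABP record by `nirs_delay_true`.
#'
#' @param abp A [cvr_ts] from [generate_abp] (used for duration bookkeeping).
#' @param coupling Reactivity coupling in \[-1, +1\] for this channel.
#' @param config A [sim_config] object.
#' @param channel_id Channel identifier (names the traces).
#' @return A `cvr_channel` object: list with `channel_id` and a `traces`
#'   list holding `HbO_norm`, `HHb_norm`, `tHb_norm`, `HbDiff_norm` and the
#'   `_short` counterparts, each a [cvr_ts] in arbitrary concentration units.
#' @export
generate_nirs_channel <- function(abp, coupling, config, channel_id = "ch1") {
  stopifnot(inherits(abp, "cvr_ts"), inherits(config, "cvr_sim_config"))
  if (!is.numeric(coupling) || length(coupling) != 1L || !is.finite(coupling) ||
      coupling < -1 || coupling > 1)
    stop("coupling must be a single value in [-1, +1]", call. = FALSE)
  dur <- (length(abp) ) / abp$rate
  if (dur + 1e-9 < config$duration)
    stop("abp does not cover the configured duration", call. = FALSE)
  n <- round(config$duration * config$nirs_rate)
  t <- (seq_len(n) - 1) / config$nirs_rate  # true physiological time

  s <- abp_components(config, t, "slow") /
    slow_sd(config$slow_freqs, config$slow_amps)
  u <- band_process(t, INDEP_SLOW_FREQS,
                    sub_seed(config$seed, paste0(channel_id, "_indep")))
  modulation <- coupling * s + (1 - abs(coupling)) * u
  scalp <- config$scalp_fraction * config$scalp_amp *
    band_process(t, SCALP_FREQS, sub_seed(config$seed, "scalp_shared"))

  noise <- function(tag) {
    if (config$sensor_noise_sd == 0) return(numeric(n))
    with_seed(sub_seed(config$seed, paste0(channel_id, "_", tag)),
              stats::rnorm(n, 0, config$sensor_noise_sd))
  }
  hbo_n <- config$hbo_base + config$scalp_hbo_base +
    config$hbo_slow_amp * modulation + scalp + noise("hbo_norm")
  hhb_n <- config$hhb_base + config$scalp_hhb_base +
    config$hhb_slow_amp * modulation + scalp + noise("hhb_norm")
  hbo_s <- config$scalp_hbo_base + scalp + noise("hbo_short")
  hhb_s <- config$scalp_hhb_base + scalp + noise("hhb_short")

  if (!is.null(config$impulse_time)) {
    i <- round(config$impulse_time * config$nirs_rate) + 1L
    if (i >= 1L && i <= n) {
      hbo_n[i] <- hbo_n[i] + 50; hhb_n[i] <- hhb_n[i] + 50
      hbo_s[i] <- hbo_s[i] + 50; hhb_s[i] <- hhb_s[i] + 50
    }
  }

  mk <- function(v, trace) cvr_ts(v, config$nirs_rate, 0,
                                  paste0(channel_id, "_", trace), "a.u.")
  cvr_channel(channel_id, list(
    HbO_norm = mk(hbo_n, "HbO_norm"),
    HHb_norm = mk(hhb_n, "HHb_norm"),
    tHb_norm = mk(hbo_n + hhb_n, "tHb_norm"),
    HbDiff_norm = mk(hbo_n - hhb_n, "HbDiff_norm"),
    HbO_short = mk(hbo_s, "HbO_short"),
    HHb_short = mk(hhb_s, "HHb_short"),
    tHb_short = mk(hbo_s + hhb_s, "tHb_short"),
    HbDiff_short = mk(hbo_s - hhb_s, "HbDiff_short")
  ))
}

#' Simulate a complete multi-channel recording
#'
#' Generates the niABP stream and one NIRS channel bundle per entry of
#' `config$coupling`, assembled as a [cvr_record]. Channel ids are
#' `"ch1"`, `"ch2"`, ... (matching the built-in optode layouts), or the
#' names of `config$coupling` if set.
#'
#' @param config A [sim_config] object.
#' @return A `cvr_record` with `abp`, `channels` and `meta` (meta records the
#'   true simulated delay and the scenario seed).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "cvr_sim_config"))
  abp <- generate_abp(config)
  ids <- names(config$coupling)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("ch%d", seq_along(config$coupling))
  channels <- vector("list", length(ids))
  names(channels) <- ids
  for (i in seq_along(ids))
    channels[[i]] <- generate_nirs_channel(abp, config$coupling[i], config, ids[i])
  cvr_record(abp, channels,
             meta = list(true_delay = config$nirs_delay_true,
                         seed = config$seed, aligned = FALSE))
}

#' Read a simulation scenario from JSON
#'
#' The JSON document mirrors the [sim_config] fields (scalar fields as
#' scalars, `slow_freqs`/`slow_amps`/`coupling` as arrays). Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to a JSON scenario file.
#' @param seed Optional seed overriding the file's `seed` field.
#' @return A `cvr_sim_config`.
#' @export
sim_config_from_json <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown simulation config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}
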