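# Shared fixtures: small, fast simulation configs used across test files.

# A short noiseless scenario with matched stream rates and a true delay that
# the default 3.22-s correction cancels exactly (322 samples at 100 Hz).
exact_cfg <- function(duration = 500, coupling = c(ch1 = 1), ...) {
  sim_config(duration = duration, abp_rate = 100, nirs_rate = 100,
             cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
             coupling = coupling, scalp_fraction = 0, sensor_noise_sd = 0,
             nirs_delay_true = 3.22, seed = 11, ...)
}

# Default-rate scenario (250 Hz NIRS / 100 Hz ABP) with modest noise.
noisy_cfg <- function(duration = 400, coupling = c(ch1 = 1), seed = 7, ...) {
  sim_config(duration = duration, coupling = coupling,
             sensor_noise_sd = 0.2, seed = seed, ...)
}

# Full small pipeline: simulate -> align -> preprocess -> indices.
quick_indices <- function(cfg, delay = 3.22, ecfg = engine_config()) {
  rec <- simulate_recording(cfg)
  rec <- align_streams(rec, nirs_delay = delay,
                       decim_window = ecfg$decim_window)
  rec <- preprocess_record(rec, quiet = TRUE)
  suppressWarnings(compute_cvr(rec, ecfg))
}

# Independent slow-band power oracle: periodogram mass in [f_lo, f_hi] Hz.
band_power <- function(series, f_lo = 0.005, f_hi = 0.05) {
  v <- series$values[!is.na(series$values)]
  v <- v - mean(v)
  n <- length(v)
  sp <- Mod(stats::fft(v))^2 / n
  freq <- (seq_len(n) - 1) * series$rate / n
  sum(sp[freq >= f_lo & freq <= f_hi])
}
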