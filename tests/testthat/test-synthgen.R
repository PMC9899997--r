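test_that("degenerate config yields a constant ABP series", {
  cfg <- sim_config(duration = 10, abp_rate = 100, abp_mean = 90,
                    cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                    slow_freqs = numeric(0), slow_amps = numeric(0),
                    sensor_noise_sd = 0, coupling = 1)
  abp <- generate_abp(cfg)
  expect_length(abp$values, 1000L)
  expect_true(all(abp$values == 90))
})

test_that("a configured slow wave dominates the spectrum at its frequency and amplitude", {
  cfg <- sim_config(duration = 600, abp_rate = 100,
                    cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                    slow_freqs = 0.02, slow_amps = 5,
                    sensor_noise_sd = 0, coupling = 1)
  abp <- generate_abp(cfg)
  v <- abp$values - mean(abp$values)
  n <- length(v)
  sp <- Mod(stats::fft(v))^2
  freq <- (seq_len(n) - 1) * cfg$abp_rate / n
  half <- freq > 0 & freq <= cfg$abp_rate / 2
  peak_freq <- freq[half][which.max(sp[half])]
  expect_equal(peak_freq, 0.02, tolerance = 1e-9)
  # least-squares sinusoid fit as independent amplitude oracle
  t <- ts_times(abp)
  fit <- lm(abp$values ~ sin(2 * pi * 0.02 * t) + cos(2 * pi * 0.02 * t))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 5, tolerance = 0.01)
})

test_that("identical configs give bit-identical recordings", {
  cfg <- noisy_cfg(duration = 60)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$abp$values, r2$abp$values)
  expect_identical(r1$channels$ch1$traces$HbO_norm$values,
                   r2$channels$ch1$traces$HbO_norm$values)
  r3 <- simulate_recording(noisy_cfg(duration = 60, seed = 8))
  expect_false(identical(r1$abp$values, r3$abp$values))
})

test_that("hemoglobin identities hold exactly at every generated sample", {
  cfg <- noisy_cfg(duration = 60, coupling = c(a = 0.5, b = -0.7))
  rec <- simulate_recording(cfg)
  for (ch in rec$channels) {
    expect_identical(ch$traces$tHb_norm$values,
                     ch$traces$HbO_norm$values + ch$traces$HHb_norm$values)
    expect_identical(ch$traces$HbDiff_norm$values,
                     ch$traces$HbO_norm$values - ch$traces$HHb_norm$values)
    expect_identical(ch$traces$tHb_short$values,
                     ch$traces$HbO_short$values + ch$traces$HHb_short$values)
  }
})

test_that("short channel carries the scalp process but no cerebral component", {
  cfg <- sim_config(duration = 120, coupling = 1, scalp_fraction = 0.5,
                    sensor_noise_sd = 0, seed = 5)
  rec <- simulate_recording(cfg)
  ch <- rec$channels[[1L]]
  # remove shared scalp+baseline: residual of the short channel is flat
  expect_lt(stats::sd(ch$traces$HbO_short$values -
                        ch$traces$HHb_short$values -
                        (cfg$scalp_hbo_base - cfg$scalp_hhb_base)), 1e-12)
  # normal minus short leaves exactly the cerebral modulation (no scalp)
  pure <- ch$traces$HbO_norm$values - ch$traces$HbO_short$values
  t <- ts_times(ch$traces$HbO_norm)
  carrier <- cvrmap:::abp_components(cfg, t, "slow") /
    cvrmap:::slow_sd(cfg$slow_freqs, cfg$slow_amps)
  expect_equal(pure, cfg$hbo_base + cfg$hbo_slow_amp * carrier,
               tolerance = 1e-12)
})

test_that("with no cerebral content, normal minus short is zero-mean noise", {
  cfg <- sim_config(duration = 120, coupling = 1, scalp_fraction = 0.6,
                    hbo_base = 0, hhb_base = 0,
                    hbo_slow_amp = 0, hhb_slow_amp = 0,
                    sensor_noise_sd = 0.3, seed = 9)
  rec <- simulate_recording(cfg)
  ch <- rec$channels[[1L]]
  d <- ch$traces$HbO_norm$values - ch$traces$HbO_short$values
  expect_lt(abs(mean(d)), 0.02)          # zero-mean
  expect_equal(stats::sd(d), sqrt(2) * 0.3, tolerance = 0.05)  # noise only
})

test_that("downstream tHbx is nondecreasing in the coupling parameter", {
  couplings <- c(-1, -0.5, 0, 0.5, 1)
  cfg <- sim_config(duration = 500, abp_rate = 100, nirs_rate = 100,
                    cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                    coupling = couplings, scalp_fraction = 0,
                    sensor_noise_sd = 0, nirs_delay_true = 3.22, seed = 21)
  idx <- quick_indices(cfg)
  means <- vapply(seq_along(couplings), function(i) {
    s <- idx$series[[paste0("ch", i, "_tHbx")]]
    mean(s$values, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_equal(means[couplings == 1], 1, tolerance = 1e-9)
  expect_equal(means[couplings == -1], -1, tolerance = 1e-9)
})

test_that("invalid config fields are rejected naming the field", {
  expect_error(sim_config(duration = -5), "duration")
  expect_error(sim_config(slow_freqs = 0.1, slow_amps = 1), "slow_freqs")
  expect_error(sim_config(coupling = 1.5), "coupling")
  expect_error(sim_config(scalp_fraction = 2), "scalp_fraction")
  cfg <- noisy_cfg(duration = 30)
  abp <- generate_abp(cfg)
  expect_error(generate_nirs_channel(abp, coupling = 2, cfg), "coupling")
})

test_that("scenario JSON round-trips into a validated config", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(duration = 60, coupling = c(0.5, -0.5),
                            sensor_noise_sd = 0, seed = 4),
                       path, auto_unbox = TRUE, digits = NA)
  cfg <- sim_config_from_json(path)
  expect_s3_class(cfg, "cvr_sim_config")
  expect_equal(cfg$coupling, c(0.5, -0.5))
  expect_equal(cfg$seed, 4L)
  jsonlite::write_json(list(duration = 60, couplng = 1), path,
                       auto_unbox = TRUE)
  expect_error(sim_config_from_json(path), "couplng")
})
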