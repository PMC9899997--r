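test_that("decimation means match hand-computed window means", {
  x <- cvr_ts(rep(5, 5000), 250)
  expect_equal(decimate(x, 10)$values, c(5, 5))
  y <- cvr_ts(0:19, 1)
  d <- decimate(y, 10)
  expect_equal(d$values, c(4.5, 14.5))
  expect_equal(ts_times(d), c(10, 20))   # right-edge timestamps
  # incomplete trailing window dropped
  z <- cvr_ts(0:24, 1)
  expect_equal(decimate(z, 10)$values, c(4.5, 14.5))
  expect_error(decimate(cvr_ts(1:10, 0.1), 10), "2 sample periods")
})

test_that("a 10-s mean annihilates full-period sinusoids of any phase", {
  t <- (0:(250 * 60 - 1)) / 250
  for (case in list(c(0.1, 17.3, 0.7), c(1.1, 250, 2.1), c(0.2, 3, 5.5))) {
    x <- cvr_ts(case[2] * sin(2 * pi * case[1] * t + case[3]), 250)
    expect_lt(max(abs(decimate(x, 10)$values)), 1e-9 * case[2])
  }
})

test_that("windows below the valid-fraction threshold yield missing means", {
  v <- rep(1, 30)
  v[1:6] <- NA            # window 1 has 40% valid
  v[11:14] <- NA          # window 2 has 60% valid
  d <- decimate(cvr_ts(v, 1), 10, min_valid = 0.5)
  expect_identical(is.na(d$values), c(TRUE, FALSE, FALSE))
  expect_equal(d$values[2:3], c(1, 1))
})

test_that("pearson_cor matches the product-moment definition and contract", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_cor(c(1, 1, 1), c(1, 2, 3))))  # zero variance
  expect_true(is.na(pearson_cor(c(1, 2, NA), c(1, 2, 3)))) # < 3 pairs
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(30, 100, 10); y <- rnorm(30, 50, 5)
    expect_equal(pearson_cor(x, y), stats::cor(x, y), tolerance = 1e-14)
  }
})

test_that("sliding window count follows n - w + 1 and emits on full occupancy", {
  x <- cvr_ts(sin(1:40), 0.1, start = 10)
  y <- cvr_ts(cos(1:40), 0.1, start = 10)
  cfg <- engine_config()
  s <- sliding_index(x, y, cfg)
  expect_length(s$values, 11L)         # 40 - 30 + 1
  expect_equal(s$timestamps[1L], 10 + 29 * 10)  # first full window's right edge
  # affine surrogate: every emitted value is 1 (up to float rounding)
  s2 <- sliding_index(cvr_ts(2 * y$values + 5, 0.1, start = 10), y, cfg)
  expect_equal(s2$values, rep(1, 11), tolerance = 1e-12)
  # a single missing mean inside a window knocks that window out
  xm <- x; xm$values[35L] <- NA
  s3 <- sliding_index(xm, y, cfg)
  expect_identical(is.na(s3$values), seq(30, 40) >= 35)
  # overlap shorter than the window: empty series plus warning
  expect_warning(s4 <- sliding_index(cvr_ts(1:10, 0.1), cvr_ts(1:10, 0.1), cfg),
                 "shorter")
  expect_length(s4$values, 0L)
})

test_that("sliding correlations equal naive per-window recomputation", {
  cfg <- engine_config()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(30:80, 1)
    x <- rnorm(n, 90, 8) + cumsum(rnorm(n, 0, 0.5))
    y <- 0.3 * x + rnorm(n, 40, 6)
    if (rep %% 4 == 0) x[sample(n, 2)] <- NA
    sx <- cvr_ts(x, 0.1, 10); sy <- cvr_ts(y, 0.1, 10)
    got <- sliding_index(sx, sy, cfg)$values
    want <- vapply(30:n, function(e) {
      xi <- x[(e - 29):e]; yi <- y[(e - 29):e]
      if (anyNA(xi) || anyNA(yi)) return(NA_real_)
      stats::cor(xi, yi)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("indices are bounded and affine-equivariant", {
  cfg <- engine_config()
  set.seed(7)
  y <- cvr_ts(rnorm(60, 90, 5), 0.1)
  x <- cvr_ts(rnorm(60, 40, 5), 0.1)
  base <- sliding_index(x, y, cfg)$values
  expect_true(all(abs(base) <= 1))
  up <- sliding_index(cvr_ts(3.7 * x$values - 2, 0.1), y, cfg)$values
  dn <- sliding_index(cvr_ts(-0.4 * x$values + 9, 0.1), y, cfg)$values
  expect_equal(up, base, tolerance = 1e-12)
  expect_equal(dn, -base, tolerance = 1e-12)
})

test_that("zero-variance windows emit missing, not errors", {
  cfg <- engine_config()
  x <- cvr_ts(c(rep(3, 35), rnorm(15)), 0.1)
  y <- cvr_ts(rnorm(50), 0.1)
  s <- sliding_index(x, y, cfg)
  expect_true(all(is.na(s$values[1:6])))   # windows fully inside the flatline
  expect_true(any(!is.na(s$values)))
})

test_that("five indices per channel are emitted, eight channels give forty", {
  idx1 <- quick_indices(exact_cfg(duration = 400))
  expect_length(idx1$series, 5L)
  expect_setequal(vapply(idx1$series, function(s) s$index_type, character(1)),
                  c("HbOx", "HHbx", "tHbx", "HbDiffx", "COx"))
  idx8 <- quick_indices(exact_cfg(duration = 320,
                                  coupling = stats::setNames(rep(0.5, 8),
                                                             paste0("ch", 1:8))))
  expect_length(idx8$series, 40L)
})

test_that("with HHb identically zero, tHbx, HbOx and HbDiffx coincide", {
  cfg <- exact_cfg(duration = 400)
  rec <- align_streams(simulate_recording(cfg))
  ch <- rec$channels$ch1
  n <- length(ch$traces$HbO_norm)
  zero <- cvr_ts(rep(0, n), ch$traces$HbO_norm$rate,
                 ch$traces$HbO_norm$start)
  ch$traces$HHb_pure <- zero
  ch$traces$HbO_pure <- ch$traces$HbO_norm
  ch$traces$tHb_pure <- ch$traces$HbDiff_pure <- NULL
  rec$channels$ch1 <- derive_traces(ch)
  idx <- compute_cvr(rec, engine_config(index_types = c("HbOx", "tHbx", "HbDiffx")))
  expect_identical(idx$series$ch1_tHbx$values, idx$series$ch1_HbOx$values)
  expect_identical(idx$series$ch1_HbDiffx$values, idx$series$ch1_HbOx$values)
})

test_that("a missing surrogate trace is skipped with a warning", {
  cfg <- exact_cfg(duration = 330)
  rec <- align_streams(simulate_recording(cfg))
  rec <- preprocess_record(rec, quiet = TRUE)
  rec$channels$ch1$traces$rSO2 <- NULL
  expect_warning(idx <- compute_cvr(rec), "rSO2")
  expect_length(idx$series, 4L)
})

test_that("engine config invariants are enforced", {
  expect_error(engine_config(decim_window = 0), "decim_window")
  expect_error(engine_config(corr_window = 2), "corr_window")
  expect_error(engine_config(update_step = 0), "update_step")
  cfg <- engine_config(corr_window = 10)
  expect_equal(cfg$min_valid_means_per_window, 10L)
})

test_that("index series timestamps advance by update_step x decim_window", {
  idx <- quick_indices(exact_cfg(duration = 420),
                       ecfg = engine_config(update_step = 2))
  s <- idx$series$ch1_tHbx
  expect_true(all(abs(diff(s$timestamps) - 20) < 1e-9))
  expect_true(all(abs(s$values[!is.na(s$values)]) <= 1))
})
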