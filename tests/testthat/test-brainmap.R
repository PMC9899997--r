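test_that("lobar8 layout has 8 normal channels, 4 per hemisphere", {
  lay <- build_layout("lobar8")
  normal <- lay$channels[lay$channels$kind == "normal", ]
  expect_equal(nrow(normal), 8L)
  pos <- channel_positions(lay)
  hemis <- ifelse(pos$x < 0.5, "L", "R")
  expect_equal(sum(hemis == "L"), 4L)
  expect_equal(sum(hemis == "R"), 4L)
  expect_true(all(lay$channels$separation_mm[lay$channels$kind == "normal"] == 30))
  expect_true(all(lay$channels$separation_mm[lay$channels$kind == "short"] == 10))
})

test_that("grid4x4 layout has 24 normal channels from 8 Tx + 8 Rx", {
  lay <- build_layout("grid4x4")
  expect_equal(sum(lay$channels$kind == "normal"), 24L)
  expect_equal(sum(lay$optodes$role == "transmitter"), 8L)
  expect_equal(sum(lay$optodes$role == "receiver"), 8L)
})

test_that("grid channel enumeration matches the closed form and brute force", {
  expect_equal(nrow(enumerate_grid_channels(4, 4)), 24L)
  expect_equal(nrow(enumerate_grid_channels(2, 2)), 4L)
  expect_equal(nrow(enumerate_grid_channels(1, 2)), 1L)
  for (r in 1:6) for (c in 1:6) {
    got <- nrow(enumerate_grid_channels(r, c))
    expect_equal(got, r * (c - 1) + c * (r - 1))
    # brute-force adjacency scan as the independent oracle
    brute <- 0L
    for (i in seq_len(r)) for (j in seq_len(c)) {
      if (j < c) brute <- brute + 1L
      if (i < r) brute <- brute + 1L
    }
    expect_equal(got, brute)
  }
  # every enumerated pair joins one transmitter and one receiver
  g <- enumerate_grid_channels(4, 4)
  expect_true(all(startsWith(g$tx_id, "T")))
  expect_true(all(startsWith(g$rx_id, "R")))
  expect_false(anyDuplicated(g$channel_id) > 0)
})

test_that("channels referencing wrong-role optodes fail validation", {
  spec <- list(
    layout_id = "bad",
    optodes = list(list(id = "A", role = "receiver", x = 0.3, y = 0.5),
                   list(id = "B", role = "receiver", x = 0.4, y = 0.5)),
    channels = list(list(channel_id = "ch1", tx = "A", rx = "B",
                         kind = "normal", separation_mm = 30)))
  expect_error(build_layout(spec), "role")
  spec$optodes[[1]]$role <- "transmitter"
  expect_s3_class(build_layout(spec), "cvr_layout")
  spec$channels[[1]]$separation_mm <- 20
  expect_error(build_layout(spec), "separation")
  expect_error(build_layout("nonesuch"), "unknown built-in")
})

test_that("the colour map is a linear blue-white-red diverging scale", {
  expect_equal(index_to_color(-1), "#0000FF")
  expect_equal(index_to_color(1), "#FF0000")
  expect_equal(index_to_color(0), "#FFFFFF")
  expect_equal(index_to_color(NA), "#808080")
  expect_equal(index_to_color(c(-2, 2)), c("#0000FF", "#FF0000"))  # clamped
  # hue symmetry: colour of -v swaps the red and blue components of +v
  for (v in seq(0, 1, 0.1)) {
    up <- grDevices::col2rgb(index_to_color(v))
    dn <- grDevices::col2rgb(index_to_color(-v))
    expect_equal(unname(up["red", 1]), unname(dn["blue", 1]))
    expect_equal(unname(up["blue", 1]), unname(dn["red", 1]))
    expect_equal(unname(up["green", 1]), unname(dn["green", 1]))
  }
})

make_index_set <- function(channels, times, value_fun) {
  cvr_indices(stats::setNames(lapply(channels, function(id)
    cvr_index(id, "tHbx", times, value_fun(id, times))),
    paste0(channels, "_tHbx")))
}

test_that("frame count is the inclusive tick count of the index span", {
  idx <- make_index_set(paste0("ch", 1:8), seq(0, 100, 10),
                        function(id, t) rep(0.5, length(t)))
  frames <- render_frames(idx, "lobar8", "tHbx", cadence = 10)
  expect_length(frames, 11L)
})

test_that("constant +1 input paints every channel the red endpoint", {
  idx <- make_index_set(paste0("ch", 1:8), seq(10, 30, 10),
                        function(id, t) rep(1, length(t)))
  frames <- render_frames(idx, "lobar8", "tHbx", cadence = 10)
  for (f in frames)
    expect_true(all(f$colors == "#FF0000"))
})

test_that("a channel with no values is gray in every frame; stale values expire", {
  times <- seq(10, 60, 10)
  idx <- make_index_set(paste0("ch", 1:8), times, function(id, t) {
    if (id == "ch3") rep(NA_real_, length(t))
    else if (id == "ch5") c(0.5, rep(NA_real_, length(t) - 1))
    else rep(-1, length(t))
  })
  frames <- render_frames(idx, "lobar8", "tHbx", cadence = 10)
  for (f in frames) expect_equal(f$colors[["ch3"]], "#808080")
  # ch5's only value (t=10) is carried at t=10 but expired by t=30
  expect_equal(frames[[1L]]$values[["ch5"]], 0.5)
  expect_true(is.na(frames[[3L]]$values[["ch5"]]))
})

test_that("frames are deterministic and written as PNG files", {
  idx <- make_index_set(paste0("ch", 1:8), seq(0, 20, 10),
                        function(id, t) seq(-1, 1, length.out = length(t)))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  f1 <- render_frames(idx, "lobar8", "tHbx", cadence = 10, out_dir = dir1)
  f2 <- render_frames(idx, "lobar8", "tHbx", cadence = 10, out_dir = dir2)
  expect_identical(lapply(f1, `[[`, "values"), lapply(f2, `[[`, "values"))
  expect_identical(lapply(f1, `[[`, "raster"), lapply(f2, `[[`, "raster"))
  pngs <- list.files(dir1, pattern = "^frame_\\d{4}\\.png$")
  expect_length(pngs, 3L)
  img <- png::readPNG(file.path(dir1, pngs[1L]))
  expect_equal(dim(img)[1:2], c(220, 220))
})

test_that("requesting an absent index type lists the available ones", {
  idx <- make_index_set("ch1", c(10, 20), function(id, t) c(0, 0))
  expect_error(render_frames(idx, "lobar8", "COx"), "tHbx")
})

test_that("interpolated fields stay within the index range", {
  idx <- make_index_set(paste0("ch", 1:8), c(10, 20),
                        function(id, t) rep(0.25, length(t)))
  frames <- render_frames(idx, "lobar8", "tHbx", cadence = 10,
                          interpolate = TRUE, width = 80, height = 80)
  expect_length(frames, 2L)
  expect_true(all(frames[[1L]]$raster >= 0 & frames[[1L]]$raster <= 1))
})
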