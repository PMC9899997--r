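#' Enumerate channels of a checkerboard optode grid
#'
#' On a `rows x cols` grid of optodes with alternating transmitter/receiver
#' roles (checkerboard: role is transmitter where row+col is even), every
#' orthogonally adjacent optode pair forms one channel, giving
#' `rows*(cols-1) + cols*(rows-1)` channels -- 24 for the 4x4 grid.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @return A data.frame with `channel_id`, `tx_id`, `rx_id` and the grid
#'   coordinates of the channel midpoint (`row`, `col`, possibly half-integer).
#' @export
enumerate_grid_channels <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  opt_id <- function(r, c) {
    role <- if ((r + c) %% 2 == 0) "T" else "R"
    sprintf("%s%d_%d", role, r, c)
  }
  out <- list()
  k <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    for (d in list(c(0L, 1L), c(1L, 0L))) {  # right neighbour, then below
      r2 <- r + d[1L]; c2 <- c + d[2L]
      if (r2 > rows || c2 > cols) next
      k <- k + 1L
      a <- opt_id(r, c); b <- opt_id(r2, c2)
      tx <- if (startsWith(a, "T")) a else b
      rx <- if (startsWith(a, "R")) a else b
      out[[k]] <- data.frame(channel_id = sprintf("ch%d", k),
                             tx_id = tx, rx_id = rx,
                             row = (r + r2) / 2, col = (c + c2) / 2)
    }
  }
  if (k == 0L)
    return(data.frame(channel_id = character(0), tx_id = character(0),
                      rx_id = character(0), row = numeric(0), col = numeric(0)))
  do.call(rbind, out)
}

lobar_sites <- function() {
  # Left-hemisphere lobe sites on the normalised template (anterior = y up);
  # right hemisphere is the x mirror. Cosmetic placement, no registration.
  data.frame(lobe = c("Frontal", "Parietal", "Temporal", "Occipital"),
             x = c(0.36, 0.38, 0.17, 0.36),
             y = c(0.76, 0.55, 0.46, 0.24))
}

#' Build an optode layout on the 2D brain template
#'
#' Either names a built-in layout or supplies an explicit description.
#' Built-ins: `"lobar8"` -- 8 normal channels, one per lobe (frontal,
#' parietal, temporal, occipital) per hemisphere, each with a short
#' scalp-reference channel; `"grid4x4"` -- 8 transmitters and 8 receivers in
#' a 4x4 checkerboard on the left hemisphere forming 24 normal channels.
#' Explicit descriptions are a list (or JSON file, see [layout_from_json])
#' with `layout_id`, `optodes` (id, role in transmitter/receiver/reference,
#' x, y in \[0,1\], hemisphere) and `channels` (channel_id, tx, rx, kind in
#' normal/short, separation_mm).
#'
#' Validation enforces the montage geometry: a channel's `tx` must be a
#' transmitter; its `rx` a receiver (normal channels, 30 mm nominal
#' separation) or a reference optode (short channels, 10 mm); channel ids
#' unique.
#'
#' @param spec `"lobar8"`, `"grid4x4"`, or an explicit layout list.
#' @return An object of class `cvr_layout`.
#' @export
build_layout <- function(spec = "lobar8") {
  if (is.character(spec) && length(spec) == 1L) {
    spec <- switch(spec,
                   lobar8 = builtin_lobar8(),
                   grid4x4 = builtin_grid4x4(),
                   stop("unknown built-in layout '", spec,
                        "' (available: lobar8, grid4x4)", call. = FALSE))
  }
  validate_layout(spec)
}

builtin_lobar8 <- function() {
  sites <- lobar_sites()
  optodes <- list(); channels <- list()
  k <- 0L
  for (i in seq_len(nrow(sites))) for (hemi in c("L", "R")) {
    k <- k + 1L
    x <- if (hemi == "L") sites$x[i] else 1 - sites$x[i]
    y <- sites$y[i]
    dx <- if (hemi == "L") 0.07 else -0.07   # receiver toward the midline
    tag <- sprintf("%s%d", hemi, i)
    optodes[[length(optodes) + 1L]] <- list(id = paste0("Tx", tag),
                                            role = "transmitter",
                                            x = x, y = y, hemisphere = hemi)
    optodes[[length(optodes) + 1L]] <- list(id = paste0("Rx", tag),
                                            role = "receiver",
                                            x = x + dx, y = y, hemisphere = hemi)
    optodes[[length(optodes) + 1L]] <- list(id = paste0("Ref", tag),
                                            role = "reference",
                                            x = x + dx / 3, y = y - 0.03,
                                            hemisphere = hemi)
    channels[[length(channels) + 1L]] <- list(channel_id = sprintf("ch%d", k),
                                              tx = paste0("Tx", tag),
                                              rx = paste0("Rx", tag),
                                              kind = "normal", separation_mm = 30)
    channels[[length(channels) + 1L]] <- list(channel_id = sprintf("sh%d", k),
                                              tx = paste0("Tx", tag),
                                              rx = paste0("Ref", tag),
                                              kind = "short", separation_mm = 10)
  }
  list(layout_id = "lobar8", template = "head_top",
       optodes = optodes, channels = channels)
}

builtin_grid4x4 <- function() {
  grid <- enumerate_grid_channels(4, 4)
  xmap <- function(col) 0.08 + (col - 1) / 3 * 0.34  # left hemisphere band
  ymap <- function(row) 0.78 - (row - 1) / 3 * 0.52
  optodes <- list()
  for (r in 1:4) for (c in 1:4) {
    role <- if ((r + c) %% 2 == 0) "transmitter" else "receiver"
    id <- sprintf("%s%d_%d", if (role == "transmitter") "T" else "R", r, c)
    optodes[[length(optodes) + 1L]] <- list(id = id, role = role,
                                            x = xmap(c), y = ymap(r),
                                            hemisphere = "L")
  }
  channels <- lapply(seq_len(nrow(grid)), function(i)
    list(channel_id = grid$channel_id[i], tx = grid$tx_id[i],
         rx = grid$rx_id[i], kind = "normal", separation_mm = 30))
  list(layout_id = "grid4x4", template = "head_top",
       optodes = optodes, channels = channels)
}

validate_layout <- function(spec) {
  need <- c("layout_id", "optodes", "channels")
  if (!is.list(spec) || !all(need %in% names(spec)))
    stop("layout validation error: need fields ",
         paste(need, collapse = ", "), call. = FALSE)
  opt <- do.call(rbind, lapply(spec$optodes, function(o)
    data.frame(id = o$id, role = o$role, x = o$x, y = o$y,
               hemisphere = if (is.null(o$hemisphere)) "" else o$hemisphere)))
  if (anyDuplicated(opt$id))
    stop("layout validation error: duplicate optode ids", call. = FALSE)
  if (!all(opt$role %in% c("transmitter", "receiver", "reference")))
    stop("layout validation error: optode role must be transmitter, receiver or reference",
         call. = FALSE)
  if (any(opt$x < 0 | opt$x > 1 | opt$y < 0 | opt$y > 1))
    stop("layout validation error: optode positions must lie in [0,1]^2",
         call. = FALSE)
  chn <- do.call(rbind, lapply(spec$channels, function(ch)
    data.frame(channel_id = ch$channel_id, tx = ch$tx, rx = ch$rx,
               kind = ch$kind,
               separation_mm = if (is.null(ch$separation_mm)) NA_real_
                               else ch$separation_mm)))
  if (anyDuplicated(chn$channel_id))
    stop("layout validation error: duplicate channel ids", call. = FALSE)
  if (!all(chn$kind %in% c("normal", "short")))
    stop("layout validation error: channel kind must be normal or short",
         call. = FALSE)
  role_of <- stats::setNames(opt$role, opt$id)
  for (i in seq_len(nrow(chn))) {
    if (!(chn$tx[i] %in% opt$id) || !(chn$rx[i] %in% opt$id))
      stop("layout validation error: channel '", chn$channel_id[i],
           "' references an unknown optode", call. = FALSE)
    if (role_of[[chn$tx[i]]] != "transmitter")
      stop("layout validation error: channel '", chn$channel_id[i],
           "' tx optode '", chn$tx[i], "' has role ", role_of[[chn$tx[i]]],
           call. = FALSE)
    want_rx <- if (chn$kind[i] == "normal") "receiver" else "reference"
    if (role_of[[chn$rx[i]]] != want_rx)
      stop("layout validation error: ", chn$kind[i], " channel '",
           chn$channel_id[i], "' rx optode '", chn$rx[i], "' has role ",
           role_of[[chn$rx[i]]], " (expected ", want_rx, ")", call. = FALSE)
    want_sep <- if (chn$kind[i] == "normal") 30 else 10
    if (!is.na(chn$separation_mm[i]) && chn$separation_mm[i] != want_sep)
      stop("layout validation error: ", chn$kind[i], " channel '",
           chn$channel_id[i], "' must have nominal separation ", want_sep,
           " mm", call. = FALSE)
  }
  structure(list(layout_id = spec$layout_id,
                 template = if (is.null(spec$template)) "head_top"
                            else spec$template,
                 optodes = opt, channels = chn),
            class = "cvr_layout")
}

#' Read an optode layout from JSON
#'
#' @param path JSON file with `layout_id`, `optodes`, `channels` (see
#'   [build_layout]); or a file containing just a built-in name.
#' @return A `cvr_layout`.
#' @export
layout_from_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.character(spec)) return(build_layout(spec[[1L]]))
  build_layout(spec)
}

#' @export
print.cvr_layout <- function(x, ...) {
  cat(sprintf("<cvr_layout> %s: %d optodes, %d normal + %d short channel(s)\n",
              x$layout_id, nrow(x$optodes),
              sum(x$channels$kind == "normal"),
              sum(x$channels$kind == "short")))
  invisible(x)
}

# Midpoints of tx-rx positions for the layout's normal channels.
channel_positions <- function(layout) {
  stopifnot(inherits(layout, "cvr_layout"))
  chn <- layout$channels[layout$channels$kind == "normal", , drop = FALSE]
  px <- stats::setNames(layout$optodes$x, layout$optodes$id)
  py <- stats::setNames(layout$optodes$y, layout$optodes$id)
  data.frame(channel_id = chn$channel_id,
             x = (px[chn$tx] + px[chn$rx]) / 2,
             y = (py[chn$tx] + py[chn$rx]) / 2,
             row.names = NULL)
}

#' Map CVR index values to colours
#'
#' Linear symmetric diverging blue-white-red map: -1 maps to pure blue
#' (intact reactivity), +1 to pure red (impaired), 0 to the neutral white
#' midpoint. Values outside \[-1, +1\] are clamped; missing values map to a
#' fixed gray. The map is hue-symmetric: the colour of `-v` is the colour of
#' `+v` with the red and blue components exchanged.
#'
#' @param value Numeric vector of index values (NA allowed).
#' @param missing_color Hex colour for missing values (default `"#808080"`).
#' @return Character vector of `#RRGGBB` colours.
#' @export
index_to_color <- function(value, missing_color = "#808080") {
  v <- pmax(-1, pmin(1, value))
  v[is.na(v)] <- 0
  r <- ifelse(v <= 0, 1 + v, 1)
  b <- ifelse(v >= 0, 1 - v, 1)
  g <- 1 - abs(v)
  out <- grDevices::rgb(r, g, b)
  out[is.na(value)] <- missing_color
  out
}

read_brain_outline <- function() {
  path <- system.file("extdata", "brain_outline.json", package = "cvrmap")
  poly <- jsonlite::read_json(path, simplifyVector = TRUE)$outline
  m <- if (is.matrix(poly)) poly else do.call(rbind, lapply(poly, unlist))
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

# Rasterise one frame: white background, brain outline in dark gray, one
# filled disc per normal channel at the tx-rx midpoint.
rasterize_frame <- function(values, layout, width, height, radius = 0.04,
                            missing_color = "#808080", interpolate = FALSE) {
  pos <- channel_positions(layout)
  img <- array(1, dim = c(height, width, 3))
  px <- function(x) pmin(width, pmax(1, round(x * (width - 1)) + 1))
  py <- function(y) pmin(height, pmax(1, round((1 - y) * (height - 1)) + 1))
  outline <- read_brain_outline()

  if (interpolate) {
    v <- values[pos$channel_id]
    okc <- !is.na(v)
    if (any(okc)) {
      cx <- (col(matrix(0, height, width)) - 1) / (width - 1)
      cy <- 1 - (row(matrix(0, height, width)) - 1) / (height - 1)
      inside <- points_in_polygon(as.vector(cx), as.vector(cy), outline)
      num <- matrix(0, height, width); den <- matrix(0, height, width)
      for (i in which(okc)) {
        d2 <- (cx - pos$x[i])^2 + (cy - pos$y[i])^2
        w <- 1 / (d2 + 1e-6)
        num <- num + w * v[i]; den <- den + w
      }
      field <- pmax(-1, pmin(1, num / den))
      cols <- grDevices::col2rgb(index_to_color(as.vector(field))) / 255
      for (k in 1:3) {
        plane <- img[, , k]
        plane[inside] <- cols[k, inside]
        img[, , k] <- plane
      }
    }
  }

  # outline: dense parametric samples along each polygon edge
  o <- rbind(outline, outline[1L, , drop = FALSE])
  for (i in seq_len(nrow(o) - 1L)) {
    s <- seq(0, 1, length.out = 24)
    xs <- px(o[i, 1] + s * (o[i + 1L, 1] - o[i, 1]))
    ys <- py(o[i, 2] + s * (o[i + 1L, 2] - o[i, 2]))
    for (k in 1:3) img[cbind(ys, xs, k)] <- 0.25
  }

  rpix <- max(1, round(radius * width))
  for (i in seq_len(nrow(pos))) {
    val <- values[[pos$channel_id[i]]]
    colr <- grDevices::col2rgb(index_to_color(val, missing_color)) / 255
    cxp <- px(pos$x[i]); cyp <- py(pos$y[i])
    xr <- max(1, cxp - rpix):min(width, cxp + rpix)
    yr <- max(1, cyp - rpix):min(height, cyp + rpix)
    for (yy in yr) {
      dx2 <- rpix^2 - (yy - cyp)^2
      if (dx2 < 0) next
      xs <- xr[abs(xr - cxp) <= sqrt(dx2)]
      for (k in 1:3) img[yy, xs, k] <- colr[k]
    }
  }
  img
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Render timed heat-map frames of a CVR index
#'
#' Replays an index series as topographic frames on the brain template: one
#' frame per cadence tick over the series' time span (inclusive of both
#' ends), each normal channel drawn as a filled disc at its tx-rx midpoint,
#' coloured by the channel's most recent index value at or before the tick
#' ([index_to_color]). A value older than one cadence interval -- or a
#' channel with no value at all -- renders as the missing gray.
#'
#' @param indices A `cvr_indices` object or path to an index CSV.
#' @param layout A `cvr_layout` (or built-in name passed to [build_layout]).
#' @param index_type Which index to render (default `"tHbx"`).
#' @param cadence Frame interval in seconds (default 10, the display rate).
#' @param out_dir If non-`NULL`, frames are written there as numbered PNGs
#'   (`frame_0001.png`, ...).
#' @param width,height Raster size in pixels.
#' @param interpolate If `TRUE`, an inverse-distance-weighted field between
#'   the channel markers is painted inside the brain outline (off by
#'   default: the display shows discrete channel patches).
#' @param missing_color Colour for missing values.
#' @return Invisibly, a list of `cvr_frame` objects (timestamp, per-channel
#'   values and colours, raster array).
#' @export
render_frames <- function(indices, layout = "lobar8", index_type = "tHbx",
                          cadence = 10, out_dir = NULL,
                          width = 220, height = 220, interpolate = FALSE,
                          missing_color = "#808080") {
  if (is.character(indices)) indices <- read_index_csv(indices)
  stopifnot(inherits(indices, "cvr_indices"))
  if (is.character(layout)) layout <- build_layout(layout)
  stopifnot(inherits(layout, "cvr_layout"))
  sel <- Filter(function(s) s$index_type == index_type, indices$series)
  if (!length(sel)) {
    avail <- unique(vapply(indices$series, function(s) s$index_type, character(1)))
    stop("index type '", index_type, "' not present (available: ",
         paste(avail, collapse = ", "), ")", call. = FALSE)
  }
  by_channel <- stats::setNames(sel, vapply(sel, function(s) s$channel_id,
                                            character(1)))
  t_all <- unlist(lapply(sel, function(s) s$timestamps))
  if (!length(t_all)) stop("index series are empty; nothing to render",
                           call. = FALSE)
  ticks <- seq(min(t_all), max(t_all) + cadence / 1e6, by = cadence)
  pos <- channel_positions(layout)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  frames <- vector("list", length(ticks))
  for (f in seq_along(ticks)) {
    tk <- ticks[f]
    vals <- stats::setNames(rep(NA_real_, nrow(pos)), pos$channel_id)
    for (id in pos$channel_id) {
      s <- by_channel[[id]]
      if (is.null(s)) next
      at <- which(s$timestamps <= tk + 1e-9 & s$timestamps > tk - cadence - 1e-9)
      if (!length(at)) next
      vals[[id]] <- s$values[max(at)]
    }
    raster <- rasterize_frame(vals, layout, width, height,
                              missing_color = missing_color,
                              interpolate = interpolate)
    fr <- structure(list(timestamp = tk, index_type = index_type,
                         values = vals,
                         colors = stats::setNames(
                           index_to_color(vals, missing_color), names(vals)),
                         raster = raster),
                    class = "cvr_frame")
    if (!is.null(out_dir))
      png::writePNG(raster, file.path(out_dir, sprintf("frame_%04d.png", f)))
    frames[[f]] <- fr
  }
  invisible(frames)
}

#' @export
print.cvr_frame <- function(x, ...) {
  cat(sprintf("<cvr_frame> %s @ t = %g s: %d channel(s), %d missing\n",
              x$index_type, x$timestamp, length(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.cvr_frame <- function(x, ...) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = 1)
  graphics::rasterImage(x$raster, 0, 0, 1, 1)
  graphics::title(main = sprintf("%s at t = %g s", x$index_type, x$timestamp))
  invisible(x)
}
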