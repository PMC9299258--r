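# Eight-stage paired RGB-D augmentation pipeline. Every geometric stage is
# applied with identical parameters to the colour and depth channels; the
# photometric stage touches colour only. Stage order is fixed: ToSensor,
# PhotometricDistort, Expand, RandomSampleCrop, RandomMirror, ToPercentCoords,
# Resize, SubtractMeans.

#' Build an augmentation sample from an RGB-D scene
#'
#' @param scene An `rgbd_scene` (rgb 0-255, depth in mm, corner-form boxes).
#' @return A `sample` list: `rgb`, `depth`, `boxes`, `labels`, `coord_mode`.
#' @export
as_sample <- function(scene) {
  structure(list(rgb = scene$rgb * 1.0, depth = scene$depth * 1.0,
                 boxes = rbind(scene$boxes), labels = scene$labels,
                 coord_mode = "absolute"),
            class = "rgbd_sample")
}

#' ToSensor: numeric conversion
#'
#' Converts both channels to real-valued arrays (the analogue of a
#' tensor-conversion stage); geometry untouched.
#'
#' @param s A sample from [as_sample()].
#' @return The sample with double-typed channels.
#' @export
to_sensor <- function(s) {
  s$rgb <- s$rgb * 1.0
  s$depth <- s$depth * 1.0
  s
}

#' PhotometricDistort: colour jitter on the RGB channel only
#'
#' Random brightness shift, contrast scale, saturation scale and hue rotation
#' applied to the colour image; depth and boxes are untouched, and output
#' values are clipped to 0-255. Passing `params` with zero/unit magnitudes
#' forces the identity.
#'
#' @param s A sample.
#' @param params Optional list `brightness` (additive, default U(-32, 32)),
#'   `contrast` (multiplicative, U(0.5, 1.5)), `saturation` (U(0.5, 1.5)),
#'   `hue` (degrees, U(-18, 18)); each jitter is applied with probability
#'   0.5 when sampled.
#' @return The distorted sample.
#' @export
photometric_distort <- function(s, params = NULL) {
  if (is.null(params)) {
    params <- list(
      brightness = if (stats::runif(1) < 0.5) stats::runif(1, -32, 32) else 0,
      contrast = if (stats::runif(1) < 0.5) stats::runif(1, 0.5, 1.5) else 1,
      saturation = if (stats::runif(1) < 0.5) stats::runif(1, 0.5, 1.5) else 1,
      hue = if (stats::runif(1) < 0.5) stats::runif(1, -18, 18) else 0)
  }
  x <- s$rgb + params$brightness
  x <- (x - 127.5) * params$contrast + 127.5
  if (params$saturation != 1 || params$hue != 0) {
    d <- dim(x)
    m <- t(matrix(pmin(pmax(x, 0), 255), d[1] * d[2], 3L))
    hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
    h <- (hsv[1L, ] * 360 + params$hue) %% 360
    sat <- pmin(pmax(hsv[2L, ] * params$saturation, 0), 1)
    x <- array(hsv_to_rgb(h, sat, hsv[3L, ]) * 255, d)
  }
  s$rgb <- pmin(pmax(x, 0), 255)
  s
}

#' Expand: paste both channels onto a larger canvas
#'
#' With probability 0.5 (when parameters are sampled) the pair is pasted at a
#' random offset onto a canvas scaled by `r` in `[1, max_ratio]`; the colour
#' fill is the per-channel image mean, the depth fill is the scene's far
#' value, and boxes are translated by the offset.
#'
#' @param s A sample in absolute coordinates.
#' @param max_ratio Maximum canvas scale (>= 1), default 4.
#' @param params Optional list `ratio`, `ox`, `oy` (integer pixel offsets).
#' @param rgb_fill,depth_fill Fill values; defaults are the channel means
#'   and `max(depth)`.
#' @return The expanded sample.
#' @export
expand <- function(s, max_ratio = 4, params = NULL, rgb_fill = NULL,
                   depth_fill = NULL) {
  if (max_ratio < 1) stop("invalid config: max_ratio must be >= 1")
  stopifnot(s$coord_mode == "absolute")
  h <- dim(s$rgb)[1]; w <- dim(s$rgb)[2]
  if (is.null(params)) {
    if (stats::runif(1) < 0.5) return(s)
    ratio <- stats::runif(1, 1, max_ratio)
    params <- list(ratio = ratio,
                   ox = sample.int(floor(w * ratio) - w + 1L, 1L) - 1L,
                   oy = sample.int(floor(h * ratio) - h + 1L, 1L) - 1L)
  }
  H <- floor(h * params$ratio); W <- floor(w * params$ratio)
  ox <- params$ox; oy <- params$oy
  if (ox + w > W || oy + h > H) stop("expand offset out of canvas")
  if (is.null(rgb_fill)) rgb_fill <- apply(s$rgb, 3L, mean)
  if (is.null(depth_fill)) depth_fill <- max(s$depth)
  rgb <- array(rep(rgb_fill, each = H * W), c(H, W, 3L))
  rgb[oy + seq_len(h), ox + seq_len(w), ] <- s$rgb
  depth <- matrix(depth_fill, H, W)
  depth[oy + seq_len(h), ox + seq_len(w)] <- s$depth
  s$rgb <- rgb; s$depth <- depth
  if (nrow(s$boxes) > 0)
    s$boxes <- s$boxes + rep(c(ox, oy, ox, oy), each = nrow(s$boxes))
  s
}

#' RandomSampleCrop: SSD-style minimum-IoU crop
#'
#' Samples a mode from \{no-crop, min-IoU in `min_ious`, unconstrained\},
#' then retries random crop rectangles (up to 50 times) until every ground
#' truth whose centre falls inside the crop has IoU with the crop of at
#' least the sampled minimum and at least one box survives; boxes are
#' retained by the centre rule and clipped to the crop. Falls back to
#' no-crop when no valid rectangle is found.
#'
#' @param s A sample in absolute coordinates.
#' @param min_ious Minimum-IoU menu, default `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param params Optional forced crop: list `x, y, w, h` (or `mode =
#'   "none"`).
#' @return The cropped sample.
#' @export
random_sample_crop <- function(s, min_ious = c(0.1, 0.3, 0.5, 0.7, 0.9),
                               params = NULL) {
  stopifnot(s$coord_mode == "absolute")
  h <- dim(s$rgb)[1]; w <- dim(s$rgb)[2]
  apply_crop <- function(s, rx, ry, rw, rh) {
    keep <- integer(0)
    if (nrow(s$boxes) > 0) {
      cx <- (s$boxes[, 1] + s$boxes[, 3]) / 2
      cy <- (s$boxes[, 2] + s$boxes[, 4]) / 2
      keep <- which(cx > rx & cx < rx + rw & cy > ry & cy < ry + rh)
    }
    s$rgb <- s$rgb[ry + seq_len(rh), rx + seq_len(rw), , drop = FALSE]
    s$depth <- s$depth[ry + seq_len(rh), rx + seq_len(rw), drop = FALSE]
    b <- s$boxes[keep, , drop = FALSE]
    if (nrow(b) > 0) {
      b[, c(1, 3)] <- pmin(pmax(b[, c(1, 3)] - rx, 0), rw)
      b[, c(2, 4)] <- pmin(pmax(b[, c(2, 4)] - ry, 0), rh)
    }
    s$boxes <- b
    s$labels <- s$labels[keep]
    s
  }
  if (!is.null(params)) {
    if (identical(params$mode, "none")) return(s)
    return(apply_crop(s, params$x, params$y, params$w, params$h))
  }
  mode <- sample(length(min_ious) + 2L, 1L)
  if (mode == 1L) return(s)                       # no-crop
  min_iou <- if (mode == length(min_ious) + 2L) 0 else min_ious[mode - 1L]
  for (trial in seq_len(50L)) {
    rw <- floor(stats::runif(1, 0.3, 1) * w)
    rh <- floor(stats::runif(1, 0.3, 1) * h)
    if (rw / rh < 0.5 || rw / rh > 2) next
    rx <- floor(stats::runif(1, 0, w - rw + 1))
    ry <- floor(stats::runif(1, 0, h - rh + 1))
    if (nrow(s$boxes) > 0) {
      cxs <- (s$boxes[, 1] + s$boxes[, 3]) / 2
      cys <- (s$boxes[, 2] + s$boxes[, 4]) / 2
      inside <- cxs > rx & cxs < rx + rw & cys > ry & cys < ry + rh
      if (!any(inside)) next
      crop_box <- c(rx, ry, rx + rw, ry + rh)
      ovs <- iou_matrix(crop_box, s$boxes[inside, , drop = FALSE])[1L, ]
      if (any(ovs < min_iou)) next
    }
    return(apply_crop(s, rx, ry, rw, rh))
  }
  s                                               # fallback: no-crop
}

#' RandomMirror: horizontal flip of both channels
#'
#' @param s A sample in absolute coordinates.
#' @param params Optional list `flip` (logical) to force the outcome;
#'   sampled with probability `p` otherwise.
#' @param p Flip probability, default 0.5.
#' @return The (possibly) mirrored sample.
#' @export
random_mirror <- function(s, params = NULL, p = 0.5) {
  flip <- if (is.null(params)) stats::runif(1) < p else isTRUE(params$flip)
  if (!flip) return(s)
  w <- dim(s$rgb)[2]
  s$rgb <- s$rgb[, w:1, , drop = FALSE]
  s$depth <- s$depth[, w:1, drop = FALSE]
  if (nrow(s$boxes) > 0) {
    x1 <- w - s$boxes[, 3]
    x2 <- w - s$boxes[, 1]
    s$boxes[, 1] <- x1; s$boxes[, 3] <- x2
  }
  s
}

#' ToPercentCoords: normalise boxes by the image size
#'
#' @param s A sample in absolute coordinates.
#' @return The sample with fractional boxes and `coord_mode = "percent"`.
#' @export
to_percent_coords <- function(s) {
  stopifnot(s$coord_mode == "absolute")
  h <- dim(s$rgb)[1]; w <- dim(s$rgb)[2]
  if (nrow(s$boxes) > 0)
    s$boxes <- s$boxes / rep(c(w, h, w, h), each = nrow(s$boxes))
  s$coord_mode <- "percent"
  s
}

#' Resize: bilinear resize of both channels to a square target
#'
#' Percent-coordinate boxes are scale-free and unchanged; absolute boxes are
#' rescaled.
#'
#' @param s A sample.
#' @param size Target side in pixels, default 300.
#' @return The resized sample.
#' @export
resize_sample <- function(s, size = 300) {
  h <- dim(s$rgb)[1]; w <- dim(s$rgb)[2]
  s$rgb <- .resize_bilinear(s$rgb, size, size)
  s$depth <- .resize_bilinear(as_cube(s$depth), size, size)[, , 1L]
  if (s$coord_mode == "absolute" && nrow(s$boxes) > 0) {
    s$boxes[, c(1, 3)] <- s$boxes[, c(1, 3)] * size / w
    s$boxes[, c(2, 4)] <- s$boxes[, c(2, 4)] * size / h
  }
  s
}

#' SubtractMeans: channel-mean normalisation
#'
#' Depth is first scaled to `[0, 1]` by the configured depth range, then a
#' single depth mean is subtracted; the three colour channels each lose
#' their configured mean.
#'
#' @param s A sample.
#' @param rgb_means Length-3 colour means (0-255 scale); default: the
#'   sample's own channel means.
#' @param depth_mean Depth mean on the 0-1 scale; default: the sample's own
#'   mean after range scaling.
#' @param depth_range Near/far millimetres used for depth scaling.
#' @return The normalised sample (`normalized = TRUE`).
#' @export
subtract_means <- function(s, rgb_means = NULL, depth_mean = NULL,
                           depth_range = c(500, 4500)) {
  if (is.null(rgb_means)) rgb_means <- apply(s$rgb, 3L, mean)
  d01 <- (s$depth - depth_range[1]) / (depth_range[2] - depth_range[1])
  d01 <- pmin(pmax(d01, 0), 1)
  if (is.null(depth_mean)) depth_mean <- mean(d01)
  for (ch in 1:3) s$rgb[, , ch] <- s$rgb[, , ch] - rgb_means[ch]
  s$depth <- d01 - depth_mean
  s$normalized <- TRUE
  s
}

#' The full eight-stage augmentation pipeline
#'
#' Composes ToSensor, PhotometricDistort, Expand, RandomSampleCrop,
#' RandomMirror, ToPercentCoords, Resize and SubtractMeans in that order.
#' The output is always a `size` x `size` pair with percent-coordinate boxes
#' in `[0, 1]` and one label per surviving box.
#'
#' @param s A sample from [as_sample()].
#' @param config Augmentation config (see [default_config()]`$augment`);
#'   `rgb_means`/`depth_mean` may be `NULL` to use per-sample means.
#' @param depth_range Near/far millimetres for depth scaling.
#' @param params Optional per-stage forced parameters (lists `photometric`,
#'   `expand`, `crop`, `mirror`) for deterministic replay; a stage with
#'   forced identity parameters is a no-op.
#' @return The augmented, normalised sample.
#' @export
augment <- function(s, config = default_config()$augment,
                    depth_range = c(500, 4500), params = list()) {
  s <- to_sensor(s)
  s <- photometric_distort(s, params$photometric)
  s <- expand(s, config$expand_max_ratio, params$expand)
  s <- random_sample_crop(s, config$crop_min_ious, params$crop)
  s <- random_mirror(s, params$mirror, p = config$mirror_prob)
  s <- to_percent_coords(s)
  s <- resize_sample(s, config$size)
  s <- subtract_means(s, config$rgb_means, config$depth_mean, depth_range)
  # guard: drop degenerate boxes (can arise from clipping at crop borders)
  if (nrow(s$boxes) > 0) {
    ok <- s$boxes[, 3] > s$boxes[, 1] & s$boxes[, 4] > s$boxes[, 2]
    s$boxes <- s$boxes[ok, , drop = FALSE]
    s$labels <- s$labels[ok]
  }
  s
}

#' Materialise k augmented copies of each scene
#'
#' Dataset-expansion reading of the pipeline: returns `k` independently
#' augmented versions per input scene.
#'
#' @param scenes List of `rgbd_scene` objects.
#' @param k Copies per scene.
#' @param config,depth_range Passed to [augment()].
#' @return A flat list of augmented samples.
#' @export
expand_dataset <- function(scenes, k, config = default_config()$augment,
                           depth_range = c(500, 4500)) {
  out <- list()
  for (sc in scenes)
    for (i in seq_len(k))
      out[[length(out) + 1L]] <- augment(as_sample(sc), config, depth_range)
  out
}
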