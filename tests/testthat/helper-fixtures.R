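# Shared fixtures, built in code. Small canvases keep the unit tests fast;
# the acceptance smoke test uses full-size Kinect-style scenes.

tiny_config <- function(...) {
  args <- list(image_width = 96, image_height = 80,
               n_fruits = c(2L, 3L), fruit_radius = c(8, 16))
  user <- list(...)
  args[names(user)] <- user
  do.call(scene_config, args)
}

tiny_scene <- function(seed = 11, ...) generate_scene(tiny_config(...), seed)

# independent rasterization oracle for IoU: count pixels of a fine grid
# falling inside each box and in both
iou_raster_oracle <- function(a, b, n = 220L) {
  lo <- pmin(a[c(1, 2)], b[c(1, 2)])
  hi <- pmax(a[c(3, 4)], b[c(3, 4)])
  xs <- seq(lo[1], hi[1], length.out = n)
  ys <- seq(lo[2], hi[2], length.out = n)
  gx <- rep(xs, times = n); gy <- rep(ys, each = n)
  ina <- gx >= a[1] & gx <= a[3] & gy >= a[2] & gy <= a[4]
  inb <- gx >= b[1] & gx <= b[3] & gy >= b[2] & gy <= b[4]
  sum(ina & inb) / sum(ina | inb)
}

# independent straight-line greedy NMS reimplementation
nms_oracle <- function(boxes, scores, thr, top_k = Inf) {
  ord <- order(-scores, seq_along(scores))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) >= top_k) break
    ok <- TRUE
    for (j in kept) {
      if (iou(boxes[i, ], boxes[j, ]) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

random_boxes <- function(n, scale = 1) {
  x1 <- runif(n, 0, 0.7 * scale); y1 <- runif(n, 0, 0.7 * scale)
  cbind(x1, y1, x1 + runif(n, 0.05, 0.3) * scale,
        y1 + runif(n, 0.05, 0.3) * scale)
}
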