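abs_sample <- function(seed = 11) as_sample(tiny_scene(seed))

test_that("photometric distortion touches colour only, clipped to range", {
  s <- abs_sample()
  set.seed(1)
  out <- photometric_distort(s)
  expect_identical(out$depth, s$depth)
  expect_identical(out$boxes, s$boxes)
  expect_true(all(out$rgb >= 0 & out$rgb <= 255))
  # zero-magnitude jitter is the identity
  id <- photometric_distort(s, params = list(brightness = 0, contrast = 1,
                                             saturation = 1, hue = 0))
  expect_equal(id$rgb, s$rgb, tolerance = 1e-9)
})

test_that("expand pastes both channels and translates boxes", {
  s <- abs_sample()
  # ratio 1, offset (0,0) is the identity
  id <- expand(s, params = list(ratio = 1, ox = 0L, oy = 0L))
  expect_equal(id$rgb, s$rgb)
  expect_equal(id$boxes, s$boxes)
  out <- expand(s, params = list(ratio = 2.5, ox = 40L, oy = 17L))
  h <- dim(s$rgb)[1]; w <- dim(s$rgb)[2]
  expect_equal(dim(out$rgb)[1:2], floor(c(h, w) * 2.5))
  # boxes shifted by the offset
  expect_equal(out$boxes,
               s$boxes + rep(c(40, 17, 40, 17), each = nrow(s$boxes)))
  # cropping the canvas back recovers the originals exactly
  expect_equal(out$rgb[17 + seq_len(h), 40 + seq_len(w), ], s$rgb)
  expect_equal(out$depth[17 + seq_len(h), 40 + seq_len(w)], s$depth)
  # depth fill is the far value
  expect_equal(out$depth[1, 1], max(s$depth))
  expect_error(expand(s, max_ratio = 0.5), "max_ratio")
})

test_that("random crops obey the centre rule and the minimum IoU", {
  s <- abs_sample()
  id <- random_sample_crop(s, params = list(mode = "none"))
  expect_equal(id$rgb, s$rgb)
  # forced crop: boxes with centres outside are dropped, rest clipped
  out <- random_sample_crop(s, params = list(x = 10L, y = 5L, w = 50L,
                                             h = 40L))
  cx <- (s$boxes[, 1] + s$boxes[, 3]) / 2
  cy <- (s$boxes[, 2] + s$boxes[, 4]) / 2
  inside <- cx > 10 & cx < 60 & cy > 5 & cy < 45
  expect_equal(nrow(out$boxes), sum(inside))
  expect_equal(out$labels, s$labels[inside])
  if (nrow(out$boxes) > 0) {
    expect_true(all(out$boxes[, c(1, 3)] >= 0 & out$boxes[, c(1, 3)] <= 50))
    expect_true(all(out$boxes[, c(2, 4)] >= 0 & out$boxes[, c(2, 4)] <= 40))
  }
  expect_equal(dim(out$rgb)[1:2], c(40, 50))
  expect_equal(dim(out$depth), c(40, 50))
  # sampled crops satisfy IoU(crop, box) >= sampled minimum for survivors;
  # exercised indirectly: any surviving box must overlap the crop window
  set.seed(9)
  for (rep in 1:20) {
    out <- random_sample_crop(s)
    expect_true(nrow(out$boxes) == nrow(s$boxes) || nrow(out$boxes) >= 1)
    if (nrow(out$boxes) > 0)
      expect_true(all(out$boxes[, 3] > out$boxes[, 1] &
                        out$boxes[, 4] > out$boxes[, 2]))
  }
})

test_that("mirroring is an involution that reflects x-coordinates", {
  s <- abs_sample()
  w <- dim(s$rgb)[2]
  once <- random_mirror(s, params = list(flip = TRUE))
  twice <- random_mirror(once, params = list(flip = TRUE))
  expect_equal(twice$rgb, s$rgb)
  expect_equal(twice$depth, s$depth)
  expect_equal(twice$boxes, s$boxes)
  # reflection formula and width preservation
  expect_equal(once$boxes[, 1], w - s$boxes[, 3])
  expect_equal(once$boxes[, 3] - once$boxes[, 1],
               s$boxes[, 3] - s$boxes[, 1])
  skip_if(nrow(s$boxes) == 0)
})

test_that("percent coordinates are scale-free under resize", {
  s <- abs_sample()
  p <- to_percent_coords(s)
  expect_true(all(p$boxes >= 0 & p$boxes <= 1))
  r <- resize_sample(p, 300)
  expect_equal(r$boxes, p$boxes)
  expect_equal(dim(r$rgb), c(300, 300, 3))
  expect_equal(dim(r$depth), c(300, 300))
})

test_that("mean subtraction is invertible and scales depth to [0,1]", {
  s <- abs_sample()
  rng <- c(500, 4500)
  out <- subtract_means(s, rgb_means = c(100, 110, 90), depth_mean = 0.4,
                        depth_range = rng)
  back <- out$rgb
  for (ch in 1:3) back[, , ch] <- back[, , ch] + c(100, 110, 90)[ch]
  expect_equal(back, s$rgb)
  expect_true(all(out$depth >= -0.4 & out$depth <= 0.6))
})

test_that("the composed pipeline yields 300x300 percent-coordinate output", {
  s <- abs_sample()
  # all stochastic stages forced to identity: deterministic normalise+resize
  idp <- list(photometric = list(brightness = 0, contrast = 1,
                                 saturation = 1, hue = 0),
              expand = list(ratio = 1, ox = 0L, oy = 0L),
              crop = list(mode = "none"), mirror = list(flip = FALSE))
  cfg <- default_config()$augment
  cfg$rgb_means <- c(0, 0, 0); cfg$depth_mean <- 0
  out <- augment(s, cfg, params = idp)
  ref <- resize_sample(to_percent_coords(to_sensor(abs_sample())), 300)
  expect_equal(out$rgb, ref$rgb, tolerance = 1e-9)
  expect_equal(out$boxes, ref$boxes)
  # stochastic runs keep the contracts: size, box range, label pairing
  set.seed(10)
  for (rep in 1:10) {
    out <- augment(abs_sample(), cfg)
    expect_equal(dim(out$rgb), c(300, 300, 3))
    expect_equal(dim(out$depth), c(300, 300))
    expect_equal(nrow(out$boxes), length(out$labels))
    if (nrow(out$boxes) > 0) {
      expect_true(all(out$boxes >= 0 & out$boxes <= 1))
      expect_true(all(out$boxes[, 3] > out$boxes[, 1]))
    }
  }
})

test_that("geometric stages keep colour and depth in lockstep", {
  # depth encodes object identity on synthetic scenes: after any geometric
  # stage, the same pixels move in both channels
  s <- abs_sample()
  out <- expand(s, params = list(ratio = 1.8, ox = 11L, oy = 23L))
  out <- random_sample_crop(out, params = list(x = 5L, y = 8L, w = 80L,
                                               h = 70L))
  out <- random_mirror(out, params = list(flip = TRUE))
  # apply the same transforms to an index grid stored as depth
  s2 <- s
  s2$depth <- matrix(seq_along(s$depth), nrow(s$depth))
  ref <- expand(s2, params = list(ratio = 1.8, ox = 11L, oy = 23L),
                depth_fill = -1)
  ref <- random_sample_crop(ref, params = list(x = 5L, y = 8L, w = 80L,
                                               h = 70L))
  ref <- random_mirror(ref, params = list(flip = TRUE))
  moved <- ref$depth > 0
  expect_equal(out$depth[moved], s$depth[ref$depth[moved]])
})

test_that("dataset expansion materialises k copies per scene", {
  scenes <- list(tiny_scene(1), tiny_scene(2))
  cfg <- default_config()$augment
  set.seed(3)
  out <- expand_dataset(scenes, 3, cfg)
  expect_length(out, 6L)
  for (s in out) expect_equal(dim(s$rgb), c(300, 300, 3))
})
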