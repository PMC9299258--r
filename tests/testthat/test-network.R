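# Desk-scale network tests use a narrow width multiplier; spatial geometry
# is width-independent.

test_that("both branches produce the six-level pyramid at any width", {
  set.seed(2)
  br_rgb <- build_branch(3L, 1 / 32, seed = 2)
  br_dep <- build_branch(1L, 1 / 32, seed = 3)
  x <- array(rnorm(300 * 300 * 3), c(300, 300, 3))
  d <- matrix(rnorm(300 * 300), 300, 300)
  pr <- feature_pyramid(br_rgb, x)
  pd <- feature_pyramid(br_dep, d)
  expect_equal(vapply(pr$maps, function(m) dim(m)[1], numeric(1)),
               c(38, 19, 10, 5, 3, 1))
  expect_equal(vapply(pd$maps, function(m) dim(m)[2], numeric(1)),
               c(38, 19, 10, 5, 3, 1))
  # wider branch: same spatial sizes, more channels
  br_wide <- build_branch(3L, 1 / 16, seed = 2)
  pw <- feature_pyramid(br_wide, x)
  expect_equal(vapply(pw$maps, function(m) dim(m)[1], numeric(1)),
               c(38, 19, 10, 5, 3, 1))
  expect_true(all(vapply(pw$maps, function(m) dim(m)[3], numeric(1)) >=
                    vapply(pr$maps, function(m) dim(m)[3], numeric(1))))
  expect_error(build_branch(2L), "in_channels")
  expect_error(feature_pyramid(br_rgb, d), "channels")
})

test_that("receptive fields follow the dilation arithmetic", {
  expect_equal(receptive_field(list(c(3, 1, 1), c(3, 1, 1))), 5)
  expect_equal(receptive_field(list(c(3, 1, 1), c(3, 1, 2))), 7)
  expect_equal(receptive_field(list(c(1, 1, 1))), 1)
  expect_equal(receptive_field(list(c(3, 2, 1), c(3, 1, 1))), 7)
  # empirical cross-check: gradient support of a small random conv stack
  probe <- function(specs, n = 19L) {
    layers <- list()
    cin <- 1L
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      layers[[i]] <- nn_conv(paste0("p", i), cin, 1L, k = s[1],
                             stride = s[2], pad = s[1] %/% 2 * s[3],
                             dil = s[3], act = "none")
      cin <- 1L
    }
    params <- with_seed(1, nn_init_params(layers))
    for (nm in names(params)) params[[nm]] <- abs(params[[nm]]) + 0.1
    x <- array(1, c(n, n, 1))
    fw <- nn_forward(layers, params, x)
    mid <- (dim(fw$y)[1] + 1) %/% 2
    gy <- fw$y * 0; gy[mid, mid, 1] <- 1
    gx <- nn_backward(layers, params, fw$caches, gy)$gx
    support <- which(abs(gx[, , 1]) > 1e-12, arr.ind = TRUE)
    max(support[, 1]) - min(support[, 1]) + 1L
  }
  expect_equal(probe(list(c(3, 1, 1), c(3, 1, 1))),
               receptive_field(list(c(3, 1, 1), c(3, 1, 1))))
  expect_equal(probe(list(c(3, 1, 1), c(3, 1, 2))),
               receptive_field(list(c(3, 1, 1), c(3, 1, 2))))
})

test_that("the inception block preserves shape and concatenates widths", {
  spec <- inception_block_spec("inc", 12L, dilation = 2L)
  x <- array(rnorm(9 * 9 * 12), c(9, 9, 12))
  y <- inception_block(x, spec, seed = 4)
  expect_equal(dim(y)[1:2], c(9, 9))
  widths <- vapply(spec$branches, function(br) br[[length(br)]]$cout,
                   integer(1))
  expect_equal(dim(y)[3], sum(widths))
  expect_equal(dim(y)[3], 12L)
  # the factorized 1x3 -> 3x1 path has receptive field 3, like a full 3x3
  expect_equal(receptive_field(list(c(3, 1, 1))), 3)
  # a model built with inception extras still emits the exact prior count
  m <- rdssd_model("rgb", 1 / 32, use_inception = TRUE, seed = 5)
  det <- rd_ssd_forward(m, rgb = array(rnorm(300 * 300 * 3),
                                       c(300, 300, 3)))
  expect_equal(nrow(det$loc), 8732)
  expect_true(all(is.finite(det$conf)))
})

test_that("head flattening matches the prior order (marker round-trip)", {
  # inject a one-hot spatial marker and locate it in the flat output
  for (trial in list(c(h = 3, w = 4, k = 6), c(h = 5, w = 5, k = 4))) {
    hh <- trial["h"]; ww <- trial["w"]; k <- trial["k"]
    y <- array(0, c(hh, ww, k * 4))
    cell_r <- 2L; cell_c <- 3L; box_j <- 2L; comp <- 3L
    y[cell_r, cell_c, (box_j - 1L) * 4L + comp] <- 1
    fl <- flatten_head(y, k, 4L)
    # priors enumerate cells column-major: cell = (col-1)*H + row
    cell <- (cell_c - 1L) * hh + cell_r
    expect_equal(which(rowSums(abs(fl)) > 0),
                 as.integer((cell - 1L) * k + box_j))
    expect_equal(which(colSums(abs(fl)) > 0), as.integer(comp))
    expect_equal(unflatten_head(fl, hh, ww, k, 4L), y)
  }
})

test_that("the fused forward pass emits one row per fused prior", {
  m <- rdssd_model("fused", 1 / 32, seed = 6)
  rgb <- array(0, c(300, 300, 3))
  dep <- matrix(0, 300, 300)
  det <- rd_ssd_forward(m, rgb, dep)
  expect_equal(nrow(det$loc), 17464)
  expect_equal(nrow(det$conf), 17464)
  expect_equal(ncol(det$conf), 7L)
  expect_true(all(is.finite(det$loc)) && all(is.finite(det$conf)))
  # fused rows are (colour, depth) in order: the first 8732 rows equal the
  # rgb-only model's output under identical parameters
  m_rgb <- m
  m_rgb$mode <- "rgb"
  m_rgb$branches <- m$branches["rgb"]
  m_rgb$heads <- m$heads["rgb"]
  m_rgb$priors$active <- m$priors$rgb
  det_r <- rd_ssd_forward(m_rgb, rgb = rgb)
  expect_equal(det$loc[1:8732, ], det_r$loc)
  expect_error(rd_ssd_forward(m, rgb = rgb), "missing depth")
  expect_error(rd_ssd_forward(m, rgb = array(0, c(200, 200, 3)),
                              depth = dep), "300")
})

test_that("backpropagated parameter gradients match finite differences", {
  # full-model gradient check on a miniature geometry: single 10x10 input
  # through a 2-spec prior layout would need a custom model, so instead
  # check through the real model at one parameter per segment depth
  m <- rdssd_model("rgb", 1 / 64, seed = 7)
  set.seed(7)
  rgb <- array(rnorm(300 * 300 * 3, sd = 0.5), c(300, 300, 3))
  pri <- m$priors$active
  gt <- matrix(c(0.3, 0.3, 0.6, 0.6), 1)
  mt <- match_priors(pri, gt, 2L)
  loss_of <- function(params) {
    det <- rd_ssd_forward(m, rgb = rgb, params = params)
    multibox_loss(det$conf, det$loc, mt)$F_loss
  }
  det <- rd_ssd_forward(m, rgb = rgb, keep_caches = TRUE)
  mbl <- multibox_loss_grad(det$conf, det$loc, mt)
  gr <- rd_ssd_backward(m, det$state, mbl$gloc, mbl$gconf)
  eps <- 1e-5
  for (nm in c("r.conv4_3.W", "r.conv7.b", "r.loc1.W", "r.conf3.W",
               "r.conv11_2.W")) {
    p <- m$params[[nm]]
    i <- with_seed(8, sample(length(p), 1))
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_lt(abs(gr[[nm]][i] - num), 1e-4 * max(1, abs(num)))
  }
})
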