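test_that("the convolutional LSTM step matches scalar hand computation", {
  # zero weights: gates 0.5, cell and output 0
  p0 <- make_lstm_params(1, 1)
  for (nm in names(p0)) p0[[nm]][] <- 0
  z <- array(0, c(3, 3, 1))
  st <- lstm_step(array(1, c(3, 3, 1)), z, z, p0)
  expect_equal(unique(as.vector(st$i)), 0.5)
  expect_equal(unique(as.vector(st$f)), 0.5)
  expect_equal(unique(as.vector(st$o)), 0.5)
  expect_equal(max(abs(st$C)), 0)
  expect_equal(max(abs(st$H)), 0)
  # scalar case: 1x1 maps, conv kernels with only the centre tap = 1,
  # peepholes and biases 1; X = 1, H_prev = 0, C_prev = 0
  p1 <- make_lstm_params(1, 1)
  for (nm in names(p1)) {
    p1[[nm]][] <- 0
    if (grepl("\\.W[xh]", nm)) p1[[nm]][1, 5] <- 1   # centre of 3x3
    if (grepl("\\.Wc|\\.b", nm)) p1[[nm]][] <- 1
  }
  one <- array(1, c(1, 1, 1)); zero <- array(0, c(1, 1, 1))
  st <- lstm_step(one, zero, zero, p1)
  sig <- function(x) 1 / (1 + exp(-x))
  i_ref <- sig(1 * 1 + 0 + 1 * 0 + 1)        # Wxi X + Whi H + Wci C + bi
  f_ref <- sig(1 + 0 + 0 + 1)
  g_ref <- tanh(1 + 0 + 1)
  C_ref <- f_ref * 0 + i_ref * g_ref
  o_ref <- sig(1 + 0 + 1 * C_ref + 1)
  H_ref <- o_ref * tanh(C_ref)
  expect_equal(as.vector(st$i), i_ref, tolerance = 1e-12)
  expect_equal(as.vector(st$C), C_ref, tolerance = 1e-12)
  expect_equal(as.vector(st$H), H_ref, tolerance = 1e-12)
  # boundedness: gates in (0,1), cell bounded by |C_prev| + 1
  set.seed(61)
  pr <- make_lstm_params(2, 3)
  X <- array(rnorm(5 * 5 * 2, sd = 2), c(5, 5, 2))
  Hp <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  Cp <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  st <- lstm_step(X, Hp, Cp, pr)
  expect_true(all(st$i > 0 & st$i < 1))
  expect_true(all(st$f > 0 & st$f < 1))
  expect_true(all(abs(st$C) <= abs(Cp) + 1 + 1e-12))
  expect_error(lstm_step(X, Hp, Cp[, , 1:2], pr), "mismatch")
})

test_that("beta weights follow the geometric closed form", {
  expect_equal(beta_weights(3), c(0.125, 0.25, 0.5))
  for (n in 1:8) {
    b <- beta_weights(n)
    expect_equal(b[n], 0.5)
    expect_equal(sum(b), 1 - 0.5^n)
  }
})

test_that("the mask loss is the beta-weighted MSE sum", {
  m1 <- matrix(0.5, 4, 4); m2 <- matrix(0.5, 4, 4)
  truth <- matrix(0.5, 4, 4)
  expect_equal(mask_loss(list(m1, m2), truth), 0)
  # N = 2 with per-block MSEs (1, 2): 0.25 * 1 + 0.5 * 2 = 1.25
  t0 <- matrix(0, 2, 2)
  ma <- matrix(1, 2, 2)                 # MSE 1
  mb <- matrix(sqrt(2), 2, 2)           # MSE 2
  expect_equal(mask_loss(list(ma, mb), t0), 1.25)
  # truths are downsampled to each block's resolution when needed
  big <- matrix(runif(64), 8, 8)
  expect_gte(mask_loss(list(matrix(0.5, 4, 4)), big), 0)
})

test_that("perceptual loss is a symmetric MSE with quadratic scaling", {
  feat <- make_feature_extractor(seed = 9)
  a <- array(runif(16 * 16 * 3), c(16, 16, 3))
  b <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(perceptual_loss(a, a, feat), 0)
  expect_equal(perceptual_loss(a, b, feat), perceptual_loss(b, a, feat))
  # scaling the features by s scales the loss by s^2
  feat2 <- function(img) feat(img) * 3
  expect_equal(perceptual_loss(a, b, feat2),
               9 * perceptual_loss(a, b, feat), tolerance = 1e-12)
})

test_that("the adversarial loss takes its textbook values", {
  expect_equal(adversarial_loss(1, 0), 0)
  expect_equal(adversarial_loss(0.5, 0.5), 2 * log(0.5))
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(0.2, 0.3, -0.1), 0.4)
})

test_that("the attention recurrence starts at 0.5 and stays in [0,1]", {
  gen <- list(params = make_hrgan_params(4, seed = 3), channels = 4)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  # the initial map is the constant 0.5 (checked through a zeroed mask head:
  # with zero weights every sigmoid output is exactly 0.5 too)
  masks <- attention_recurrence(img, gen, n_steps = 3)
  expect_length(masks, 3L)
  for (m in masks) expect_true(all(m >= 0 & m <= 1))
  # first block consumes the 0.5 initial map: verify via the generator
  # forward's input construction
  ly <- hrgan_layers(4)
  fw <- generator_forward(gen$params$g, ly, img, 1, 4, keep = TRUE)
  expect_equal(unique(as.vector(fw$steps[[1]]$fin$caches[[1]]$x[, , 4])),
               0.5)
})

test_that("checkpoints restore identical generator outputs", {
  pairs <- make_highlight_pairs(4, size = 24, seed = 5)
  fit <- hrgan_fit(pairs, steps = 3,
                   config = list(n_blocks = 2L, channels = 4L,
                                 image_size = 24L, lr = 2e-3,
                                 batch_size = 2L),
                   seed = 5)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  fit2 <- load_checkpoint(f)
  out1 <- predict(fit, pairs[[1]]$highlight)
  out2 <- predict(fit2, pairs[[1]]$highlight)
  expect_identical(out1[[1]]$output, out2[[1]]$output)
  expect_true(all(out1[[1]]$output >= 0 & out1[[1]]$output <= 1))
  expect_error(hrgan_fit(list(), steps = 1), "empty")
})
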