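# Highlight-removal GAN: a recurrent-attention generator whose convolutional
# LSTM refines a specular-intensity mask over N recursive blocks, a removal
# head producing the highlight-free image, a small discriminator, and the
# loss stack (weighted recurrent mask MSE + perceptual MSE + adversarial).
# Images live on the [0, 1] scale throughout this module.

conv3f <- function(x, W) .conv_fwd(as_cube(x), W, numeric(nrow(W)),
                                   3L, 3L, 1L, 1L, 1L, 1L)
conv3b <- function(x, W, g, need_gx = TRUE)
  .conv_bwd(as_cube(x), W, as_cube(g), 3L, 3L, 1L, 1L, 1L, 1L, need_gx)
chan_mul <- function(x, v) x * rep(v, each = dim(x)[1] * dim(x)[2])
chan_sum <- function(x) apply(x, 3L, sum)

#' Convolutional LSTM parameters
#'
#' 3x3 convolutional input/hidden weights, per-channel (Hadamard) peephole
#' weights on the cell state, and per-gate biases.
#'
#' @param cin Input feature channels.
#' @param ch Hidden/cell channels.
#' @param prefix Parameter-name prefix.
#' @return Named parameter list.
#' @export
make_lstm_params <- function(cin, ch, prefix = "g.lstm") {
  conv_w <- function(ci) matrix(stats::rnorm(ch * 9 * ci,
                                             sd = sqrt(1 / (9 * ci))),
                                ch, 9 * ci)
  p <- list()
  for (g in c("i", "f", "c", "o")) {
    p[[paste0(prefix, ".Wx", g)]] <- conv_w(cin)
    p[[paste0(prefix, ".Wh", g)]] <- conv_w(ch)
    p[[paste0(prefix, ".b", g)]] <- numeric(ch)
  }
  for (g in c("i", "f", "o")) p[[paste0(prefix, ".Wc", g)]] <- numeric(ch)
  p
}

#' One convolutional LSTM step with peephole connections
#'
#' The five gate equations: input gate
#' `i = sigma(Wxi*X + Whi*H_prev + Wci (.) C_prev + bi)`, forget gate
#' `f = sigma(Wxf*X + Whf*H_prev + Wcf (.) C_prev + bf)`, cell
#' `C = f (.) C_prev + i (.) tanh(Wxc*X + Whc*H_prev + bc)`, output gate
#' `o = sigma(Wxo*X + Who*H_prev + Wco (.) C + bo)`, and output
#' `H = o (.) tanh(C)`, where `*` is 3x3 convolution and `(.)` the
#' elementwise product (peepholes broadcast per channel).
#'
#' @param X Input features (H x W x Cin).
#' @param H_prev,C_prev Previous hidden state and cell state (H x W x Ch).
#' @param params Parameters from [make_lstm_params()].
#' @param prefix Parameter-name prefix.
#' @return List with `H`, `C`, the gate activations `i`, `f`, `o`, and a
#'   `cache` for backpropagation.
#' @examples
#' p <- make_lstm_params(1, 1)
#' for (nm in names(p)) p[[nm]][] <- 0
#' st <- lstm_step(array(1, c(2, 2, 1)), array(0, c(2, 2, 1)),
#'                 array(0, c(2, 2, 1)), p)
#' unique(as.vector(st$i))  # 0.5
#' @export
lstm_step <- function(X, H_prev, C_prev, params, prefix = "g.lstm") {
  X <- as_cube(X); H_prev <- as_cube(H_prev); C_prev <- as_cube(C_prev)
  if (!all(dim(H_prev) == dim(C_prev)))
    stop("hidden/cell state shape mismatch")
  pn <- function(s) params[[paste0(prefix, ".", s)]]
  badd <- function(x, b) x + rep(b, each = dim(x)[1] * dim(x)[2])
  pre_i <- badd(conv3f(X, pn("Wxi")) + conv3f(H_prev, pn("Whi")) +
                  chan_mul(C_prev, pn("Wci")), pn("bi"))
  i <- sigmoid(pre_i)
  pre_f <- badd(conv3f(X, pn("Wxf")) + conv3f(H_prev, pn("Whf")) +
                  chan_mul(C_prev, pn("Wcf")), pn("bf"))
  f <- sigmoid(pre_f)
  g <- tanh(badd(conv3f(X, pn("Wxc")) + conv3f(H_prev, pn("Whc")),
                 pn("bc")))
  C <- f * C_prev + i * g
  pre_o <- badd(conv3f(X, pn("Wxo")) + conv3f(H_prev, pn("Who")) +
                  chan_mul(C, pn("Wco")), pn("bo"))
  o <- sigmoid(pre_o)
  tC <- tanh(C)
  H <- o * tC
  list(H = H, C = C, i = i, f = f, o = o,
       cache = list(X = X, H_prev = H_prev, C_prev = C_prev, i = i, f = f,
                    g = g, o = o, C = C, tC = tC))
}

# backward through one LSTM step; returns input/state grads and accumulates
# parameter grads
lstm_backward <- function(dH, dC_in, cache, params, prefix = "g.lstm",
                          grads = list()) {
  pn <- function(s) paste0(prefix, ".", s)
  gadd <- function(nm, v)
    grads[[nm]] <<- if (is.null(grads[[nm]])) v else grads[[nm]] + v
  cc <- cache
  do_ <- dH * cc$tC
  dpre_o <- do_ * cc$o * (1 - cc$o)
  dC <- dH * cc$o * (1 - cc$tC^2) + dC_in +
    chan_mul(dpre_o, params[[pn("Wco")]])
  di <- dC * cc$g;      dpre_i <- di * cc$i * (1 - cc$i)
  df <- dC * cc$C_prev; dpre_f <- df * cc$f * (1 - cc$f)
  dg <- dC * cc$i;      dpre_c <- dg * (1 - cc$g^2)
  dC_prev <- dC * cc$f + chan_mul(dpre_i, params[[pn("Wci")]]) +
    chan_mul(dpre_f, params[[pn("Wcf")]])
  gadd(pn("Wci"), chan_sum(dpre_i * cc$C_prev))
  gadd(pn("Wcf"), chan_sum(dpre_f * cc$C_prev))
  gadd(pn("Wco"), chan_sum(dpre_o * cc$C))
  gadd(pn("bi"), chan_sum(dpre_i)); gadd(pn("bf"), chan_sum(dpre_f))
  gadd(pn("bc"), chan_sum(dpre_c)); gadd(pn("bo"), chan_sum(dpre_o))
  dX <- NULL; dHp <- NULL
  for (pair in list(c("Wxi", "i"), c("Wxf", "f"), c("Wxc", "c"),
                    c("Wxo", "o"))) {
    dpre <- switch(pair[2], i = dpre_i, f = dpre_f, c = dpre_c, o = dpre_o)
    r <- conv3b(cc$X, params[[pn(pair[1])]], dpre)
    gadd(pn(pair[1]), r$gw)
    dX <- if (is.null(dX)) r$gx else dX + r$gx
  }
  for (pair in list(c("Whi", "i"), c("Whf", "f"), c("Whc", "c"),
                    c("Who", "o"))) {
    dpre <- switch(pair[2], i = dpre_i, f = dpre_f, c = dpre_c, o = dpre_o)
    r <- conv3b(cc$H_prev, params[[pn(pair[1])]], dpre)
    gadd(pn(pair[1]), r$gw)
    dHp <- if (is.null(dHp)) r$gx else dHp + r$gx
  }
  list(dX = dX, dH_prev = dHp, dC_prev = dC_prev, grads = grads)
}

# ---- generator / discriminator definitions ---------------------------------

hrgan_layers <- function(channels) {
  ch <- as.integer(channels)
  list(
    g_in = list(nn_conv("g.in", 4L, ch)),
    g_res = list(nn_conv("g.res1", ch, ch), nn_conv("g.res2", ch, ch,
                                                    act = "none")),
    g_mask = list(nn_conv("g.mask", ch, 1L, act = "sigmoid")),
    g_removal = list(nn_conv("g.d1", 4L, ch), nn_conv("g.d2", ch, ch),
                     nn_conv("g.out", ch, 3L, act = "sigmoid")),
    d_conv = list(nn_conv("d.c1", 3L, 8L, stride = 2),
                  nn_conv("d.c2", 8L, 16L, stride = 2),
                  nn_conv("d.c3", 16L, 32L, stride = 2)),
    feat = list(nn_conv("feat.c1", 3L, 8L, stride = 2),
                nn_conv("feat.c2", 8L, 8L, stride = 2)))
}

make_hrgan_params <- function(channels, seed) {
  ly <- hrgan_layers(channels)
  with_seed(seed, {
    gp <- c(nn_init_params(c(ly$g_in, ly$g_res, ly$g_mask, ly$g_removal)),
            make_lstm_params(channels, channels))
    dp <- nn_init_params(ly$d_conv)
    dp[["d.w"]] <- stats::rnorm(32L, sd = sqrt(1 / 32))
    dp[["d.b"]] <- 0
    fp <- nn_init_params(ly$feat)
    list(g = gp, d = dp, feat = fp)
  })
}

# full generator forward: N recursive attention blocks then the removal head
generator_forward <- function(params, ly, img, n_blocks, channels,
                              keep = FALSE) {
  img <- as_cube(img)
  hh <- dim(img)[1]; ww <- dim(img)[2]
  M <- matrix(0.5, hh, ww)                      # initial highlight intensity
  Hs <- array(0, c(hh, ww, channels))
  Cs <- array(0, c(hh, ww, channels))
  masks <- vector("list", n_blocks)
  steps <- if (keep) vector("list", n_blocks)
  for (t in seq_len(n_blocks)) {
    inp <- abind3(img, as_cube(M))
    fin <- nn_forward(ly$g_in, params, inp)
    fres <- nn_forward(ly$g_res, params, fin$y)
    X <- fin$y + fres$y                         # residual module output
    st <- lstm_step(X, Hs, Cs, params)
    mh <- nn_forward(ly$g_mask, params, st$H)
    Hs <- st$H; Cs <- st$C
    masks[[t]] <- mh$y[, , 1L]
    if (keep)
      steps[[t]] <- list(fin = fin, fres = fres, lstm = st$cache, mh = mh)
    M <- masks[[t]]
  }
  inp2 <- abind3(img, as_cube(M))
  rem <- nn_forward(ly$g_removal, params, inp2)
  out <- list(masks = masks, output = rem$y)
  if (keep) out <- c(out, list(steps = steps, rem = rem, img = img))
  out
}

# backward through the generator given d(output image) and per-mask grads
generator_backward <- function(params, ly, fw, dout, dmasks, n_blocks) {
  grads <- list()
  br <- nn_backward(ly$g_removal, params, fw$rem$caches, dout, grads)
  grads <- br$grads
  dM <- br$gx[, , 4L]                           # mask channel of removal input
  dH <- NULL; dC <- NULL
  for (t in rev(seq_len(n_blocks))) {
    dMt <- dmasks[[t]]
    if (!is.null(dM)) dMt <- dMt + dM
    st <- fw$steps[[t]]
    bm <- nn_backward(ly$g_mask, params, st$mh$caches, as_cube(dMt), grads)
    grads <- bm$grads
    dHt <- bm$gx
    if (!is.null(dH)) dHt <- dHt + dH
    if (is.null(dC)) dC <- dHt * 0
    lb <- lstm_backward(dHt, dC, st$lstm, params, grads = grads)
    grads <- lb$grads
    dX <- lb$dX
    bres <- nn_backward(ly$g_res, params, st$fres$caches, dX, grads)
    grads <- bres$grads
    bin <- nn_backward(ly$g_in, params, st$fin$caches, dX + bres$gx, grads)
    grads <- bin$grads
    dM <- if (t > 1L) bin$gx[, , 4L] else NULL
    dH <- lb$dH_prev; dC <- lb$dC_prev
  }
  grads
}

disc_forward <- function(params, ly, img, keep = FALSE) {
  r <- nn_forward(ly$d_conv, params, as_cube(img))
  v <- apply(r$y, 3L, mean)
  score <- sigmoid(sum(v * params[["d.w"]]) + params[["d.b"]])
  out <- list(score = score, v = v)
  if (keep) out$caches <- r
  out
}

disc_backward <- function(params, ly, fw, dscore, grads = list(),
                          need_gx = FALSE) {
  D <- fw$score
  dpre <- dscore * D * (1 - D)
  gw <- dpre * fw$v
  grads[["d.w"]] <- if (is.null(grads[["d.w"]])) gw else grads[["d.w"]] + gw
  grads[["d.b"]] <- if (is.null(grads[["d.b"]])) dpre else
    grads[["d.b"]] + dpre
  y <- fw$caches$y
  dfeat <- array(rep(dpre * params[["d.w"]],
                     each = dim(y)[1] * dim(y)[2]) /
                   (dim(y)[1] * dim(y)[2]), dim(y))
  b <- nn_backward(ly$d_conv, params, fw$caches$caches, dfeat, grads,
                   need_input_grad = need_gx)
  list(grads = b$grads, gx = if (need_gx) b$gx)
}

# ---- exported loss operations ----------------------------------------------

#' Recurrent-block supervision weights
#'
#' `beta_i = 0.5^(N - i + 1)`: the final block's mask carries weight 0.5 and
#' earlier blocks are downweighted geometrically; the weights sum to
#' `1 - 0.5^N`.
#'
#' @param n_blocks Number of recursive blocks N.
#' @return Numeric vector of length N.
#' @export
beta_weights <- function(n_blocks) 0.5^(n_blocks - seq_len(n_blocks) + 1)

#' Weighted recurrent mask loss
#'
#' `L_M = sum_i beta_i * MSE(M_i, T_i)` over the recursive attention blocks,
#' with `beta_i = 0.5^(N - i + 1)`. Truths are resized to each mask's
#' resolution when they differ.
#'
#' @param masks List of predicted intensity masks `M_1..M_N`.
#' @param truths Ground-truth intensity mask, or a list of per-block truths.
#' @return The scalar mask loss.
#' @export
mask_loss <- function(masks, truths) {
  n <- length(masks)
  if (!is.list(truths)) truths <- rep(list(truths), n)
  b <- beta_weights(n)
  sum(vapply(seq_len(n), function(i) {
    t_i <- truths[[i]]
    if (!all(dim(rbind(t_i)) == dim(masks[[i]])))
      t_i <- .resize_bilinear(as_cube(t_i), nrow(masks[[i]]),
                              ncol(masks[[i]]))[, , 1L]
    b[i] * mean((masks[[i]] - t_i)^2)
  }, numeric(1)))
}

#' Perceptual loss under an injected feature extractor
#'
#' Mean squared error between fixed-extractor features of the two images.
#' The extractor is injected — typically a frozen convolutional network
#' ([make_feature_extractor()]); no pretrained weights are required.
#'
#' @param pred,truth Images on the same scale.
#' @param feature_fn Function mapping an image to a feature array.
#' @return The scalar perceptual loss.
#' @export
perceptual_loss <- function(pred, truth, feature_fn) {
  mean((feature_fn(pred) - feature_fn(truth))^2)
}

#' Fixed random convolutional feature extractor
#'
#' A small frozen two-layer strided conv net with seeded random weights,
#' standing in for a pretrained backbone as the perceptual-loss feature
#' function.
#'
#' @param seed Seed for the frozen weights.
#' @param channels Unused width hook (fixed at 8).
#' @return A function `image -> feature array`.
#' @export
make_feature_extractor <- function(seed = 99L, channels = 8L) {
  ly <- hrgan_layers(channels)$feat
  params <- with_seed(seed, nn_init_params(ly))
  function(img) nn_forward(ly, params, as_cube(img))$y
}

#' Adversarial loss of the discriminator
#'
#' `L_Adv = E[log D(I_f)] + E[log(1 - D(G(I_h)))]` over a batch: zero for a
#' perfect discriminator and `2 log 0.5` when D outputs 0.5 everywhere. The
#' generator minimises the complement of the second term
#' (`-E[log D(G(I_h))]`, the non-saturating form).
#'
#' @param D_real Discriminator scores on highlight-free images, in (0, 1).
#' @param D_fake Discriminator scores on generated images.
#' @return The scalar adversarial loss.
#' @export
adversarial_loss <- function(D_real, D_fake) {
  eps <- 1e-8
  mean(log(pmax(D_real, eps))) + mean(log(pmax(1 - D_fake, eps)))
}

#' Total highlight-removal loss
#'
#' The unweighted sum `L_T = L_M + L_P + L_Adv`.
#'
#' @param L_M,L_P,L_Adv Component losses.
#' @return Their sum.
#' @export
total_loss <- function(L_M, L_P, L_Adv) L_M + L_P + L_Adv

#' Run the recurrent attention stack of a generator
#'
#' Starting from the constant initial intensity map 0.5, each recursive
#' block consumes the input image concatenated with the previous mask and
#' emits a refined mask in `[0, 1]`.
#'
#' @param image H x W x 3 image on the 0-1 scale.
#' @param generator A fitted `hrgan` object (or a list with `params$g`,
#'   `channels`).
#' @param n_steps Number of recursive blocks to run.
#' @return List of `n_steps` masks.
#' @export
attention_recurrence <- function(image, generator, n_steps) {
  ly <- hrgan_layers(generator$channels)
  generator_forward(generator$params$g, ly, image, n_steps,
                    generator$channels)$masks
}

# ---- training ---------------------------------------------------------------

#' Fit the highlight-removal GAN on paired synthetic data
#'
#' Alternating discriminator/generator updates with Adam. The generator
#' objective combines the recurrent mask loss `L_M`, the perceptual loss
#' `L_P` against the clean image, and the non-saturating adversarial term;
#' the discriminator maximises `L_Adv`. Pairs come from
#' [synthesize_highlights()] (highlight image, clean image, intensity mask).
#'
#' @param pairs List of lists with elements `highlight` (H x W x 3, 0-1),
#'   `clean` (H x W x 3, 0-1) and `mask` (H x W, 0-1).
#' @param steps Training steps.
#' @param config HRGAN configuration, see [default_config()]`$hrgan`.
#' @param seed Integer seed.
#' @param verbose Print progress every 50 steps.
#' @return An object of class `hrgan`: parameters, layer config and the
#'   per-step loss `trace` (`L_M`, `L_P`, `L_Adv`, `L_T`, `L_D`).
#' @export
hrgan_fit <- function(pairs, steps = 200L, config = default_config()$hrgan,
                      seed = 1L, verbose = FALSE) {
  if (length(pairs) == 0L) stop("invalid input: empty training set")
  chn <- config$channels
  nb <- config$n_blocks
  ly <- hrgan_layers(chn)
  params <- make_hrgan_params(chn, seed)
  feat_fn_layers <- ly$feat
  with_seed(seed + 1L, {
    g_opt <- adam_init(params$g)
    d_opt <- adam_init(params$d)
    trace <- vector("list", steps)
    for (step in seq_len(steps)) {
      idx <- sample(length(pairs), min(config$batch_size, length(pairs)))
      fakes <- list()
      l_m <- l_p <- 0
      g_grads <- list()
      d_grads <- list()
      d_real <- d_fake <- numeric(0)
      bsz <- length(idx)
      for (j in seq_along(idx)) {
        pr <- pairs[[idx[j]]]
        fw <- generator_forward(params$g, ly, pr$highlight, nb, chn,
                                keep = TRUE)
        fakes[[j]] <- list(fw = fw, pr = pr)
        # discriminator pass on real and (detached) fake
        fr <- disc_forward(params$d, ly, pr$clean, keep = TRUE)
        ff <- disc_forward(params$d, ly, fw$output, keep = TRUE)
        d_real[j] <- fr$score; d_fake[j] <- ff$score
        # D maximises log D(real) + log(1 - D(fake))
        eps <- 1e-8
        rb <- disc_backward(params$d, ly, fr,
                            -1 / (max(fr$score, eps) * bsz), d_grads)
        d_grads <- rb$grads
        fb <- disc_backward(params$d, ly, ff,
                            1 / (max(1 - ff$score, eps) * bsz), d_grads)
        d_grads <- fb$grads
      }
      res <- adam_step(params$d, d_grads, d_opt, lr = config$lr)
      params$d <- res$params; d_opt <- res$state
      # generator pass against the updated discriminator
      for (j in seq_along(idx)) {
        fw <- fakes[[j]]$fw; pr <- fakes[[j]]$pr
        npx_m <- length(pr$mask)
        b <- beta_weights(nb)
        dmasks <- lapply(seq_len(nb), function(t)
          (2 * b[t] / (npx_m * bsz)) * (fw$masks[[t]] - pr$mask))
        l_m <- l_m + mask_loss(fw$masks, pr$mask) / bsz
        # perceptual term
        fp_pred <- nn_forward(feat_fn_layers, params$feat, fw$output)
        fp_true <- nn_forward(feat_fn_layers, params$feat, pr$clean)
        df <- fp_pred$y - fp_true$y
        l_p <- l_p + mean(df^2) / bsz
        bp <- nn_backward(feat_fn_layers, params$feat, fp_pred$caches,
                          2 * df / (length(df) * bsz))
        dout <- bp$gx
        # non-saturating adversarial term: minimise -log D(fake)
        ff <- disc_forward(params$d, ly, fw$output, keep = TRUE)
        ab <- disc_backward(params$d, ly, ff,
                            -1 / (max(ff$score, 1e-8) * bsz),
                            need_gx = TRUE)
        dout <- dout + ab$gx
        g_grads <- grads_add(g_grads,
                             generator_backward(params$g, ly, fw, dout,
                                                dmasks, nb))
      }
      res <- adam_step(params$g, g_grads, g_opt, lr = config$lr)
      params$g <- res$params; g_opt <- res$state
      l_adv <- adversarial_loss(d_real, d_fake)
      trace[[step]] <- data.frame(step = step, L_M = l_m, L_P = l_p,
                                  L_Adv = l_adv,
                                  L_T = total_loss(l_m, l_p, l_adv),
                                  L_D = -l_adv)
      if (verbose && step %% 50L == 0L)
        message(sprintf("step %d  L_M=%.4f  L_P=%.4f  L_Adv=%.3f", step,
                        l_m, l_p, l_adv))
    }
    structure(list(params = params, channels = chn, n_blocks = nb,
                   config = config, seed = seed,
                   trace = do.call(rbind, trace)),
              class = "hrgan")
  })
}

#' @export
print.hrgan <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("HRGAN highlight remover: %d blocks, %d channels, %d steps\n",
              x$n_blocks, x$channels, nrow(tr)))
  cat(sprintf("  L_M %.4f -> %.4f; L_P %.4f -> %.4f\n", tr$L_M[1],
              tr$L_M[nrow(tr)], tr$L_P[1], tr$L_P[nrow(tr)]))
  invisible(x)
}

#' Remove highlights from images with a fitted HRGAN
#'
#' @param object A fitted `hrgan`.
#' @param newdata List of H x W x 3 images on the 0-1 scale (or a single
#'   image).
#' @param ... Unused.
#' @return List per image with `output` (highlight-free estimate) and
#'   `masks` (the recurrent attention masks).
#' @export
predict.hrgan <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  ly <- hrgan_layers(object$channels)
  lapply(newdata, function(img) {
    fw <- generator_forward(object$params$g, ly, img, object$n_blocks,
                            object$channels)
    list(output = fw$output, masks = fw$masks)
  })
}

#' Build paired highlight training data from synthetic scenes
#'
#' Crops/resizes synthetic scenes to small square patches and applies
#' [synthesize_highlights()], yielding (highlight, clean, mask) triples on
#' the 0-1 scale.
#'
#' @param n_pairs Number of pairs.
#' @param size Patch side in pixels (default 64).
#' @param seed Integer seed.
#' @param n_blobs Highlight blobs per image.
#' @return List of pairs for [hrgan_fit()].
#' @export
make_highlight_pairs <- function(n_pairs, size = 64L, seed = 1L,
                                 n_blobs = 2L) {
  cfg <- scene_config(image_width = size * 2L, image_height = size * 2L,
                      n_fruits = c(1L, 3L),
                      fruit_radius = c(size / 6, size / 3))
  lapply(seq_len(n_pairs), function(i) {
    sc <- generate_scene(cfg, seed + i - 1L)
    rgb <- .resize_bilinear(sc$rgb, size, size)
    hl <- synthesize_highlights(rgb, seed = seed + 10000L + i,
                                n_blobs = n_blobs)
    list(highlight = hl$rgb / 255, clean = rgb / 255, mask = hl$mask)
  })
}
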