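#' @useDynLib rdssd, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- minimal convolutional network engine -----------------------------------
# A "stack" is an ordered list of layer descriptors; parameters live in a flat
# named list so one Adam state can drive an arbitrary collection of stacks.
# Feature maps are H x W x C arrays throughout (see src/nn_ops.cpp).

as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected an H x W x C array")
  storage.mode(x) <- "double"
  x
}

nn_conv <- function(name, cin, cout, k = 3L, stride = 1L, pad = 1L,
                    dil = 1L, act = "relu", kh = k, kw = k, pad_h = pad,
                    pad_w = pad) {
  list(type = "conv", name = name, cin = as.integer(cin),
       cout = as.integer(cout), kh = as.integer(kh), kw = as.integer(kw),
       stride = as.integer(stride), pad_h = as.integer(pad_h),
       pad_w = as.integer(pad_w), dil = as.integer(dil), act = act)
}

nn_pool <- function(k = 2L, stride = k, pad = 0L, ceil = FALSE) {
  list(type = "pool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), ceil = isTRUE(ceil))
}

# He-normal init for the conv stacks; biases zero.
nn_init_params <- function(layers, gain = 2) {
  params <- list()
  for (ly in layers) {
    if (ly$type == "inception") {
      for (br in ly$branches)
        params <- c(params, nn_init_params(br, gain))
    } else if (ly$type == "conv") {
      K <- ly$kh * ly$kw * ly$cin
      params[[paste0(ly$name, ".W")]] <-
        matrix(stats::rnorm(ly$cout * K, sd = sqrt(gain / K)), ly$cout, K)
      params[[paste0(ly$name, ".b")]] <- numeric(ly$cout)
    }
  }
  params
}

nn_act <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         tanh = tanh(x),
         none = x,
         stop("unknown activation: ", act))
}

nn_act_grad <- function(gy, y, act) {
  switch(act,
         relu = gy * (y > 0),
         sigmoid = gy * y * (1 - y),
         tanh = gy * (1 - y^2),
         none = gy,
         stop("unknown activation: ", act))
}

# Forward pass through one stack. Returns the output and per-layer caches
# (inputs and post-activation outputs) needed by nn_backward.
nn_forward <- function(layers, params, x) {
  x <- as_cube(x)
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      W <- params[[paste0(ly$name, ".W")]]
      b <- params[[paste0(ly$name, ".b")]]
      y <- .conv_fwd(x, W, b, ly$kh, ly$kw, ly$stride, ly$pad_h,
                     ly$pad_w, ly$dil)
      y <- nn_act(y, ly$act)
      caches[[i]] <- list(x = x, y = y)
    } else if (ly$type == "inception") {
      subs <- lapply(ly$branches, nn_forward, params = params, x = x)
      y <- do.call(abind3, lapply(subs, `[[`, "y"))
      caches[[i]] <- list(subs = lapply(subs, `[[`, "caches"))
    } else {
      res <- .maxpool_fwd(x, ly$k, ly$stride, ly$pad, ly$ceil)
      y <- res$y
      caches[[i]] <- list(idx = res$idx, h = nrow(x), w = ncol(x))
    }
    x <- y
  }
  list(y = x, caches = caches)
}

# Backward pass; `grads` accumulates into an existing named list so several
# stacks (branches, heads) can share one gradient pool.
nn_backward <- function(layers, params, caches, gy, grads = list(),
                        need_input_grad = TRUE) {
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "conv") {
      gy <- nn_act_grad(gy, cc$y, ly$act)
      W <- params[[paste0(ly$name, ".W")]]
      res <- .conv_bwd(cc$x, W, as_cube(gy), ly$kh, ly$kw, ly$stride,
                       ly$pad_h, ly$pad_w, ly$dil,
                       need_gx = need_input_grad || i > 1L)
      nw <- paste0(ly$name, ".W"); nb <- paste0(ly$name, ".b")
      grads[[nw]] <- if (is.null(grads[[nw]])) res$gw else grads[[nw]] + res$gw
      grads[[nb]] <- if (is.null(grads[[nb]])) res$gb else grads[[nb]] + res$gb
      gy <- res$gx
    } else if (ly$type == "inception") {
      widths <- vapply(ly$branches, function(br) {
        tail_conv <- br[[length(br)]]; tail_conv$cout
      }, integer(1))
      ends <- cumsum(widths)
      gx_sum <- NULL
      for (j in seq_along(ly$branches)) {
        cols <- (ends[j] - widths[j] + 1L):ends[j]
        res <- nn_backward(ly$branches[[j]], params, cc$subs[[j]],
                           gy[, , cols, drop = FALSE], grads)
        grads <- res$grads
        gx_sum <- if (is.null(gx_sum)) res$gx else gx_sum + res$gx
      }
      gy <- gx_sum
    } else {
      gy <- .maxpool_bwd(as_cube(gy), cc$idx, cc$h, cc$w)
    }
  }
  list(gx = gy, grads = grads)
}

# channel-wise concatenation of H x W x C arrays
abind3 <- function(...) {
  xs <- list(...)
  h <- dim(xs[[1]])[1]; w <- dim(xs[[1]])[2]
  array(c(...), c(h, w, sum(vapply(xs, function(x) dim(x)[3], numeric(1)))))
}

grads_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Numerical utilities shared by the loss modules.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
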