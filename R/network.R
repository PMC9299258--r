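# Dual-branch detector: VGG16-style SSD trunks for the colour (3-channel)
# and depth (1-channel) inputs, six-level feature pyramids with spatial
# sizes 38, 19, 10, 5, 3, 1 for a 300x300 input, per-layer 3x3 detection
# heads, and decision-level fusion of the two prediction lists.

ch <- function(base, wm) max(1L, as.integer(round(base * wm)))

# the six trunk segments; each segment ends at one pyramid tap
branch_segments <- function(in_channels, wm, prefix, use_inception = FALSE) {
  cv <- function(nm, cin, cout, ...) nn_conv(paste0(prefix, ".", nm),
                                             cin, cout, ...)
  c64 <- ch(64, wm); c128 <- ch(128, wm); c256 <- ch(256, wm)
  c512 <- ch(512, wm); c1024 <- ch(1024, wm)
  seg1 <- list(
    cv("conv1_1", in_channels, c64), cv("conv1_2", c64, c64), nn_pool(),
    cv("conv2_1", c64, c128), cv("conv2_2", c128, c128), nn_pool(),
    cv("conv3_1", c128, c256), cv("conv3_2", c256, c256),
    cv("conv3_3", c256, c256), nn_pool(ceil = TRUE),   # 75 -> 38
    cv("conv4_1", c256, c512), cv("conv4_2", c512, c512),
    cv("conv4_3", c512, c512))
  seg2 <- list(
    nn_pool(),                                          # 38 -> 19
    cv("conv5_1", c512, c512), cv("conv5_2", c512, c512),
    cv("conv5_3", c512, c512), nn_pool(3L, 1L, 1L),
    cv("conv6", c512, c1024, k = 3, pad = 6, dil = 6),
    cv("conv7", c1024, c1024, k = 1, pad = 0))
  seg3 <- list(cv("conv8_1", c1024, c256, k = 1, pad = 0),
               cv("conv8_2", c256, c512, stride = 2))   # 19 -> 10
  seg4 <- list(cv("conv9_1", c512, c128, k = 1, pad = 0),
               cv("conv9_2", c128, c256, stride = 2))   # 10 -> 5
  seg5 <- list(cv("conv10_1", c256, c128, k = 1, pad = 0),
               cv("conv10_2", c128, c256, pad = 0))     # 5 -> 3
  seg6 <- list(cv("conv11_1", c256, c128, k = 1, pad = 0),
               cv("conv11_2", c128, c256, pad = 0))     # 3 -> 1
  if (use_inception) {
    seg3 <- c(seg3, list(inception_block_spec(paste0(prefix, ".inc8"),
                                              c512, dilation = 2L)))
    seg4 <- c(seg4, list(inception_block_spec(paste0(prefix, ".inc9"),
                                              c256, dilation = 2L)))
  }
  list(seg1, seg2, seg3, seg4, seg5, seg6)
}

segment_out_channels <- function(segments) {
  vapply(segments, function(seg) {
    for (ly in rev(seg)) {
      if (ly$type == "conv") return(ly$cout)
      if (ly$type == "inception")
        return(sum(vapply(ly$branches,
                          function(br) br[[length(br)]]$cout, integer(1))))
    }
    stop("segment has no convolution")
  }, integer(1))
}

#' Shape-preserving multi-branch (Inception-style) block specification
#'
#' Three parallel paths over the same input: a 1x1 convolution, a factorized
#' 1x3 followed by 3x1 pair (receptive field 3, like a full 3x3), and a 3x3
#' convolution with the given dilation rate (receptive field `2*dilation+1`).
#' Outputs are concatenated channel-wise; padding preserves the spatial size.
#' Total output channels equal the input channels so the block can drop into
#' an existing trunk.
#'
#' @param name Parameter-name prefix.
#' @param cin Input (= output) channel count; split across the three paths.
#' @param dilation Dilation rate of the 3x3 path, 1 or 2.
#' @return An inception layer descriptor usable inside a layer stack.
#' @export
inception_block_spec <- function(name, cin, dilation = 2L) {
  c1 <- max(1L, cin %/% 4L)
  c3 <- max(1L, cin %/% 4L)
  c2 <- cin - c1 - c3
  list(type = "inception", name = name, branches = list(
    list(nn_conv(paste0(name, ".b1"), cin, c1, k = 1, pad = 0)),
    # factorized 1x3 then 3x1: receptive field 3, per-axis padding
    list(nn_conv(paste0(name, ".b2a"), cin, c2, kh = 1L, kw = 3L,
                 pad_h = 0L, pad_w = 1L),
         nn_conv(paste0(name, ".b2b"), c2, c2, kh = 3L, kw = 1L,
                 pad_h = 1L, pad_w = 0L)),
    list(nn_conv(paste0(name, ".b3"), cin, c3, k = 3,
                 pad = as.integer(dilation), dil = as.integer(dilation)))))
}

#' Apply an inception block to a feature map
#'
#' Convenience wrapper: initialises the block's parameters (seeded) on first
#' use unless supplied, runs the forward pass, and returns the concatenated
#' feature map.
#'
#' @param x H x W x C input feature map.
#' @param spec Block descriptor from [inception_block_spec()].
#' @param params Named parameter list; freshly initialised when `NULL`.
#' @param seed Seed for fresh initialisation.
#' @return H x W x C output feature map (same spatial size and width).
#' @export
inception_block <- function(x, spec, params = NULL, seed = 1L) {
  if (is.null(params))
    params <- with_seed(seed, nn_init_params(list(spec)))
  nn_forward(list(spec), params, x)$y
}

#' Analytic receptive field of a convolution stack
#'
#' Applies the standard recurrence: starting from 1 pixel, each layer with
#' kernel `k`, stride `s` and dilation `d` grows the field by
#' `d * (k - 1)` times the product of all preceding strides.
#'
#' @param stack List of `c(kernel, stride, dilation)` triples, in order.
#' @return The receptive-field side length in input pixels.
#' @examples
#' receptive_field(list(c(3, 1, 1), c(3, 1, 1)))  # 5
#' receptive_field(list(c(3, 1, 1), c(3, 1, 2)))  # 7
#' @export
receptive_field <- function(stack) {
  rf <- 1
  jump <- 1
  for (ly in stack) {
    k <- ly[1]; s <- ly[2]; d <- if (length(ly) >= 3) ly[3] else 1
    rf <- rf + d * (k - 1) * jump
    jump <- jump * s
  }
  rf
}

#' Build one feature-extractor branch
#'
#' A VGG16-style trunk (conv1 through conv4_3, the dilated conv6/conv7 pair
#' replacing the fully-connected layers, and the conv8-conv11 extras) whose
#' six taps form the feature pyramid with spatial sizes 38, 19, 10, 5, 3, 1
#' for a 300x300 input. `width_multiplier` scales every channel width for
#' CPU-scale use; the depth branch differs from the colour branch only in
#' its first layer's input channels.
#'
#' @param in_channels 3 (colour) or 1 (depth).
#' @param width_multiplier Positive channel-width scale.
#' @param prefix Parameter-name prefix (default by channel count).
#' @param use_inception Append shape-preserving inception refinement blocks
#'   to the conv8/conv9 extras.
#' @param seed Seed for parameter initialisation.
#' @return An `rdssd_branch`: `segments` (layer stacks), `params`,
#'   `out_channels` per tap.
#' @export
build_branch <- function(in_channels, width_multiplier = 1,
                         prefix = if (in_channels == 1) "d" else "r",
                         use_inception = FALSE, seed = 1L) {
  if (!in_channels %in% c(1L, 3L))
    stop("invalid config: in_channels must be 1 or 3")
  if (width_multiplier <= 0) stop("invalid config: width_multiplier <= 0")
  segments <- branch_segments(in_channels, width_multiplier, prefix,
                              use_inception)
  params <- with_seed(seed, nn_init_params(unlist(segments,
                                                  recursive = FALSE)))
  structure(list(segments = segments, params = params,
                 out_channels = segment_out_channels(segments),
                 prefix = prefix, in_channels = in_channels),
            class = "rdssd_branch")
}

#' Feature pyramid of one branch
#'
#' @param branch An `rdssd_branch` (or a list of segments plus params).
#' @param x Input image array (H x W x C, C matching the branch).
#' @param params Parameter list overriding `branch$params`.
#' @param keep_caches Keep per-layer caches for backpropagation.
#' @return List with `maps` (six feature maps) and optionally `caches`.
#' @export
feature_pyramid <- function(branch, x, params = branch$params,
                            keep_caches = FALSE) {
  x <- as_cube(x)
  if (dim(x)[3] != branch$in_channels)
    stop("input has ", dim(x)[3], " channels; branch expects ",
         branch$in_channels)
  maps <- vector("list", 6L)
  caches <- vector("list", 6L)
  for (i in 1:6) {
    res <- nn_forward(branch$segments[[i]], params, x)
    maps[[i]] <- res$y
    if (keep_caches) caches[[i]] <- res$caches
    x <- res$y
  }
  out <- list(maps = maps)
  if (keep_caches) out$caches <- caches
  out
}

# ---- detection heads --------------------------------------------------------

head_layers <- function(prefix, tap_channels, specs, n_classes = 6L) {
  ks <- vapply(specs, `[[`, integer(1), "boxes_per_location")
  loc <- conf <- vector("list", 6L)
  for (i in 1:6) {
    loc[[i]] <- nn_conv(paste0(prefix, ".loc", i), tap_channels[i],
                        4L * ks[i], act = "none")
    conf[[i]] <- nn_conv(paste0(prefix, ".conf", i), tap_channels[i],
                         (n_classes + 1L) * ks[i], act = "none")
  }
  list(loc = loc, conf = conf, ks = ks)
}

# flatten an H x W x (k*d) head output to (H*W*k) x d rows in prior order
# (cells column-major, then the k-box menu)
flatten_head <- function(y, k, d) {
  hh <- dim(y)[1]; ww <- dim(y)[2]
  m <- matrix(y, hh * ww, k * d)         # row = cell (col-major)
  a3 <- array(t(m), c(d, k, hh * ww))    # [component, box, cell]
  matrix(aperm(a3, c(2L, 3L, 1L)), k * hh * ww, d)
}

unflatten_head <- function(g, hh, ww, k, d) {
  a3 <- aperm(array(g, c(k, hh * ww, d)), c(3L, 1L, 2L))
  array(t(matrix(a3, d * k, hh * ww)), c(hh, ww, k * d))
}

#' Apply the detection heads to a feature pyramid
#'
#' Each pyramid level gets a 3x3 localization head (4 offsets per box) and a
#' 3x3 confidence head (`n_classes + 1` scores per box); outputs are
#' flattened in exactly the prior-box order of [generate_priors()].
#'
#' @param pyramid List of six feature maps (from [feature_pyramid()]).
#' @param heads Head stacks built by the model constructor.
#' @param params Parameter list.
#' @return List with `loc` (N x 4) and `conf` (N x (n_classes + 1)), plus
#'   caches when `keep_caches`.
#' @param keep_caches Keep conv caches for backpropagation.
#' @export
detection_heads <- function(pyramid, heads, params, keep_caches = FALSE) {
  locs <- confs <- vector("list", 6L)
  caches <- list(loc = vector("list", 6L), conf = vector("list", 6L))
  for (i in 1:6) {
    k <- heads$ks[i]
    rl <- nn_forward(list(heads$loc[[i]]), params, pyramid[[i]])
    rc <- nn_forward(list(heads$conf[[i]]), params, pyramid[[i]])
    hh <- dim(rl$y)[1]; ww <- dim(rl$y)[2]
    locs[[i]] <- flatten_head(rl$y, k, 4L)
    confs[[i]] <- flatten_head(rc$y, k, dim(rc$y)[3] / k)
    if (keep_caches) {
      caches$loc[[i]] <- rl$caches
      caches$conf[[i]] <- rc$caches
    }
  }
  out <- list(loc = do.call(rbind, locs), conf = do.call(rbind, confs))
  if (keep_caches) out$caches <- caches
  out
}

# ---- the full dual-branch model --------------------------------------------

#' Construct an RGB-D SSD model
#'
#' Builds the requested branches (colour, depth or both), their detection
#' heads and the prior-box sets; with both branches the predictions are
#' fused at decision level by concatenating the two branches' prediction
#' lists over the fused prior set (colour first), giving 17,464 rows at
#' full 300x300 geometry.
#'
#' @param mode `"fused"` (both branches), `"rgb"` or `"depth"`.
#' @param width_multiplier Channel-width scale (1 = full width).
#' @param use_inception Use inception refinement blocks in the extras.
#' @param n_classes Number of foreground classes (default 6).
#' @param image_size Input side in pixels (default 300).
#' @param seed Seed for parameter initialisation.
#' @return An `rdssd_model`.
#' @export
rdssd_model <- function(mode = c("fused", "rgb", "depth"),
                        width_multiplier = 1, use_inception = FALSE,
                        n_classes = 6L, image_size = 300L, seed = 1L) {
  mode <- match.arg(mode)
  specs <- layer_specs_300()
  branches <- list()
  params <- list()
  heads <- list()
  priors <- list()
  if (mode %in% c("fused", "rgb")) {
    br <- build_branch(3L, width_multiplier, "r", use_inception, seed)
    hd <- head_layers("r", br$out_channels, specs, n_classes)
    hp <- with_seed(seed + 1L,
                    nn_init_params(c(hd$loc, hd$conf)))
    branches$rgb <- br; heads$rgb <- hd
    params <- c(params, br$params, hp)
    priors$rgb <- generate_priors(specs, image_size, "rgb")
  }
  if (mode %in% c("fused", "depth")) {
    br <- build_branch(1L, width_multiplier, "d", use_inception, seed + 2L)
    hd <- head_layers("d", br$out_channels, specs, n_classes)
    hp <- with_seed(seed + 3L, nn_init_params(c(hd$loc, hd$conf)))
    branches$depth <- br; heads$depth <- hd
    params <- c(params, br$params, hp)
    priors$depth <- generate_priors(specs, image_size, "depth")
  }
  priors$active <- switch(mode,
                          fused = fuse_priors(priors$rgb, priors$depth),
                          rgb = priors$rgb, depth = priors$depth)
  structure(list(mode = mode, branches = branches, heads = heads,
                 params = params, priors = priors, n_classes = n_classes,
                 image_size = image_size,
                 width_multiplier = width_multiplier),
            class = "rdssd_model")
}

#' @export
print.rdssd_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<rdssd_model mode '%s': %d priors, %d parameters, width x%g>\n",
              x$mode, nrow(x$priors$active$boxes), n_par,
              x$width_multiplier))
  invisible(x)
}

#' Forward pass of the RGB-D SSD model
#'
#' Runs the branch(es) on a preprocessed 300x300 pair and concatenates
#' per-branch predictions in (colour, depth) order over the fused prior set.
#'
#' @param model An `rdssd_model`.
#' @param rgb Normalised colour image (300 x 300 x 3), or `NULL` in depth
#'   mode.
#' @param depth Normalised depth map (300 x 300), or `NULL` in rgb mode.
#' @param params Parameter list override (defaults to the model's).
#' @param keep_caches Keep all caches for backpropagation.
#' @return A `detections` list: `loc` (N x 4 offsets), `conf` (N x
#'   (n_classes + 1) scores), `priors` (the active `prior_box_set`).
#' @export
rd_ssd_forward <- function(model, rgb = NULL, depth = NULL,
                           params = model$params, keep_caches = FALSE) {
  outs <- list()
  state <- list()
  for (br_name in names(model$branches)) {
    x <- if (br_name == "rgb") rgb else depth
    if (is.null(x)) stop("missing ", br_name, " input for mode ", model$mode)
    x <- as_cube(x)
    if (dim(x)[1] != model$image_size || dim(x)[2] != model$image_size)
      stop("input must be ", model$image_size, "x", model$image_size)
    pyr <- feature_pyramid(model$branches[[br_name]], x, params,
                           keep_caches = keep_caches)
    hd <- detection_heads(pyr$maps, model$heads[[br_name]], params,
                          keep_caches = keep_caches)
    outs[[br_name]] <- hd
    if (keep_caches)
      state[[br_name]] <- list(pyramid = pyr, heads = hd$caches,
                               maps = pyr$maps)
  }
  det <- list(loc = do.call(rbind, lapply(outs, `[[`, "loc")),
              conf = do.call(rbind, lapply(outs, `[[`, "conf")),
              priors = model$priors$active)
  if (keep_caches) det$state <- state
  structure(det, class = "detections")
}

# backward pass: gradients of a scalar loss wrt loc/conf rows -> parameter
# gradients, reusing the caches kept by rd_ssd_forward.
rd_ssd_backward <- function(model, state, gloc, gconf, params = model$params) {
  grads <- list()
  offset <- 0L
  specs <- layer_specs_300()
  for (br_name in names(model$branches)) {
    br <- model$branches[[br_name]]
    hd <- model$heads[[br_name]]
    st <- state[[br_name]]
    n_br <- sum(vapply(specs, function(s) s$grid^2 * s$boxes_per_location,
                       numeric(1)))
    rows <- offset + seq_len(n_br)
    gl <- gloc[rows, , drop = FALSE]
    gc <- gconf[rows, , drop = FALSE]
    offset <- offset + n_br
    # per-layer rows
    per_layer <- vapply(specs, function(s) s$grid^2 * s$boxes_per_location,
                        numeric(1))
    ends <- cumsum(per_layer)
    gmaps <- vector("list", 6L)
    for (i in 1:6) {
      rws <- (ends[i] - per_layer[i] + 1L):ends[i]
      k <- hd$ks[i]
      hh <- dim(st$maps[[i]])[1]; ww <- dim(st$maps[[i]])[2]
      gy_loc <- unflatten_head(gl[rws, , drop = FALSE], hh, ww, k, 4L)
      gy_conf <- unflatten_head(gc[rws, , drop = FALSE], hh, ww, k,
                                ncol(gconf))
      bl <- nn_backward(list(hd$loc[[i]]), params, st$heads$loc[[i]],
                        gy_loc, grads)
      grads <- bl$grads
      bc <- nn_backward(list(hd$conf[[i]]), params, st$heads$conf[[i]],
                        gy_conf, grads)
      grads <- bc$grads
      gmaps[[i]] <- bl$gx + bc$gx
    }
    # trunk: deepest segment first, carrying the running gradient
    gcarry <- NULL
    for (i in 6:1) {
      g <- gmaps[[i]]
      if (!is.null(gcarry)) g <- g + gcarry
      res <- nn_backward(br$segments[[i]], params, st$pyramid$caches[[i]],
                         g, grads, need_input_grad = i > 1L)
      grads <- res$grads
      gcarry <- res$gx
    }
  }
  grads
}
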