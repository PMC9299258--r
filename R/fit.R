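# Model fitting and prediction: the classic fit / predict / print / summary /
# plot surface around the dual-branch detector.

# deterministic preprocessing (no stochastic augmentation): numeric
# conversion, percent coords, resize to the model input, mean subtraction.
preprocess_scene <- function(scene, rgb_means, depth_mean, size = 300,
                             depth_range = c(500, 4500)) {
  s <- as_sample(scene)
  s <- to_sensor(s)
  s <- to_percent_coords(s)
  s <- resize_sample(s, size)
  s <- subtract_means(s, rgb_means, depth_mean, depth_range)
  s
}

dataset_means <- function(scenes, depth_range) {
  rgb <- rowMeans(vapply(scenes, function(sc) apply(sc$rgb, 3L, mean),
                         numeric(3)))
  dep <- mean(vapply(scenes, function(sc) {
    d01 <- (sc$depth - depth_range[1]) / (depth_range[2] - depth_range[1])
    mean(pmin(pmax(d01, 0), 1))
  }, numeric(1)))
  list(rgb = rgb, depth = dep)
}

#' Fit an RGB-D SSD fruit detector
#'
#' Trains the dual-branch (or single-branch) detector on a list of RGB-D
#' scenes by minimising the composite multibox objective
#' `F = (C_loss + L_all_loss) / N` with Adam. Channel means are estimated
#' from the training scenes; each iteration draws a batch of scenes, runs
#' the paired augmentation pipeline (when enabled), matches the fused priors
#' to the ground truth, and backpropagates through both branches. Training
#' mAP is evaluated on the raw training scenes every `eval_every` iterations
#' and the run stops early once `map_target` (if set) is reached.
#'
#' @param scenes List of `rgbd_scene` objects (see [generate_scene()] or
#'   [load_dataset()]).
#' @param mode `"fused"`, `"rgb"` or `"depth"` — which branches to train.
#' @param config Run configuration, see [default_config()].
#' @param seed Integer seed controlling initialisation, batching and
#'   augmentation.
#' @param verbose Print a progress line at each evaluation.
#' @return An object of class `rdssd` with the trained `model`, the per-
#'   iteration loss `trace` (iteration, F_loss, C_loss, L_all_loss, and mAP
#'   where evaluated), the channel `means`, and the resolved `config`.
#' @seealso [predict.rdssd()], [evaluate_model()]
#' @export
rdssd_fit <- function(scenes, mode = c("fused", "rgb", "depth"),
                      config = default_config(), seed = config$seed,
                      verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(scenes) == 0L) stop("empty training set")
  tr <- config$training
  depth_range <- scenes[[1]]$depth_range
  if (is.null(depth_range)) depth_range <- c(500, 4500)
  means <- dataset_means(scenes, depth_range)
  if (!is.null(config$augment$rgb_means)) means$rgb <- config$augment$rgb_means
  if (!is.null(config$augment$depth_mean)) means$depth <- config$augment$depth_mean
  size <- config$augment$size
  acfg <- config$augment
  acfg$rgb_means <- means$rgb; acfg$depth_mean <- means$depth
  use_aug <- !isFALSE(tr$augment)

  object <- with_seed(seed, {
    model <- rdssd_model(mode, config$network$width_multiplier,
                         config$network$use_inception_extras, seed = seed)
    priors <- model$priors$active
    # without augmentation the preprocessed tensors and matches are constant
    fixed <- if (!use_aug) lapply(scenes, function(sc) {
      s <- preprocess_scene(sc, means$rgb, means$depth, size, depth_range)
      list(s = s, match = match_priors(priors, s$boxes, s$labels,
                                       config$match$iou_threshold))
    })
    params <- model$params
    opt <- adam_init(params)
    trace <- vector("list", tr$iterations)
    best_map <- NA_real_
    for (it in seq_len(tr$iterations)) {
      idx <- sample(length(scenes), tr$batch_size,
                    replace = tr$batch_size > length(scenes))
      grads <- list()
      fl <- cl <- ll <- 0; nb <- 0L
      for (i in idx) {
        if (use_aug) {
          s <- augment(as_sample(scenes[[i]]), acfg, depth_range)
          if (nrow(s$boxes) == 0L) next
          mt <- match_priors(priors, s$boxes, s$labels,
                             config$match$iou_threshold)
        } else {
          s <- fixed[[i]]$s
          mt <- fixed[[i]]$match
        }
        if (mt$N == 0L) next
        det <- rd_ssd_forward(model, if (model$mode != "depth") s$rgb,
                              if (model$mode != "rgb") s$depth,
                              params = params, keep_caches = TRUE)
        mbl <- multibox_loss_grad(det$conf, det$loc, mt,
                                  config$loss$neg_pos_ratio,
                                  config$loss$alpha)
        grads <- grads_add(grads, rd_ssd_backward(model, det$state,
                                                  mbl$gloc, mbl$gconf,
                                                  params))
        fl <- fl + mbl$F_loss; cl <- cl + mbl$C_loss / max(mbl$N, 1L)
        ll <- ll + mbl$L_all_loss / max(mbl$N, 1L)
        nb <- nb + 1L
      }
      if (nb > 0L) {
        res <- adam_step(params, grads_scale(grads, 1 / nb), opt,
                         lr = tr$learning_rate)
        params <- res$params; opt <- res$state
      }
      row <- data.frame(iteration = it, F_loss = fl / max(nb, 1L),
                        C_loss = cl / max(nb, 1L),
                        L_all_loss = ll / max(nb, 1L), mAP = NA_real_)
      if (it %% tr$eval_every == 0L || it == tr$iterations) {
        model$params <- params
        ev <- evaluate_model(structure(list(model = model, means = means,
                                            config = config,
                                            depth_range = depth_range),
                                       class = "rdssd"), scenes)
        row$mAP <- best_map <- ev$map
        if (verbose)
          message(sprintf("iter %d  F=%.3f  mAP=%.3f", it, row$F_loss,
                          ev$map))
        trace[[it]] <- row
        if (!is.null(tr$map_target) && ev$map >= tr$map_target) break
      }
      trace[[it]] <- row
    }
    model$params <- params
    structure(list(model = model, mode = mode, means = means,
                   depth_range = depth_range, config = config, seed = seed,
                   trace = do.call(rbind, trace[!vapply(trace, is.null,
                                                        logical(1))]),
                   train_map = best_map, n_scenes = length(scenes)),
              class = "rdssd")
  })
  object
}

#' @export
print.rdssd <- function(x, ...) {
  cat(sprintf("RGB-D SSD detector (mode '%s', width x%g)\n", x$mode,
              x$model$width_multiplier))
  cat(sprintf("  trained on %d scene(s), %d iteration(s)\n", x$n_scenes,
              max(x$trace$iteration)))
  cat(sprintf("  final F_loss %.4f", x$trace$F_loss[nrow(x$trace)]))
  if (!is.na(x$train_map)) cat(sprintf(", training mAP %.4f", x$train_map))
  cat("\n")
  invisible(x)
}

#' @export
summary.rdssd <- function(object, ...) {
  tr <- object$trace
  cat(sprintf("RGB-D SSD detector, mode '%s'\n", object$mode))
  cat(sprintf("  priors: %d (%s)\n", nrow(object$model$priors$active$boxes),
              object$model$priors$active$branch))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(object$model$params, length, numeric(1)))))
  cat(sprintf("  channel means: rgb (%.1f, %.1f, %.1f), depth %.3f\n",
              object$means$rgb[1], object$means$rgb[2], object$means$rgb[3],
              object$means$depth))
  cat("  loss trace (first/last):\n")
  print(tr[unique(c(1L, nrow(tr))), c("iteration", "F_loss", "C_loss",
                                      "L_all_loss", "mAP")],
        row.names = FALSE)
  invisible(object)
}

#' Detect fruit in RGB-D scenes with a fitted model
#'
#' Runs the forward pass, decodes offsets against the fused priors, applies
#' per-class confidence filtering and non-maximum suppression, and returns
#' detections in original pixel coordinates.
#'
#' @param object A fitted `rdssd` object.
#' @param newdata List of `rgbd_scene` objects.
#' @param conf_threshold Minimum class probability, default from config.
#' @param ... Unused.
#' @return data.frame with columns `image`, `class`, `score`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @export
predict.rdssd <- function(object, newdata,
                          conf_threshold = object$config$eval$conf_threshold,
                          ...) {
  model <- object$model
  priors <- model$priors$active
  nmscfg <- object$config$nms
  out <- list()
  for (i in seq_along(newdata)) {
    sc <- newdata[[i]]
    s <- preprocess_scene(sc, object$means$rgb, object$means$depth,
                          object$config$augment$size, object$depth_range)
    det <- rd_ssd_forward(model, if (model$mode != "depth") s$rgb,
                          if (model$mode != "rgb") s$depth)
    probs <- softmax_rows(det$conf)
    boxes <- decode_boxes(det$loc, priors$boxes)
    boxes[] <- pmin(pmax(boxes, 0), 1)
    for (cl in seq_len(model$n_classes)) {
      p <- probs[, cl + 1L]
      sel <- which(p > conf_threshold)
      if (length(sel) == 0L) next
      b <- boxes[sel, , drop = FALSE]
      ok <- b[, 3] > b[, 1] & b[, 4] > b[, 2]
      sel <- sel[ok]; b <- b[ok, , drop = FALSE]
      if (length(sel) == 0L) next
      keep <- nms(b, p[sel], nmscfg$iou_threshold, nmscfg$top_k)
      out[[length(out) + 1L]] <- data.frame(
        image = i, class = cl, score = p[sel][keep],
        x_min = b[keep, 1] * sc$width, y_min = b[keep, 2] * sc$height,
        x_max = b[keep, 3] * sc$width, y_max = b[keep, 4] * sc$height)
    }
  }
  if (length(out) == 0L)
    return(data.frame(image = integer(0), class = integer(0),
                      score = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

scene_ground_truths <- function(scenes) {
  rows <- lapply(seq_along(scenes), function(i) {
    b <- rbind(scenes[[i]]$boxes)
    if (nrow(b) == 0L) return(NULL)
    data.frame(image = i, class = scenes[[i]]$labels, x_min = b[, 1],
               y_min = b[, 2], x_max = b[, 3], y_max = b[, 4])
  })
  do.call(rbind, rows)
}

#' Evaluate a fitted detector on a set of scenes
#'
#' Detection (forward pass, decoding, per-class NMS, confidence filter)
#' followed by VOC-style AP per class, mAP, and the maturity/occlusion
#' group aggregation.
#'
#' @param object A fitted `rdssd`.
#' @param scenes List of `rgbd_scene` objects with ground truth.
#' @param ... Passed to [evaluate_detections()].
#' @return An `eval_result`.
#' @export
evaluate_model <- function(object, scenes, ...) {
  det <- predict(object, scenes)
  gt <- scene_ground_truths(scenes)
  evaluate_detections(det, gt,
                      iou_threshold = object$config$eval$iou_threshold,
                      interpolation = object$config$eval$interpolation, ...)
}

#' Plot a scene with ground truth and/or predicted boxes
#'
#' @param x A fitted `rdssd` (or `NULL` to plot ground truth only).
#' @param scene An `rgbd_scene`.
#' @param detections Optional precomputed detections for this scene (as one
#'   image of a [predict.rdssd()] frame); computed when missing.
#' @param conf_threshold Score threshold for displayed boxes.
#' @param ... Unused.
#' @return Invisibly, the detections shown.
#' @export
plot.rdssd <- function(x, scene, detections = NULL, conf_threshold = 0.5,
                       ...) {
  img <- scene$rgb / 255
  graphics::plot(c(0, scene$width), c(scene$height, 0), type = "n",
                 xlab = "", ylab = "", asp = 1, axes = FALSE)
  graphics::rasterImage(img, 0, scene$height, scene$width, 0)
  b <- rbind(scene$boxes)
  if (nrow(b) > 0)
    graphics::rect(b[, 1], b[, 2], b[, 3], b[, 4], border = "white",
                   lty = 2)
  if (is.null(detections) && !is.null(x)) {
    detections <- predict(x, list(scene))
  }
  if (!is.null(detections)) {
    d <- detections[detections$score >= conf_threshold, , drop = FALSE]
    cols <- c("green3", "green4", "orange", "orange3", "red", "red3")
    if (nrow(d) > 0) {
      graphics::rect(d$x_min, d$y_min, d$x_max, d$y_max,
                     border = cols[d$class], lwd = 2)
      graphics::text(d$x_min, d$y_min - 3,
                     sprintf("tomato%d %.2f", d$class, d$score),
                     col = cols[d$class], adj = c(0, 1), cex = 0.7)
    }
  }
  invisible(detections)
}

#' Save / load a fitted model checkpoint
#'
#' Single-file serialized weights plus a configuration hash; reloading
#' reproduces identical forward outputs.
#'
#' @param object A fitted `rdssd` (or `hrgan`) object.
#' @param path Checkpoint file path.
#' @return `path` invisibly for save; the restored object for load.
#' @export
save_checkpoint <- function(object, path) {
  object$config_hash <- .crc32(serialize(object$config, NULL))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
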