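# Prior-box (default-box/anchor) geometry for the 300x300 dual-branch model.

#' Per-layer prior-box specifications for the 300x300 detector
#'
#' Returns the six detection-layer specifications used by both the colour and
#' the depth branch: feature-grid sizes 38, 19, 10, 5, 3, 1; paired min/max
#' pixel sizes 30/60, 60/111, 111/162, 162/213, 213/264, 264/315; and aspect
#' ratio menus giving 4, 6, 6, 6, 4, 4 boxes per grid location.
#'
#' @return A list of six layer specs, each with elements `grid`, `min_size`,
#'   `max_size`, `aspect_ratios` and `boxes_per_location`.
#' @examples
#' sum(vapply(layer_specs_300(), function(s) s$grid^2 * s$boxes_per_location,
#'            numeric(1)))  # 8732
#' @export
layer_specs_300 <- function() {
  grids <- c(38L, 19L, 10L, 5L, 3L, 1L)
  mins  <- c(30, 60, 111, 162, 213, 264)
  maxs  <- c(60, 111, 162, 213, 264, 315)
  ars   <- list(c(1, 2, 1/2), c(1, 2, 3, 1/2, 1/3), c(1, 2, 3, 1/2, 1/3),
                c(1, 2, 3, 1/2, 1/3), c(1, 2, 1/2), c(1, 2, 1/2))
  lapply(seq_len(6L), function(k) {
    spec <- list(grid = grids[k], min_size = mins[k], max_size = maxs[k],
                 aspect_ratios = ars[[k]])
    spec$boxes_per_location <- 2L + 2L * sum(ars[[k]] > 1)
    spec
  })
}

#' Linear prior-box scale schedule
#'
#' The linear interpolation `s_k = s_min + (s_max - s_min) / (m - 1) * (k - 1)`
#' between a smallest and a largest relative box scale over `m` detection
#' layers. Note that with the conventional endpoints (0.2, 0.9) this schedule
#' does not reproduce the pixel sizes of [layer_specs_300()], which follow the
#' canonical 300-input schedule with a special-cased first layer; the two are
#' deliberately kept as independent entry points.
#'
#' @param k Layer index, `1 <= k <= m`.
#' @param m Number of detection layers (`>= 2`).
#' @param s_min,s_max Smallest/largest relative scale.
#' @return The relative scale `s_k`.
#' @examples
#' scale_fraction(1, 6)        # 0.2
#' scale_fraction(6, 6)        # 0.9
#' @export
scale_fraction <- function(k, m, s_min = 0.2, s_max = 0.9) {
  if (m < 2) stop("m must be >= 2")
  if (any(k < 1 | k > m)) stop("layer index k out of range [1, m]")
  s_min + (s_max - s_min) / (m - 1) * (k - 1)
}

new_prior_box_set <- function(boxes, layer, branch, image_size) {
  structure(list(boxes = boxes, layer = layer, branch = branch,
                 image_size = image_size),
            class = "prior_box_set")
}

#' Generate the prior boxes for one branch
#'
#' Tiles every feature-grid cell of each detection layer with its default
#' boxes: a square of side `min_size`, a square of side
#' `sqrt(min_size * max_size)`, and a pair of rectangles with aspect `r` and
#' `1/r` for every ratio `r > 1` in the layer's menu. Centres sit at
#' `(a + 0.5) / grid`; all sizes are normalised by `image_size` and
#' coordinates are clamped to `[0, 1]`.
#'
#' Ordering is fixed and load-bearing: layers in order, cells column-major
#' (x outer, y inner), then the box menu; the detection heads flatten their
#' outputs in the same order.
#'
#' @param specs Layer specifications, as from [layer_specs_300()].
#' @param image_size Square input size in pixels.
#' @param branch Branch tag, one of `"rgb"`, `"depth"`.
#' @param clamp Clamp corner coordinates into `[0, 1]` (default `TRUE`).
#' @return A `prior_box_set`: `boxes` is an N x 4 matrix in normalised
#'   centre-form `(cx, cy, w, h)`, plus per-box `layer` indices.
#' @examples
#' p <- generate_priors()
#' nrow(p$boxes)  # 8732
#' @export
generate_priors <- function(specs = layer_specs_300(), image_size = 300,
                            branch = "rgb", clamp = TRUE) {
  out <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (sp$min_size >= sp$max_size) stop("min_size must be < max_size")
    f <- sp$grid
    s  <- sp$min_size / image_size
    s2 <- sqrt(sp$min_size * sp$max_size) / image_size
    menu <- rbind(c(s, s), c(s2, s2))
    for (r in sp$aspect_ratios[sp$aspect_ratios > 1]) {
      menu <- rbind(menu, c(s * sqrt(r), s / sqrt(r)),
                    c(s / sqrt(r), s * sqrt(r)))
    }
    kpb <- nrow(menu)
    # cells column-major: x (a) outer, y (b) inner
    cells <- expand.grid(b = seq_len(f) - 1L, a = seq_len(f) - 1L)
    cx <- rep((cells$a + 0.5) / f, each = kpb)
    cy <- rep((cells$b + 0.5) / f, each = kpb)
    wh <- menu[rep(seq_len(kpb), times = f * f), , drop = FALSE]
    out[[k]] <- cbind(cx, cy, wh)
  }
  boxes <- do.call(rbind, out)
  colnames(boxes) <- c("cx", "cy", "w", "h")
  layer <- rep(seq_along(specs),
               vapply(specs, function(s) s$grid^2 * s$boxes_per_location,
                      numeric(1)))
  if (clamp) {
    corners <- center_to_corner(boxes)
    corners[] <- pmin(pmax(corners, 0), 1)
    boxes <- corner_to_center(corners)
  }
  new_prior_box_set(boxes, layer, branch, image_size)
}

#' Fuse the prior boxes of the colour and depth branches
#'
#' Decision-level fusion concatenates the two branches' ordered prior sets,
#' colour first, so the fused set has `N_rgb + N_depth` boxes (17,464 for two
#' standard 300-input branches).
#'
#' @param rgb_priors,depth_priors `prior_box_set` objects built for the same
#'   image size.
#' @return A fused `prior_box_set` with branch tag `"fused"`.
#' @export
fuse_priors <- function(rgb_priors, depth_priors) {
  if (!identical(rgb_priors$image_size, depth_priors$image_size))
    stop("prior sets were built for different image sizes")
  new_prior_box_set(rbind(rgb_priors$boxes, depth_priors$boxes),
                    c(rgb_priors$layer, depth_priors$layer),
                    "fused", rgb_priors$image_size)
}

#' Map a prior box from feature-grid coordinates onto image pixels
#'
#' @param prior Numeric 4-vector `(cx, cy, w, h)`: centre in feature-grid
#'   units (e.g. `a + 0.5` for cell `a`), width/height normalised to the
#'   image.
#' @param w_img,h_img Image size in pixels.
#' @param w_feature,h_feature Feature-grid size; pass 1 when the centre is
#'   already normalised.
#' @return Corner-form pixel box `(x_min, y_min, x_max, y_max)`.
#' @examples
#' map_to_image(c(0.5, 0.5, 1, 1), 300, 300, 1, 1)     # full image
#' map_to_image(c(0.5, 0.5, 0.1, 0.1), 300, 300, 38, 38)[1:2]  # ~ -11, -11
#' @export
map_to_image <- function(prior, w_img, h_img, w_feature, h_feature) {
  cx <- prior[1] / w_feature
  cy <- prior[2] / h_feature
  c(x_min = (cx - prior[3] / 2) * w_img,
    y_min = (cy - prior[4] / 2) * h_img,
    x_max = (cx + prior[3] / 2) * w_img,
    y_max = (cy + prior[4] / 2) * h_img)
}

#' @export
print.prior_box_set <- function(x, ...) {
  cat(sprintf("<prior_box_set: %d boxes, branch '%s', image size %d>\n",
              nrow(x$boxes), x$branch, x$image_size))
  tab <- table(x$layer)
  cat("  per layer:", paste(sprintf("L%s=%d", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Export a prior-box set as a plain TSV for inspection
#'
#' @param priors A `prior_box_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_priors_tsv <- function(priors, path) {
  df <- data.frame(layer = priors$layer, priors$boxes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# centre-form (cx,cy,w,h) <-> corner-form (x_min,y_min,x_max,y_max)
center_to_corner <- function(b) {
  b <- rbind(b)
  out <- cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
               b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
  colnames(out) <- c("x_min", "y_min", "x_max", "y_max")
  out
}

corner_to_center <- function(b) {
  b <- rbind(b)
  out <- cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
               b[, 3] - b[, 1], b[, 4] - b[, 2])
  colnames(out) <- c("cx", "cy", "w", "h")
  out
}
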