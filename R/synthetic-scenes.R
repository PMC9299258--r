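# Seeded generator of Kinect-style registered RGB-D tomato scenes with
# 6-way ground truth (maturity x occlusion) and optional specular highlights.

# run code under a temporary RNG state so generators never disturb the
# caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Scene-generator configuration
#'
#' The defaults emulate a Kinect-V2 registered pair: a 512 x 424 canvas (the
#' depth sensor's native grid), fruit depths inside the sensor's practical
#' 500-4500 mm working range, ellipsoidal fruits in three maturity colour
#' bands (green, orange, red), and irregular green foliage occluders placed
#' strictly nearer than the fruit they cover. A fruit whose area is covered
#' by nearer objects beyond `occlusion_label_threshold` is labelled with the
#' occluded variant of its maturity class.
#'
#' @param image_width,image_height Canvas size in pixels.
#' @param n_fruits Integer range `c(min, max)` of fruits per scene.
#' @param fruit_radius Pixel range `c(min, max)` of fruit radii.
#' @param maturity_probs Probabilities over green/orange/red; must sum to 1.
#' @param occluder_density Expected occluders per fruit in `[0, 1]`.
#' @param occlusion_label_threshold Covered-area fraction above which a fruit
#'   is labelled occluded; default 0.10.
#' @param depth_range Near/far scene depth in millimetres.
#' @param highlight Logical: add specular highlight blobs and keep the clean
#'   image plus intensity mask.
#' @param highlight_blobs Integer range of highlight blob counts.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(image_width = 512, image_height = 424,
                         n_fruits = c(2L, 6L), fruit_radius = c(28, 60),
                         maturity_probs = c(1, 1, 1) / 3,
                         occluder_density = 0.5,
                         occlusion_label_threshold = 0.10,
                         depth_range = c(500, 4500),
                         highlight = FALSE, highlight_blobs = c(1L, 4L)) {
  cfg <- list(image_width = as.integer(image_width),
              image_height = as.integer(image_height),
              n_fruits = as.integer(n_fruits),
              fruit_radius = as.numeric(fruit_radius),
              maturity_probs = maturity_probs,
              occluder_density = occluder_density,
              occlusion_label_threshold = occlusion_label_threshold,
              depth_range = depth_range,
              highlight = isTRUE(highlight),
              highlight_blobs = as.integer(highlight_blobs))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (cfg$image_width < 1 || cfg$image_height < 1)
    stop("invalid scene config: zero-area image")
  if (length(cfg$fruit_radius) != 2L || cfg$fruit_radius[2] < cfg$fruit_radius[1] ||
      cfg$fruit_radius[1] <= 0)
    stop("invalid scene config: empty fruit radius range")
  if (length(cfg$n_fruits) != 2L || cfg$n_fruits[2] < cfg$n_fruits[1] ||
      cfg$n_fruits[1] < 0)
    stop("invalid scene config: bad fruit count range")
  if (abs(sum(cfg$maturity_probs) - 1) > 1e-8 || any(cfg$maturity_probs < 0))
    stop("invalid scene config: maturity_probs must be a probability vector")
  if (cfg$occlusion_label_threshold <= 0 || cfg$occlusion_label_threshold >= 1)
    stop("invalid scene config: occlusion_label_threshold must be in (0,1)")
  if (cfg$depth_range[1] >= cfg$depth_range[2] || cfg$depth_range[1] <= 0)
    stop("invalid scene config: need 0 < near < far")
  invisible(cfg)
}

# vectorised HSV (h in degrees, s,v in [0,1]) -> RGB in [0,1]
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# coarse smooth noise field via bilinear upsampling of a small random grid
noise_field <- function(h, w, cells = 8L, amplitude = 1) {
  g <- matrix(stats::runif(cells * cells, -1, 1), cells, cells)
  .resize_bilinear(array(g, c(cells, cells, 1L)), h, w)[, , 1L] * amplitude
}

# maturity hue bands (HSV degrees): green, orange, red
MATURITY_HUES <- list(c(90, 140), c(20, 40), c(0, 15))

#' Generate one synthetic RGB-D scene
#'
#' Renders ellipsoidal fruits with maturity-dependent hue and smooth
#' spherical depth blobs over a textured foliage background, then irregular
#' green occluders at strictly nearer depth, with full z-buffering. Labels
#' follow the 6-way scheme: class `2*m - 1` for a non-occluded fruit of
#' maturity `m` (1 green, 2 orange, 3 red) and `2*m` when the fraction of
#' the fruit's area covered by nearer objects exceeds the configured
#' threshold. Identical `(config, seed)` pairs yield bit-identical scenes.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @param keep_masks Attach each fruit's full rasterised mask and depth
#'   surface (`fruit_masks`), for auditing the occlusion labelling.
#' @return An `rgbd_scene`: `rgb` (H x W x 3 integer, 0-255), `depth`
#'   (H x W millimetres), `boxes` (N x 4 corner-form pixels), `labels`
#'   (class ids 1-6), `fruits` (per-fruit bookkeeping data.frame), and, when
#'   highlights are enabled, `highlight_mask` and `clean_rgb`.
#' @examples
#' sc <- generate_scene(scene_config(n_fruits = c(2, 2)), seed = 7)
#' dim(sc$rgb); sc$labels
#' @export
generate_scene <- function(config, seed, keep_masks = FALSE) {
  validate_scene_config(config)
  with_seed(seed, render_scene(config, keep_masks))
}

render_scene <- function(cfg, keep_masks = FALSE) {
  H <- cfg$image_height; W <- cfg$image_width
  near <- cfg$depth_range[1]; far <- cfg$depth_range[2]
  X <- matrix(seq_len(W), H, W, byrow = TRUE)   # column index
  Y <- matrix(seq_len(H), H, W)                 # row index

  # foliage background: dark green base + coarse texture
  base <- c(45, 72, 38)
  rgb <- array(0, c(H, W, 3L))
  for (ch in 1:3) rgb[, , ch] <- base[ch] + noise_field(H, W, 8L, 18)
  depth <- matrix(far, H, W)

  n <- if (cfg$n_fruits[1] == cfg$n_fruits[2]) cfg$n_fruits[1] else
    sample(cfg$n_fruits[1]:cfg$n_fruits[2], 1L)
  fruits <- list()
  if (n > 0) {
    for (i in seq_len(n)) {
      r <- stats::runif(1, cfg$fruit_radius[1], cfg$fruit_radius[2])
      rx <- r
      ry <- r * stats::runif(1, 0.85, 1.15)
      cx <- stats::runif(1, rx + 1, W - rx)
      cy <- stats::runif(1, ry + 1, H - ry)
      maturity <- sample(1:3, 1L, prob = cfg$maturity_probs)
      d0 <- stats::runif(1, near + 300, far - 300)
      hue <- stats::runif(1, MATURITY_HUES[[maturity]][1],
                          MATURITY_HUES[[maturity]][2])
      sat <- stats::runif(1, 0.6, 0.9)
      rho2 <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
      mask <- rho2 <= 1
      shade <- sqrt(pmax(1 - rho2, 0))
      dsurf <- d0 - r * shade                  # sphere bulges toward camera
      fruits[[i]] <- list(cx = cx, cy = cy, rx = rx, ry = ry, r = r,
                          maturity = maturity, d0 = d0, hue = hue, sat = sat,
                          mask = mask, dsurf = dsurf)
    }
    # z-buffered fruit rendering
    for (f in fruits) {
      idx <- which(f$mask & f$dsurf < depth)
      if (length(idx) == 0L) next
      shade <- sqrt(pmax(1 - ((X[idx] - f$cx) / f$rx)^2 -
                           ((Y[idx] - f$cy) / f$ry)^2, 0))
      col <- hsv_to_rgb(f$hue, f$sat, 0.40 + 0.50 * shade) * 255
      for (ch in 1:3) {
        pl <- rgb[, , ch]; pl[idx] <- col[, ch]; rgb[, , ch] <- pl
      }
      depth[idx] <- f$dsurf[idx]
    }
    # occluders: irregular green blobs strictly nearer than their fruit
    n_occ <- round(cfg$occluder_density * n)
    if (n_occ > 0) {
      targets <- sample(seq_len(n), n_occ, replace = n_occ > n)
      for (t in targets) {
        f <- fruits[[t]]
        ang <- stats::runif(1, 0, 2 * pi)
        bx <- f$cx + 0.8 * f$rx * cos(ang)
        by <- f$cy + 0.8 * f$ry * sin(ang)
        docc <- max(near + 20, f$d0 - f$r - stats::runif(1, 60, 350))
        omask <- matrix(FALSE, H, W)
        for (k in seq_len(sample(3:5, 1L))) {
          ox <- bx + stats::rnorm(1, 0, 0.3 * f$r)
          oy <- by + stats::rnorm(1, 0, 0.3 * f$r)
          orx <- f$r * stats::runif(1, 0.35, 0.65)
          ory <- f$r * stats::runif(1, 0.35, 0.65)
          omask <- omask | (((X - ox) / orx)^2 + ((Y - oy) / ory)^2 <= 1)
        }
        hue <- stats::runif(1, 95, 135)
        val <- stats::runif(1, 0.30, 0.55)
        osurf <- matrix(docc, H, W) + noise_field(H, W, 6L, 8)
        idx <- which(omask & osurf < depth)
        if (length(idx) == 0L) next
        col <- hsv_to_rgb(hue, stats::runif(1, 0.5, 0.8), val) * 255
        for (ch in 1:3) {
          pl <- rgb[, , ch]
          pl[idx] <- col[ch] + stats::runif(length(idx), -12, 12)
          rgb[, , ch] <- pl
        }
        depth[idx] <- osurf[idx]
      }
    }
  }

  # labels from recomputed coverage; boxes bound the full (unoccluded) mask
  boxes <- matrix(numeric(0), 0L, 4L,
                  dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
  labels <- integer(0)
  finfo <- NULL
  if (n > 0) {
    rows <- lapply(fruits, function(f) {
      covered <- sum(f$mask & depth < f$dsurf - 0.5) / sum(f$mask)
      occluded <- covered > cfg$occlusion_label_threshold
      cols_in <- which(colSums(f$mask) > 0)
      rows_in <- which(rowSums(f$mask) > 0)
      c(x_min = min(cols_in) - 1, y_min = min(rows_in) - 1,
        x_max = max(cols_in), y_max = max(rows_in),
        label = 2L * f$maturity - 1L + occluded,
        maturity = f$maturity, coverage = covered, d0 = f$d0)
    })
    tab <- do.call(rbind, rows)
    boxes <- tab[, 1:4, drop = FALSE]
    labels <- as.integer(tab[, "label"])
    finfo <- data.frame(maturity = as.integer(tab[, "maturity"]),
                        coverage = tab[, "coverage"], depth = tab[, "d0"])
  }
  rgb <- round(pmin(pmax(rgb, 0), 255))
  scene <- list(rgb = rgb, depth = depth, boxes = boxes, labels = labels,
                fruits = finfo, width = W, height = H,
                depth_range = cfg$depth_range)
  if (keep_masks && n > 0)
    scene$fruit_masks <- lapply(fruits, function(f)
      list(mask = f$mask, dsurf = f$dsurf, maturity = f$maturity))
  if (cfg$highlight) {
    nb <- if (cfg$highlight_blobs[1] == cfg$highlight_blobs[2])
      cfg$highlight_blobs[1] else
      sample(cfg$highlight_blobs[1]:cfg$highlight_blobs[2], 1L)
    hl <- synthesize_highlights(rgb, seed = NULL, n_blobs = nb,
                                .use_current_rng = TRUE)
    scene$clean_rgb <- scene$rgb
    scene$rgb <- hl$rgb
    scene$highlight_mask <- hl$mask
  }
  structure(scene, class = "rgbd_scene")
}

#' @export
print.rgbd_scene <- function(x, ...) {
  cat(sprintf("<rgbd_scene %dx%d: %d fruit(s)%s>\n", x$width, x$height,
              length(x$labels),
              if (!is.null(x$highlight_mask)) ", highlights" else ""))
  if (length(x$labels) > 0)
    cat("  labels:", paste0("tomato", x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Add synthetic specular highlights to an RGB image
#'
#' Adds elliptical Gaussian brightness blobs to all three channels and
#' returns the ground-truth intensity mask (the per-pixel added intensity on
#' a 0-1 scale) needed to supervise highlight removal.
#'
#' @param rgb H x W x 3 numeric image with values in 0-255.
#' @param seed Integer seed (ignored when `.use_current_rng`).
#' @param n_blobs Number of highlight blobs (>= 0).
#' @param .use_current_rng Internal: draw from the current RNG stream.
#' @return List with `rgb` (highlighted, clipped to 0-255) and `mask`
#'   (H x W intensity in `[0, 1]`).
#' @export
synthesize_highlights <- function(rgb, seed, n_blobs,
                                  .use_current_rng = FALSE) {
  if (n_blobs < 0) stop("invalid config: n_blobs must be >= 0")
  run <- function() {
    H <- dim(rgb)[1]; W <- dim(rgb)[2]
    added <- matrix(0, H, W)
    if (n_blobs > 0) {
      X <- matrix(seq_len(W), H, W, byrow = TRUE)
      Y <- matrix(seq_len(H), H, W)
      for (i in seq_len(n_blobs)) {
        cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
        sx <- stats::runif(1, 0.01, 0.05) * W
        sy <- stats::runif(1, 0.01, 0.05) * H
        amp <- stats::runif(1, 80, 200)
        added <- added + amp * exp(-((X - cx)^2 / (2 * sx^2) +
                                       (Y - cy)^2 / (2 * sy^2)))
      }
    }
    out <- rgb
    for (ch in 1:3) out[, , ch] <- pmin(pmax(rgb[, , ch] + added, 0), 255)
    list(rgb = out, mask = pmin(added / 255, 1))
  }
  if (.use_current_rng) run() else with_seed(seed, run())
}

#' Write a synthetic RGB-D dataset to disk
#'
#' Per scene: an 8-bit RGB PNG, a 16-bit depth PNG (millimetres) and a
#' VOC-dialect XML annotation; plus a `manifest.tsv` listing the triples in
#' generation order. Scene `i` uses seed `seed + i - 1`.
#'
#' @param n_scenes Number of scenes.
#' @param config A [scene_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer base seed.
#' @return The manifest data.frame (`rgb_path`, `depth_path`, `xml_path`),
#'   invisibly.
#' @export
generate_dataset <- function(n_scenes, config, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sc <- generate_scene(config, seed + i - 1L)
    stem <- sprintf("scene_%04d", i)
    rgb_path <- file.path(out_dir, paste0(stem, "_rgb.png"))
    depth_path <- file.path(out_dir, paste0(stem, "_depth.png"))
    xml_path <- file.path(out_dir, paste0(stem, ".xml"))
    png::writePNG(sc$rgb / 255, rgb_path)
    write_depth_png(sc$depth, depth_path)
    write_voc_xml(sc, xml_path, filename = paste0(stem, "_rgb.png"))
    rows[[i]] <- data.frame(rgb_path = rgb_path, depth_path = depth_path,
                            xml_path = xml_path)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param manifest_path Path to a `manifest.tsv`.
#' @return A list of `rgbd_scene`-like records (rgb 0-255, depth in mm,
#'   boxes, labels).
#' @export
load_dataset <- function(manifest_path) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    rgb <- png::readPNG(man$rgb_path[i]) * 255
    ann <- read_voc_xml(man$xml_path[i])
    structure(list(rgb = rgb, depth = read_depth_png(man$depth_path[i]),
                   boxes = ann$boxes, labels = ann$labels,
                   width = dim(rgb)[2], height = dim(rgb)[1]),
              class = "rgbd_scene")
  })
}
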