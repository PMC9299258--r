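test_that("scene generation is deterministic and validates its config", {
  cfg <- tiny_config()
  a <- generate_scene(cfg, seed = 5)
  b <- generate_scene(cfg, seed = 5)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$depth, b$depth)
  expect_identical(a$boxes, b$boxes)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$rgb, generate_scene(cfg, seed = 6)$rgb))
  expect_error(scene_config(image_width = 0), "zero-area")
  expect_error(scene_config(fruit_radius = c(10, 5)), "radius")
  expect_error(scene_config(maturity_probs = c(0.5, 0.5, 0.5)),
               "probability")
  expect_error(scene_config(depth_range = c(4000, 500)), "near < far")
})

test_that("an empty fruit range yields an object-free scene", {
  sc <- generate_scene(tiny_config(n_fruits = c(0L, 0L)), seed = 1)
  expect_equal(nrow(sc$boxes), 0L)
  expect_length(sc$labels, 0L)
  expect_equal(dim(sc$rgb), c(80, 96, 3))
})

test_that("boxes lie inside the image and pair with labels", {
  for (seed in 1:6) {
    sc <- tiny_scene(seed)
    expect_equal(nrow(sc$boxes), length(sc$labels))
    if (nrow(sc$boxes) > 0) {
      expect_true(all(sc$boxes[, 1] >= 0 & sc$boxes[, 2] >= 0))
      expect_true(all(sc$boxes[, 3] <= sc$width &
                        sc$boxes[, 4] <= sc$height))
      expect_true(all(sc$boxes[, 3] > sc$boxes[, 1] &
                        sc$boxes[, 4] > sc$boxes[, 2]))
      expect_true(all(sc$labels %in% 1:6))
    }
  }
})

test_that("occlusion labels agree with coverage recomputed from the masks", {
  hit_occluded <- FALSE
  for (seed in 1:8) {
    cfg <- tiny_config(occluder_density = 1)
    sc <- generate_scene(cfg, seed, keep_masks = TRUE)
    for (i in seq_along(sc$labels)) {
      fm <- sc$fruit_masks[[i]]
      covered <- sum(fm$mask & sc$depth < fm$dsurf - 0.5) / sum(fm$mask)
      occluded <- covered > cfg$occlusion_label_threshold
      expect_identical(sc$labels[i],
                       2L * fm$maturity - 1L + occluded)
      # depth ordering: wherever the fruit is covered, the scene depth is
      # strictly nearer than the fruit surface
      idx <- fm$mask & sc$depth < fm$dsurf - 0.5
      if (any(idx)) expect_true(all(sc$depth[idx] < fm$dsurf[idx]))
      hit_occluded <- hit_occluded || occluded
    }
  }
  expect_true(hit_occluded)   # the occluded branch was actually exercised
})

test_that("a heavily covered fruit gets the occluded label variant", {
  # high density, low threshold: expect occluded labels (even classes)
  cfg <- tiny_config(occluder_density = 1,
                     occlusion_label_threshold = 0.05)
  labs <- unlist(lapply(1:6, function(s) generate_scene(cfg, s)$labels))
  expect_true(any(labs %% 2 == 0))
})

test_that("highlight synthesis is additive, masked and bounded", {
  sc <- tiny_scene(3)
  hl <- synthesize_highlights(sc$rgb, seed = 2, n_blobs = 3)
  expect_true(all(hl$mask >= 0 & hl$mask <= 1))
  expect_true(all(hl$rgb >= 0 & hl$rgb <= 255))
  expect_gte(mean(hl$rgb), mean(sc$rgb))
  # zero blobs: identity with an all-zero mask
  hl0 <- synthesize_highlights(sc$rgb, seed = 2, n_blobs = 0)
  expect_equal(hl0$rgb, sc$rgb * 1.0)
  expect_equal(max(hl0$mask), 0)
  expect_error(synthesize_highlights(sc$rgb, 1, n_blobs = -1),
               "n_blobs")
  # scenes built with highlights carry the clean image and the mask
  sch <- generate_scene(tiny_config(highlight = TRUE), seed = 4)
  expect_false(is.null(sch$highlight_mask))
  expect_false(is.null(sch$clean_rgb))
  expect_gte(mean(sch$rgb), mean(sch$clean_rgb))
})

test_that("written datasets round-trip through PNG and XML", {
  dir <- tempfile("scenes")
  man <- generate_dataset(3, tiny_config(), dir, seed = 21)
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$rgb_path)))
  expect_true(all(file.exists(man$depth_path)))
  expect_true(all(file.exists(man$xml_path)))
  # manifest order equals generation order
  expect_identical(man$rgb_path,
                   file.path(dir, sprintf("scene_%04d_rgb.png", 1:3)))
  scenes <- load_dataset(file.path(dir, "manifest.tsv"))
  for (i in 1:3) {
    ref <- generate_scene(tiny_config(), seed = 21 + i - 1)
    expect_equal(scenes[[i]]$rgb, ref$rgb, tolerance = 1 / 254)
    # depth is stored as integer millimetres
    expect_equal(scenes[[i]]$depth, round(ref$depth))
    expect_equal(unname(scenes[[i]]$boxes), unname(round(ref$boxes)))
    expect_identical(scenes[[i]]$labels, ref$labels)
  }
  # byte-identical rewrite under the same seed
  dir2 <- tempfile("scenes2")
  generate_dataset(3, tiny_config(), dir2, seed = 21)
  for (i in 1:3) {
    expect_identical(readBin(man$rgb_path[i], "raw", 1e6),
                     readBin(file.path(dir2, basename(man$rgb_path[i])),
                             "raw", 1e6))
    expect_identical(readBin(man$depth_path[i], "raw", 1e6),
                     readBin(file.path(dir2, basename(man$depth_path[i])),
                             "raw", 1e6))
  }
})
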