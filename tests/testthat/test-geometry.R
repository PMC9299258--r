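test_that("IoU matches hand cases and the rasterization oracle", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_error(iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "degenerate")
  set.seed(41)
  for (i in 1:60) {
    a <- random_boxes(1)[1, ]
    b <- random_boxes(1)[1, ]
    v <- iou(a, b)
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, iou(b, a))
    # sampling oracle at 220^2 points: absolute accuracy ~ a few 1e-3
    expect_lt(abs(v - iou_raster_oracle(a, b)), 5e-3)
  }
})

test_that("iou_matrix agrees with the scalar IoU", {
  set.seed(42)
  A <- random_boxes(7); B <- random_boxes(5)
  M <- iou_matrix(A, B)
  for (i in 1:7) for (j in 1:5)
    expect_equal(M[i, j], iou(A[i, ], B[j, ]))
})

test_that("encode/decode are exact inverses and self-encoding is zero", {
  set.seed(43)
  priors <- cbind(runif(20, 0.2, 0.8), runif(20, 0.2, 0.8),
                  runif(20, 0.05, 0.3), runif(20, 0.05, 0.3))
  gts <- center_to_corner(cbind(runif(20, 0.3, 0.7), runif(20, 0.3, 0.7),
                                runif(20, 0.05, 0.3), runif(20, 0.05, 0.3)))
  dec <- decode_boxes(encode_boxes(gts, priors), priors)
  expect_equal(unname(dec), unname(gts), tolerance = 1e-12)
  self <- encode_boxes(center_to_corner(priors), priors)
  expect_equal(max(abs(self)), 0, tolerance = 1e-12)
  # hand case: gt (0.4,0.4,0.6,0.6) equals the prior at (0.5,0.5,0.2,0.2)
  expect_equal(as.vector(encode_boxes(c(0.4, 0.4, 0.6, 0.6),
                                      c(0.5, 0.5, 0.2, 0.2))),
               c(0, 0, 0, 0))
})

test_that("matching obeys the threshold rule and forced-best coverage", {
  # prior equal to a ground truth box -> positive with IoU 1
  pri <- matrix(c(0.5, 0.5, 0.2, 0.2), 1)
  m <- match_priors(pri, center_to_corner(pri), 3L)
  expect_equal(m$N, 1L)
  expect_equal(m$class, 3L)
  # no ground truths -> all background
  m0 <- match_priors(pri, matrix(numeric(0), 0, 4), integer(0))
  expect_equal(m0$N, 0L)
  expect_false(any(m0$positive))
  # 4 hand-placed priors vs 2 ground truths: assignment equals exhaustive
  # argmax over the IoU table plus the forced-best rule
  priors <- rbind(c(0.25, 0.25, 0.2, 0.2),
                  c(0.30, 0.25, 0.2, 0.2),
                  c(0.75, 0.75, 0.3, 0.3),
                  c(0.50, 0.50, 0.1, 0.1))
  gts <- rbind(c(0.15, 0.15, 0.35, 0.35), c(0.60, 0.60, 0.90, 0.90))
  labels <- c(2L, 5L)
  m <- match_priors(priors, gts, labels, threshold = 0.5)
  ov <- iou_matrix(center_to_corner(priors), gts)
  expected_gt <- integer(4)
  for (i in 1:4) {
    j <- which.max(ov[i, ])
    expected_gt[i] <- if (ov[i, j] > 0.5) j else 0L
  }
  for (j in 1:2) expected_gt[which.max(ov[, j])] <- j
  expect_equal(m$gt_index, expected_gt)
  expect_equal(m$class, ifelse(expected_gt > 0, labels[pmax(expected_gt, 1)],
                               0L))
  expect_equal(m$N, sum(expected_gt > 0))
})

test_that("every ground truth keeps at least one prior at any threshold", {
  set.seed(44)
  for (rep in 1:10) {
    priors <- corner_to_center(random_boxes(30))
    gts <- random_boxes(4)
    m <- match_priors(priors, gts, rep(1L, 4), threshold = 0.99)
    expect_true(all(1:4 %in% m$gt_index))
  }
})

test_that("NMS equals the brute-force greedy oracle", {
  # two identical boxes: keep the higher score only
  b <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(nms(b, c(0.9, 0.8), 0.45), 1L)
  # disjoint boxes all kept
  b2 <- rbind(c(0, 0, 1, 1), c(2, 2, 3, 3), c(5, 5, 6, 6))
  expect_setequal(nms(b2, c(0.5, 0.9, 0.7), 0.45), 1:3)
  set.seed(45)
  for (rep in 1:12) {
    boxes <- random_boxes(20)
    scores <- runif(20)
    got <- nms(boxes, scores, 0.4)
    expect_identical(got, nms_oracle(boxes, scores, 0.4))
    # survivors are pairwise below the threshold
    if (length(got) > 1) {
      ov <- iou_matrix(boxes[got, ], boxes[got, ])
      diag(ov) <- 0
      expect_true(all(ov <= 0.4 + 1e-12))
    }
  }
  expect_length(nms(random_boxes(20), runif(20), 0.99, top_k = 5L), 5L)
})
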