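make_gt <- function() {
  data.frame(image = 1, x_min = c(0, 10), y_min = 0, x_max = c(5, 15),
             y_max = 5)
}

test_that("average precision reproduces the ranked worked example", {
  gt <- make_gt()
  # perfect single detection on a single ground truth
  one <- data.frame(image = 1, score = 0.9, x_min = 0, y_min = 0,
                    x_max = 5, y_max = 5)
  expect_equal(average_precision(one, gt[1, ]), 1)
  # no detections
  expect_equal(average_precision(one[0, ], gt), 0)
  # no ground truths: undefined
  expect_true(is.na(average_precision(one, gt[0, ])))
  # ranked (TP, FP, TP) over 2 ground truths:
  # precisions 1, 1/2, 2/3 at recalls 1/2, 1/2, 1 -> all-point AP
  # = 0.5 * 1 + 0.5 * (2/3) = 0.8333
  det <- data.frame(image = 1, score = c(0.9, 0.8, 0.7),
                    x_min = c(0, 20, 10), y_min = 0,
                    x_max = c(5, 25, 15), y_max = 5)
  expect_equal(average_precision(det, gt), 0.5 + 0.5 * 2 / 3,
               tolerance = 1e-12)
  # brute-force enumeration oracle on a random instance
  set.seed(51)
  gts <- data.frame(image = rep(1:2, each = 3), random_boxes(6) * 100)
  names(gts)[2:5] <- c("x_min", "y_min", "x_max", "y_max")
  dets <- data.frame(image = sample(1:2, 10, TRUE), score = runif(10),
                     random_boxes(10) * 100)
  names(dets)[3:6] <- c("x_min", "y_min", "x_max", "y_max")
  got <- average_precision(dets, gts)
  # independent recomputation: explicit greedy match + stepwise area
  ord <- order(-dets$score)
  used <- logical(6); tp <- numeric(10)
  for (r in seq_along(ord)) {
    d <- dets[ord[r], ]
    # VOC rule: match against the highest-IoU ground truth of the image;
    # a hit on an already-claimed ground truth is a false positive
    allc <- which(gts$image == d$image)
    va <- vapply(allc, function(j)
      iou(as.numeric(d[c("x_min", "y_min", "x_max", "y_max")]),
          as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")])),
      numeric(1))
    jstar <- allc[which.max(va)]
    if (max(va) >= 0.5 && !used[jstar]) { used[jstar] <- TRUE; tp[r] <- 1 }
  }
  prec <- cumsum(tp) / seq_len(10)
  rec <- cumsum(tp) / 6
  ap_ref <- 0
  mrec <- c(0, rec)
  for (r in seq_len(10))
    if (mrec[r + 1] > mrec[r])
      ap_ref <- ap_ref + (mrec[r + 1] - mrec[r]) * max(prec[r:10])
  expect_equal(got, ap_ref, tolerance = 1e-10)
})

test_that("AP is invariant to detection input order", {
  set.seed(52)
  gts <- data.frame(image = 1, random_boxes(4) * 50)
  names(gts)[2:5] <- c("x_min", "y_min", "x_max", "y_max")
  dets <- data.frame(image = 1, score = round(runif(12), 2),
                     random_boxes(12) * 50)
  names(dets)[3:6] <- c("x_min", "y_min", "x_max", "y_max")
  base <- average_precision(dets, gts)
  # distinct scores: any input order gives the same ranking
  dets$score <- seq(0.99, 0.05, length.out = 12)
  base <- average_precision(dets, gts)
  for (rep in 1:5)
    expect_equal(average_precision(dets[sample(12), ], gts), base)
})

test_that("removing a false positive never decreases AP", {
  gt <- make_gt()
  det <- data.frame(image = 1, score = c(0.9, 0.8, 0.7),
                    x_min = c(0, 20, 10), y_min = 0,
                    x_max = c(5, 25, 15), y_max = 5)
  with_fp <- average_precision(det, gt)
  without_fp <- average_precision(det[-2, ], gt)
  expect_gte(without_fp, with_fp)
})

test_that("group metrics aggregate the six class APs", {
  # synthetic detections: classes 1..3 perfect, 4..6 absent from detections
  set.seed(53)
  gts <- data.frame(image = rep(1, 6), class = 1:6,
                    x_min = seq(0, 100, by = 20), y_min = 0,
                    x_max = seq(10, 110, by = 20), y_max = 10)
  dets <- data.frame(image = 1, class = 1:3, score = 0.9,
                     x_min = gts$x_min[1:3], y_min = 0,
                     x_max = gts$x_max[1:3], y_max = 10)
  r <- evaluate_detections(dets, gts)
  expect_equal(unname(r$ap), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$map, 0.5)
  expect_equal(unname(r$maturity), c(1, 0.5, 0))
  # non-occlusion = mean(AP1, AP3, AP5) = mean(1, 1, 0); occlusion =
  # mean(AP2, AP4, AP6) = mean(1, 0, 0)
  expect_equal(unname(r$occlusion), c(2 / 3, 1 / 3))
  # the merged mode re-evaluates on merged labels: 2 perfect detections
  # against 3 merged non-occluded ground truths -> recall 2/3 at precision 1
  rm2 <- evaluate_detections(dets, gts, group_mode = "merged")
  expect_equal(unname(rm2$occlusion[1]), 2 / 3)
  # mAP is exactly the mean of the available class APs
  expect_equal(r$map, mean(r$ap, na.rm = TRUE))
})

test_that("evaluation results serialise to JSON and a table", {
  gts <- data.frame(image = 1, class = 1L, x_min = 0, y_min = 0,
                    x_max = 10, y_max = 10)
  dets <- data.frame(image = 1, class = 1L, score = 0.9, x_min = 0,
                     y_min = 0, x_max = 10, y_max = 10)
  r <- evaluate_detections(dets, gts)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".txt")
  write_eval_result(r, jp, tp)
  j <- jsonlite::read_json(jp)
  expect_equal(j$ap$tomato1, 1)
  expect_equal(length(readLines(tp)), 2L)
})
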