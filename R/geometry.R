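# Box geometry: IoU, prior <-> ground-truth matching, offset encoding, NMS.

#' Intersection over union of two corner-form boxes
#'
#' Areas are continuous products `(x_max - x_min) * (y_max - y_min)` (no
#' +1 pixel convention); the intersection is clamped at zero so disjoint
#' boxes score exactly 0.
#'
#' @param boxA,boxB Numeric 4-vectors `(x_min, y_min, x_max, y_max)` with
#'   `x_max > x_min`, `y_max > y_min`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(boxA, boxB) {
  for (b in list(boxA, boxB)) {
    if (length(b) != 4L || !(b[3] > b[1]) || !(b[4] > b[2]))
      stop("degenerate box: require x_max > x_min and y_max > y_min")
  }
  iw <- min(boxA[3], boxB[3]) - max(boxA[1], boxB[1])
  ih <- min(boxA[4], boxB[4]) - max(boxA[2], boxB[2])
  if (iw <= 0 || ih <= 0) return(0)
  I <- iw * ih
  aA <- (boxA[3] - boxA[1]) * (boxA[4] - boxA[2])
  aB <- (boxB[3] - boxB[1]) * (boxB[4] - boxB[2])
  unname(I / (aA + aB - I))
}

#' Pairwise IoU matrix between two sets of corner-form boxes
#'
#' @param A N x 4 matrix, `B` M x 4 matrix, both corner-form.
#' @param B See `A`.
#' @return N x M matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  n <- nrow(A); m <- nrow(B)
  ix1 <- pmax(matrix(A[, 1], n, m), matrix(B[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(A[, 2], n, m), matrix(B[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(A[, 3], n, m), matrix(B[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(A[, 4], n, m), matrix(B[, 4], n, m, byrow = TRUE))
  I <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  aA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  aB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  I / (matrix(aA, n, m) + matrix(aB, n, m, byrow = TRUE) - I)
}

#' Encode ground-truth boxes as offsets relative to prior boxes
#'
#' Standard SSD parameterisation: centre deltas scaled by the prior size and
#' the centre variance, log size ratios scaled by the size variance.
#' [decode_boxes()] inverts it exactly.
#'
#' @param gt_boxes N x 4 corner-form ground-truth boxes (or a 4-vector).
#' @param priors N x 4 centre-form priors `(cx, cy, w, h)` (or a 4-vector).
#' @param variances Centre and size variances, default `c(0.1, 0.2)`.
#' @return N x 4 matrix of offsets `(dx, dy, dw, dh)`.
#' @export
encode_boxes <- function(gt_boxes, priors, variances = c(0.1, 0.2)) {
  g <- corner_to_center(gt_boxes)
  p <- rbind(priors)
  cbind((g[, 1] - p[, 1]) / (p[, 3] * variances[1]),
        (g[, 2] - p[, 2]) / (p[, 4] * variances[1]),
        log(g[, 3] / p[, 3]) / variances[2],
        log(g[, 4] / p[, 4]) / variances[2])
}

#' Decode predicted offsets back into corner-form boxes
#'
#' @param offsets N x 4 matrix of predicted offsets `(dx, dy, dw, dh)`.
#' @param priors N x 4 centre-form priors.
#' @param variances Centre and size variances, default `c(0.1, 0.2)`.
#' @return N x 4 corner-form boxes.
#' @export
decode_boxes <- function(offsets, priors, variances = c(0.1, 0.2)) {
  o <- rbind(offsets); p <- rbind(priors)
  cx <- p[, 1] + o[, 1] * variances[1] * p[, 3]
  cy <- p[, 2] + o[, 2] * variances[1] * p[, 4]
  w <- p[, 3] * exp(o[, 3] * variances[2])
  h <- p[, 4] * exp(o[, 4] * variances[2])
  center_to_corner(cbind(cx, cy, w, h))
}

#' Match prior boxes to ground-truth boxes
#'
#' Every prior whose best IoU against the ground truths exceeds `threshold`
#' (strictly) becomes a positive assigned to its argmax ground truth; in
#' addition each ground truth claims its single best-IoU prior regardless of
#' the threshold, so no object is left without a positive.
#'
#' @param priors A `prior_box_set` (or an N x 4 centre-form matrix).
#' @param gt_boxes M x 4 corner-form ground-truth boxes in the same
#'   (normalised) coordinates as the priors; may have zero rows.
#' @param gt_labels Integer class ids (1..6) of length M.
#' @param threshold Positive-match IoU threshold, default 0.5.
#' @param variances Encoding variances, see [encode_boxes()].
#' @return A `match_result`: `gt_index` (0 = background), `class` (0 =
#'   background), `loc_targets` (encoded offsets, rows valid for positives),
#'   `positive` (logical), and `N` (positive count).
#' @export
match_priors <- function(priors, gt_boxes, gt_labels, threshold = 0.5,
                         variances = c(0.1, 0.2)) {
  pc <- if (inherits(priors, "prior_box_set")) priors$boxes else rbind(priors)
  n <- nrow(pc)
  if (n == 0L) stop("empty prior set")
  gt_boxes <- rbind(gt_boxes)
  m <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  res <- list(gt_index = integer(n), class = integer(n),
              loc_targets = matrix(0, n, 4L), positive = logical(n), N = 0L)
  if (m == 0L) return(structure(res, class = "match_result"))
  ov <- iou_matrix(center_to_corner(pc), gt_boxes)
  best_gt <- max.col(ov, ties.method = "first")
  best_val <- ov[cbind(seq_len(n), best_gt)]
  positive <- best_val > threshold
  # forced-best: each ground truth claims its best still-unclaimed prior, so
  # two ground truths sharing one best prior cannot leave either uncovered
  claimed <- integer(0)
  for (j in seq_len(m)) {
    ord <- order(-ov[, j])
    free <- ord[!(ord %in% claimed)]
    if (length(free) == 0L) break          # more ground truths than priors
    i <- free[1L]
    best_gt[i] <- j
    positive[i] <- TRUE
    claimed <- c(claimed, i)
  }
  res$gt_index <- ifelse(positive, best_gt, 0L)
  res$class <- ifelse(positive, gt_labels[best_gt], 0L)
  pos <- which(positive)
  res$loc_targets[pos, ] <- encode_boxes(gt_boxes[best_gt[pos], , drop = FALSE],
                                         pc[pos, , drop = FALSE], variances)
  res$positive <- positive
  res$N <- length(pos)
  structure(res, class = "match_result")
}

#' Greedy non-maximum suppression
#'
#' Keeps detections in descending score order, discarding any box whose IoU
#' with an already-kept box exceeds `iou_threshold`. Ties in score are broken
#' by input index (stable).
#'
#' @param boxes N x 4 corner-form boxes.
#' @param scores Numeric vector of length N.
#' @param iou_threshold Suppression threshold, default 0.45.
#' @param top_k Maximum number of survivors, default 200.
#' @return Integer indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.45, top_k = 200L) {
  boxes <- rbind(boxes)
  if (nrow(boxes) == 0L) return(integer(0))
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  while (length(ord) > 0L && length(keep) < top_k) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (length(ord) > 0L) {
      ovs <- iou_matrix(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])
      ord <- ord[ovs[1L, ] <= iou_threshold]
    }
  }
  keep
}
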