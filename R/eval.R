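# VOC-style average precision and the maturity/occlusion group aggregation.

#' Average precision for one class
#'
#' Score-ranked detections are matched greedily to unmatched ground truths of
#' the same image at IoU >= `iou_threshold` (highest IoU first); duplicate
#' hits on an already-matched ground truth are false positives. AP is the
#' area under the precision-recall curve, by default using all-point
#' interpolation (the monotone precision envelope); the VOC-2007 11-point
#' protocol is available behind `interpolation = "11point"`.
#'
#' @param detections data.frame with columns `image`, `score`, `x_min`,
#'   `y_min`, `x_max`, `y_max`; zero rows allowed.
#' @param ground_truths data.frame with columns `image`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @param iou_threshold Match threshold, default 0.5.
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in `[0, 1]`, or `NA` if there are no ground truths.
#' @examples
#' gt <- data.frame(image = 1, x_min = c(0, 10), y_min = 0,
#'                  x_max = c(5, 15), y_max = 5)
#' det <- data.frame(image = 1, score = c(0.9, 0.8, 0.7),
#'                   x_min = c(0, 20, 10), y_min = 0,
#'                   x_max = c(5, 25, 15), y_max = 5)
#' average_precision(det, gt)  # 0.8333...
#' @export
average_precision <- function(detections, ground_truths, iou_threshold = 0.5,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  n_gt <- nrow(ground_truths)
  if (is.null(n_gt) || n_gt == 0L) return(NA_real_)
  if (is.null(detections) || nrow(detections) == 0L) return(0)
  ord <- order(-detections$score, seq_len(nrow(detections)))
  det <- detections[ord, , drop = FALSE]
  used <- logical(n_gt)
  tp <- numeric(nrow(det))
  cols <- c("x_min", "y_min", "x_max", "y_max")
  for (i in seq_len(nrow(det))) {
    cand <- which(ground_truths$image == det$image[i])
    if (length(cand) > 0L) {
      ovs <- iou_matrix(as.matrix(det[i, cols]),
                        as.matrix(ground_truths[cand, cols]))[1L, ]
      j <- which.max(ovs)
      if (ovs[j] >= iou_threshold && !used[cand[j]]) {
        used[cand[j]] <- TRUE
        tp[i] <- 1
      }
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  if (interpolation == "11point") {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- precision[recall >= r]
      if (length(p) == 0L) 0 else max(p)
    }, numeric(1)))
  } else {
    # monotone envelope over recall, area under the stepwise curve
    mrec <- c(0, recall, 1)
    mpre <- c(0, precision, 0)
    for (i in rev(seq_len(length(mpre) - 1L)))
      mpre[i] <- max(mpre[i], mpre[i + 1L])
    idx <- which(mrec[-1L] != mrec[-length(mrec)])
    sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
  }
}

#' Per-class AP, mAP and maturity/occlusion group metrics
#'
#' Computes AP per class over the six labels (non-occluded/occluded crossed
#' with immature, semi-mature, mature), their mean (mAP over classes present
#' in the ground truth), and group aggregates. Groups are by default means of
#' the member-class APs (immature = classes 1,2; semi-mature = 3,4; mature =
#' 5,6; non-occlusion = 1,3,5; occlusion = 2,4,6); `group_mode = "merged"`
#' instead relabels detections and ground truths onto the merged classes and
#' re-evaluates.
#'
#' @param detections data.frame with columns `image`, `class`, `score`,
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @param ground_truths data.frame with columns `image`, `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @param iou_threshold Match threshold, default 0.5.
#' @param group_mode `"mean"` (default) or `"merged"`.
#' @param interpolation Passed to [average_precision()].
#' @return An `eval_result` with `ap` (length 6, NA for absent classes),
#'   `map`, `maturity` and `occlusion` group vectors.
#' @export
evaluate_detections <- function(detections, ground_truths,
                                iou_threshold = 0.5,
                                group_mode = c("mean", "merged"),
                                interpolation = "all") {
  group_mode <- match.arg(group_mode)
  ap <- vapply(1:6, function(cl) {
    average_precision(detections[detections$class == cl, , drop = FALSE],
                      ground_truths[ground_truths$class == cl, , drop = FALSE],
                      iou_threshold, interpolation)
  }, numeric(1))
  names(ap) <- paste0("tomato", 1:6)
  groups_maturity <- list(immature = c(1L, 2L), semimature = c(3L, 4L),
                          mature = c(5L, 6L))
  groups_occlusion <- list(nonocclusion = c(1L, 3L, 5L),
                           occlusion = c(2L, 4L, 6L))
  agg <- function(groups) {
    vapply(groups, function(cls) {
      if (group_mode == "mean") {
        mean(ap[cls], na.rm = TRUE)
      } else {
        d <- detections; g <- ground_truths
        d <- d[d$class %in% cls, , drop = FALSE]
        g <- g[g$class %in% cls, , drop = FALSE]
        average_precision(d, g, iou_threshold, interpolation)
      }
    }, numeric(1))
  }
  structure(list(ap = ap, map = mean(ap, na.rm = TRUE),
                 maturity = agg(groups_maturity),
                 occlusion = agg(groups_occlusion),
                 group_mode = group_mode),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, digits = 4, ...) {
  cat("Detection evaluation (VOC-style AP at IoU 0.5)\n")
  cat("  per class:\n")
  for (i in seq_along(x$ap))
    cat(sprintf("    %-8s %s\n", names(x$ap)[i],
                ifelse(is.na(x$ap[i]), "absent",
                       formatC(x$ap[i], digits = digits, format = "f"))))
  cat(sprintf("  mAP: %.4f\n", x$map))
  cat(sprintf("  maturity:  immature %.4f  semimature %.4f  mature %.4f\n",
              x$maturity[1], x$maturity[2], x$maturity[3]))
  cat(sprintf("  occlusion: non-occluded %.4f  occluded %.4f\n",
              x$occlusion[1], x$occlusion[2]))
  invisible(x)
}

#' Write an evaluation result as JSON and a plain-text table
#'
#' @param result An `eval_result`.
#' @param json_path,txt_path Output paths; either may be `NULL` to skip.
#' @return `result`, invisibly.
#' @export
write_eval_result <- function(result, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(ap = as.list(result$ap), map = result$map,
           maturity = as.list(result$maturity),
           occlusion = as.list(result$occlusion)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines(paste(c("model", "mAP", names(result$ap)), collapse = "\t"),
               con)
    writeLines(paste(c("rdssd", formatC(c(result$map, result$ap),
                                        digits = 4, format = "f")),
                     collapse = "\t"), con)
  }
  invisible(result)
}
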