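# Multibox objective: softmax confidence loss with hard negative mining,
# smooth-L1 localization loss, and the composite F_loss = (C + L) / N.

# internal: confidence loss with gradient and the mined-prior selection.
conf_loss_impl <- function(conf, match, neg_pos_ratio = 3) {
  conf <- rbind(conf)
  n <- nrow(conf)
  p <- softmax_rows(conf)
  target <- match$class + 1L              # background = column 1
  ce <- -log(pmax(p[cbind(seq_len(n), target)], 1e-12))
  pos <- match$positive
  n_neg <- min(sum(!pos), neg_pos_ratio * match$N)
  sel_neg <- integer(0)
  if (n_neg > 0) {
    negs <- which(!pos)
    sel_neg <- negs[order(-ce[negs], negs)][seq_len(n_neg)]
  }
  sel <- c(which(pos), sel_neg)
  value <- sum(ce[sel])
  grad <- matrix(0, n, ncol(conf))
  if (length(sel) > 0) {
    grad[sel, ] <- p[sel, , drop = FALSE]
    grad[cbind(sel, target[sel])] <- grad[cbind(sel, target[sel])] - 1
  }
  list(value = value, grad = grad, selected = sel)
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

loc_loss_impl <- function(loc, match) {
  loc <- rbind(loc)
  pos <- which(match$positive)
  grad <- matrix(0, nrow(loc), 4L)
  if (length(pos) == 0L) return(list(value = 0, grad = grad))
  d <- loc[pos, , drop = FALSE] - match$loc_targets[pos, , drop = FALSE]
  grad[pos, ] <- smooth_l1_grad(d)
  list(value = sum(smooth_l1(d)), grad = grad)
}

#' Confidence (classification) loss over matched priors
#'
#' Softmax cross-entropy summed over the positive priors plus the hardest
#' background priors, where "hardest" means largest background cross-entropy
#' and at most `neg_pos_ratio` negatives are mined per positive.
#'
#' @param conf N x (1 + n_classes) matrix of raw class scores (background is
#'   column 1).
#' @param match A `match_result` from [match_priors()].
#' @param neg_pos_ratio Mined negatives per positive, default 3.
#' @return The summed confidence loss (not yet divided by N).
#' @export
confidence_loss <- function(conf, match, neg_pos_ratio = 3) {
  conf_loss_impl(conf, match, neg_pos_ratio)$value
}

#' Localization loss over positive priors
#'
#' Smooth-L1 distance between predicted offsets and the encoded ground-truth
#' offsets, summed over positive priors only.
#'
#' @param loc N x 4 matrix of predicted offsets.
#' @param match A `match_result` from [match_priors()].
#' @return The summed localization loss (not yet divided by N).
#' @export
localization_loss <- function(loc, match) {
  loc_loss_impl(loc, match)$value
}

#' Composite multibox loss
#'
#' `F_loss = (C_loss + alpha * L_all_loss) / N` over the fused prior set,
#' where `N` is the positive-match count; an image with no positives
#' contributes zero loss.
#'
#' @param conf N x (1 + n_classes) class scores.
#' @param loc N x 4 predicted offsets.
#' @param match A `match_result`.
#' @param neg_pos_ratio Mined negatives per positive, default 3.
#' @param alpha Weight on the localization term, default 1 (unweighted sum).
#' @return A `loss_breakdown` with `F_loss`, `C_loss`, `L_all_loss` and `N`.
#' @examples
#' pri <- matrix(c(0.5, 0.5, 0.2, 0.2), 1)
#' m <- match_priors(pri, center_to_corner(pri), 1L)
#' multibox_loss(matrix(0, 1, 7), matrix(0, 1, 4), m)
#' @export
multibox_loss <- function(conf, loc, match, neg_pos_ratio = 3, alpha = 1) {
  C <- confidence_loss(conf, match, neg_pos_ratio)
  L <- localization_loss(loc, match)
  F <- if (match$N > 0) (C + alpha * L) / match$N else 0
  structure(list(F_loss = F, C_loss = C, L_all_loss = L, N = match$N),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("multibox loss: F = %.4f (C = %.4f, L = %.4f, N = %d)\n",
              x$F_loss, x$C_loss, x$L_all_loss, x$N))
  invisible(x)
}

# internal: loss + gradients wrt conf and loc for training.
multibox_loss_grad <- function(conf, loc, match, neg_pos_ratio = 3,
                               alpha = 1) {
  cl <- conf_loss_impl(conf, match, neg_pos_ratio)
  ll <- loc_loss_impl(loc, match)
  if (match$N > 0) {
    list(F_loss = (cl$value + alpha * ll$value) / match$N,
         C_loss = cl$value, L_all_loss = ll$value, N = match$N,
         gconf = cl$grad / match$N, gloc = alpha * ll$grad / match$N)
  } else {
    list(F_loss = 0, C_loss = cl$value, L_all_loss = 0, N = 0L,
         gconf = conf * 0, gloc = loc * 0)
  }
}
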