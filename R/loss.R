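## Composite detection objective: Focal classification loss + L1 box loss +
## generalized-IoU loss, each with analytic gradients for the training loop.

FOCAL_EPS <- 1e-8

#' Focal classification loss
#'
#' `L_cls = sum_i -alpha_t (1 - p_t)^gamma log(p_t)`, where `p_t = p` and
#' `alpha_t = alpha` for foreground queries and `1 - p`, `1 - alpha` for
#' background. The `(1 - p_t)^gamma` factor down-weights easy examples so
#' the abundant, easily rejected background queries do not dominate the
#' gradient. The sum runs over all queries and is normalized by the number
#' of matched (foreground) queries to stay commensurate with the box terms.
#'
#' @param scores Predicted foreground probabilities in (0, 1); clamped to
#'   `[1e-8, 1 - 1e-8]`.
#' @param labels Logical vector, TRUE for foreground queries.
#' @param alpha Foreground balancing factor in (0, 1) (default 0.25).
#' @param gamma Focusing exponent >= 0 (default 2).
#' @param n_matched Normalizer; defaults to `max(1, sum(labels))`.
#' @return Scalar loss.
#' @export
focal_loss <- function(scores, labels, alpha = 0.25, gamma = 2,
                       n_matched = max(1L, sum(labels))) {
  stopifnot(alpha > 0, alpha < 1, gamma >= 0)
  p <- pmin(pmax(scores, FOCAL_EPS), 1 - FOCAL_EPS)
  pt <- ifelse(labels, p, 1 - p)
  at <- ifelse(labels, alpha, 1 - alpha)
  sum(-at * (1 - pt)^gamma * log(pt)) / n_matched
}

## dL/dp for the focal loss (same conventions); vectorized
focal_loss_grad <- function(scores, labels, alpha = 0.25, gamma = 2,
                            n_matched = max(1L, sum(labels))) {
  p <- pmin(pmax(scores, FOCAL_EPS), 1 - FOCAL_EPS)
  pt <- ifelse(labels, p, 1 - p)
  at <- ifelse(labels, alpha, 1 - alpha)
  focus <- if (gamma == 0) rep(0, length(p)) else
    gamma * (1 - pt)^(gamma - 1) * log(pt)
  dpt <- at * (focus - (1 - pt)^gamma / pt)
  dpt * ifelse(labels, 1, -1) / n_matched
}

#' L1 box regression loss
#'
#' Mean over matched pairs of the four-term absolute coordinate difference,
#' in normalized center form.
#'
#' @param pred,target N x 4 normalized center-form box matrices of matched
#'   pairs. Zero matched pairs contribute 0.
#' @return Scalar loss.
#' @export
l1_box_loss <- function(pred, target) {
  pred <- rbind(pred); target <- rbind(target)
  if (nrow(pred) == 0) return(0)
  mean(rowSums(abs(pred - target)))
}

#' Generalized-IoU box loss
#'
#' `L_GIoU = mean(1 - GIoU(pred_i, target_i))` over matched pairs; range
#' `[0, 2]`.
#'
#' @inheritParams l1_box_loss
#' @return Scalar loss.
#' @export
giou_loss <- function(pred, target) {
  pred <- rbind(pred); target <- rbind(target)
  if (nrow(pred) == 0) return(0)
  mean(1 - giou(norm_box_corners(pred), norm_box_corners(target)))
}

#' Weighted total detection loss
#'
#' @param l_cls,l_l1,l_giou Component losses.
#' @param weights A [loss_weights()] list.
#' @param n_matched Matched-pair count retained in the breakdown.
#' @return A list of class `loss_breakdown` with `l_cls`, `l_l1`, `l_giou`,
#'   `l_total` and `n_matched`; `l_total` is the exact weighted sum.
#' @export
total_loss <- function(l_cls, l_l1, l_giou, weights = loss_weights(),
                       n_matched = NA_integer_) {
  stopifnot(is.finite(l_cls), is.finite(l_l1), is.finite(l_giou))
  structure(list(
    l_cls = l_cls, l_l1 = l_l1, l_giou = l_giou,
    l_total = weights$lambda_cls * l_cls + weights$lambda_l1 * l_l1 +
      weights$lambda_giou * l_giou,
    n_matched = n_matched), class = "loss_breakdown")
}

#' Detection loss for one set of predictions
#'
#' Assigns queries to ground-truth boxes with [group_assign()], evaluates
#' the three loss components and (optionally) their gradients with respect
#' to the predicted scores and boxes.
#'
#' @param scores,boxes Predictions for all Q queries.
#' @param targets T x 4 ground-truth matrix (zero rows allowed).
#' @param group_of Query-to-group map.
#' @param weights [loss_weights()].
#' @param alpha,gamma Focal-loss parameters.
#' @param with_grad Also return `dscores` (length Q) and `dboxes` (Q x 4),
#'   the gradients of `l_total`.
#' @return A `loss_breakdown` (plus `match`, and gradients when requested).
#' @export
detection_loss <- function(scores, boxes, targets, group_of,
                           weights = loss_weights(), alpha = 0.25,
                           gamma = 2, with_grad = FALSE) {
  m <- group_assign(scores, boxes, targets, group_of, weights)
  n_matched <- nrow(m$pairs)
  norm <- max(1L, n_matched)
  l_cls <- focal_loss(scores, m$labels, alpha, gamma, n_matched = norm)
  if (n_matched > 0) {
    bp <- boxes[m$pairs[, "query"], , drop = FALSE]
    bt <- rbind(targets)[m$pairs[, "target"], , drop = FALSE]
    l_l1 <- l1_box_loss(bp, bt)
    l_gi <- giou_loss(bp, bt)
  } else {
    l_l1 <- 0; l_gi <- 0
  }
  out <- total_loss(l_cls, l_l1, l_gi, weights, n_matched)
  out$match <- m
  if (with_grad) {
    Q <- length(scores)
    dscores <- weights$lambda_cls *
      focal_loss_grad(scores, m$labels, alpha, gamma, n_matched = norm)
    dboxes <- matrix(0, Q, 4)
    if (n_matched > 0) {
      qi <- m$pairs[, "query"]
      # L1 term
      dl1 <- sign(bp - bt) / n_matched
      # GIoU term through the center-form -> corner-form map
      gg <- giou_with_grad(norm_box_corners(bp), norm_box_corners(bt))
      dcor <- -gg$grad / n_matched
      dgi <- cbind(dcor[, 1] + dcor[, 3],
                   dcor[, 2] + dcor[, 4],
                   (dcor[, 3] - dcor[, 1]) / 2,
                   (dcor[, 4] - dcor[, 2]) / 2)
      contrib <- weights$lambda_l1 * dl1 + weights$lambda_giou * dgi
      for (k in seq_len(n_matched))
        dboxes[qi[k], ] <- dboxes[qi[k], ] + contrib[k, ]
    }
    out$dscores <- dscores
    out$dboxes <- dboxes
  }
  out
}
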