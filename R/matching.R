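#' Loss-term weights
#'
#' Weights of the composite objective
#' `L_total = lambda_cls * L_cls + lambda_l1 * L_L1 + lambda_giou * L_GIoU`.
#' Defaults follow the DETR-family convention (2, 5, 2).
#'
#' @param lambda_cls,lambda_l1,lambda_giou Nonnegative weights; not all zero.
#' @export
loss_weights <- function(lambda_cls = 2, lambda_l1 = 5, lambda_giou = 2) {
  stopifnot(lambda_cls >= 0, lambda_l1 >= 0, lambda_giou >= 0,
            lambda_cls + lambda_l1 + lambda_giou > 0)
  list(lambda_cls = lambda_cls, lambda_l1 = lambda_l1,
       lambda_giou = lambda_giou)
}

norm_box_corners <- function(b) {
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' Matching cost between predictions and ground-truth boxes
#'
#' `cost = w_cls * (-score) + w_l1 * ||b_hat - b||_1 + w_giou * (1 - GIoU)`,
#' computed for every (prediction, target) pair; the classification term uses
#' the foreground probability directly. Weights default to the loss weights.
#'
#' @param scores Predicted foreground probabilities (length n).
#' @param boxes n x 4 normalized center-form prediction matrix.
#' @param targets m x 4 normalized center-form ground-truth matrix.
#' @param weights A [loss_weights()] list.
#' @return n x m cost matrix.
#' @export
match_cost <- function(scores, boxes, targets, weights = loss_weights()) {
  boxes <- rbind(boxes); targets <- rbind(targets)
  n <- nrow(boxes); m <- nrow(targets)
  l1 <- matrix(0, n, m)
  for (j in seq_len(m))
    l1[, j] <- rowSums(abs(sweep(boxes, 2, targets[j, ], "-")))
  g <- giou_pairwise(norm_box_corners(boxes), norm_box_corners(targets))
  weights$lambda_cls * (-scores) + weights$lambda_l1 * l1 +
    weights$lambda_giou * (1 - g)
}

#' Minimum-cost bipartite assignment
#'
#' Solves the Hungarian assignment for a queries x targets cost matrix.
#' When there are at least as many queries as targets every target is
#' matched; with more targets than queries only `nrow(cost)` targets can be
#' matched (a warning is issued).
#'
#' @param cost Numeric matrix of finite costs (rows = queries,
#'   columns = targets).
#' @return Integer matrix with columns `query`, `target` (1-based), ordered
#'   by target index.
#' @export
hungarian_match <- function(cost) {
  cost <- rbind(cost)
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  nq <- nrow(cost); nt <- ncol(cost)
  if (nt == 0 || nq == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("query", "target"))))
  shifted <- cost - min(cost)   # LSAP solver requires nonnegative entries
  if (nt <= nq) {
    sol <- clue::solve_LSAP(t(shifted))
    pairs <- cbind(query = as.integer(sol), target = seq_len(nt))
  } else {
    warning("more targets (", nt, ") than queries (", nq,
            "); only ", nq, " targets matched")
    sol <- clue::solve_LSAP(shifted)
    pairs <- cbind(query = seq_len(nq), target = as.integer(sol))
    pairs <- pairs[order(pairs[, "target"]), , drop = FALSE]
  }
  pairs
}

#' Group-wise one-to-many label assignment
#'
#' Runs Hungarian matching independently within each query group, so a
#' ground-truth particle can collect up to G positive queries (one per
#' group) while assignment stays one-to-one inside a group — the one-to-many
#' supervision that raises recall in densely packed scenes.
#'
#' @param scores Length-Q predicted foreground probabilities.
#' @param boxes Q x 4 normalized center-form prediction matrix.
#' @param targets T x 4 ground-truth matrix (possibly zero rows).
#' @param group_of Length-Q integer map from query index to group id.
#' @param weights A [loss_weights()] used as matching-cost weights.
#' @return A list of class `match_result`: `pairs` (global query index,
#'   target index), `per_group` (the same split by group), and `labels`
#'   (logical length Q, TRUE for matched/foreground queries).
#' @export
group_assign <- function(scores, boxes, targets, group_of,
                         weights = loss_weights()) {
  Q <- length(scores)
  stopifnot(length(group_of) == Q)
  targets <- rbind(targets)
  groups <- sort(unique(group_of))
  per_group <- list()
  pairs <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("query", "target")))
  if (nrow(targets) > 0) {
    cost <- match_cost(scores, boxes, targets, weights)
    for (g in groups) {
      idx <- which(group_of == g)
      pg <- hungarian_match(cost[idx, , drop = FALSE])
      pg[, "query"] <- idx[pg[, "query"]]
      per_group[[as.character(g)]] <- pg
      pairs <- rbind(pairs, pg)
    }
  } else {
    for (g in groups)
      per_group[[as.character(g)]] <-
        matrix(integer(0), 0, 2, dimnames = list(NULL, c("query", "target")))
  }
  labels <- rep(FALSE, Q)
  labels[pairs[, "query"]] <- TRUE
  structure(list(pairs = pairs, per_group = per_group, labels = labels),
            class = "match_result")
}
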