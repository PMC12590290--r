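#' Precision, recall and F1 from match counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, `F1 = 2PR / (P + R)`; each is
#' 0 when its denominator is 0. Values are exact; rounding (3 decimals,
#' half-up) happens only at presentation via [format.eval_report()].
#'
#' @param tp,fp,fn Nonnegative counts.
#' @param criterion Description of the matching rule (carried in the
#'   report).
#' @return A list of class `eval_report`.
#' @export
compute_prf <- function(tp, fp, fn, criterion = "") {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, criterion = criterion),
            class = "eval_report")
}

#' Round half-up at a given number of decimals
#'
#' Presentation rounding for reported metrics (base `round()` rounds half to
#' even).
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
format.eval_report <- function(x, ...) {
  sprintf("P=%.3f R=%.3f F1=%.3f (tp=%d fp=%d fn=%d)%s",
          round_half_up(x$precision), round_half_up(x$recall),
          round_half_up(x$f1), x$tp, x$fp, x$fn,
          if (nzchar(x$criterion)) paste0(" [", x$criterion, "]") else "")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## match one micrograph's picks (data.frame with x, y, score and optional
## w, h in pixels) against a truth box matrix (normalized); greedy in
## descending score order, earlier index wins on ties.
match_picks_single <- function(picks, truth_boxes, width, height,
                               criterion = c("center", "iou"),
                               radius_scale = 0.5, iou_threshold = 0.5) {
  criterion <- match.arg(criterion)
  truth_boxes <- rbind(truth_boxes)
  n_truth <- nrow(truth_boxes)
  n_pred <- nrow(picks)
  if (n_pred == 0) return(c(tp = 0L, fp = 0L, fn = n_truth))
  if (n_truth == 0) return(c(tp = 0L, fp = n_pred, fn = 0L))
  tx <- truth_boxes[, 1] * width
  ty <- truth_boxes[, 2] * height
  tside <- (truth_boxes[, 3] * width + truth_boxes[, 4] * height) / 2
  claimed <- rep(FALSE, n_truth)
  ord <- order(-picks$score)
  tp <- 0L
  if (criterion == "iou") {
    if (is.null(picks$w) || any(!is.finite(picks$w)))
      stop("IoU criterion requires pick boxes (w, h)")
    tcorn <- box_to_pixels(norm_box(truth_boxes[, 1], truth_boxes[, 2],
                                    truth_boxes[, 3], truth_boxes[, 4]),
                           width, height)
  }
  for (i in ord) {
    open <- which(!claimed)
    if (length(open) == 0) break
    if (criterion == "center") {
      d <- sqrt((tx[open] - picks$x[i])^2 + (ty[open] - picks$y[i])^2)
      ok <- d <= radius_scale * tside[open]
      if (any(ok)) {
        j <- open[ok][which.min(d[ok])]
        claimed[j] <- TRUE
        tp <- tp + 1L
      }
    } else {
      pc <- cbind(picks$x[i] - picks$w[i] / 2, picks$y[i] - picks$h[i] / 2,
                  picks$x[i] + picks$w[i] / 2, picks$y[i] + picks$h[i] / 2)
      ious <- iou(pc[rep(1, length(open)), , drop = FALSE],
                  unclass(tcorn)[open, , drop = FALSE])
      if (any(ious >= iou_threshold)) {
        j <- open[which.max(ious)]
        claimed[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  c(tp = tp, fp = n_pred - tp, fn = n_truth - tp)
}

#' Match picked particles against ground truth
#'
#' Greedy one-to-one matching with predictions taken in descending score
#' order: a prediction claims the nearest unclaimed truth particle whose
#' center lies within the criterion radius (default: half the truth box's
#' mean side), or — in IoU mode — the best-overlapping unclaimed truth with
#' IoU at or above the threshold. Unmatched predictions count as false
#' positives, unclaimed truths as false negatives.
#'
#' @param picks Pick data.frame (from [pick()] or [read_star()] via
#'   [picks_from_star()]) with `micrograph_name`, `x`, `y`, `score`.
#' @param truth An [annotation_set()].
#' @param criterion "center" (distance) or "iou".
#' @param radius_scale Center criterion: multiple of the truth box mean
#'   side used as match radius.
#' @param iou_threshold IoU criterion threshold.
#' @return Named integer vector `(tp, fp, fn)`.
#' @export
match_picks <- function(picks, truth, criterion = c("center", "iou"),
                        radius_scale = 0.5, iou_threshold = 0.5) {
  criterion <- match.arg(criterion)
  evaluate_dataset(picks, truth, criterion, radius_scale,
                   iou_threshold)$counts
}

#' Evaluate picks over a dataset
#'
#' Counts are pooled over micrographs before computing precision/recall/F1
#' (micro-averaging); a per-micrograph table is retained for diagnostics.
#' Truth micrographs with no picks at all count as all-false-negative.
#'
#' @inheritParams match_picks
#' @return List with `report` (pooled [compute_prf()] result),
#'   `per_micrograph` (data.frame) and `counts` (pooled tp/fp/fn).
#' @export
evaluate_dataset <- function(picks, truth, criterion = c("center", "iou"),
                             radius_scale = 0.5, iou_threshold = 0.5) {
  criterion <- match.arg(criterion)
  mics <- union(truth$images$micrograph_id, unique(picks$micrograph_name))
  rows <- list()
  for (m in mics) {
    tb <- boxes_for(truth, m)
    irow <- match(m, truth$images$micrograph_id)
    if (is.na(irow))
      stop("picks reference micrograph absent from truth: ", m)
    pm <- picks[picks$micrograph_name == m, , drop = FALSE]
    cnt <- match_picks_single(pm, tb, truth$images$width[irow],
                              truth$images$height[irow], criterion,
                              radius_scale, iou_threshold)
    rows[[m]] <- data.frame(micrograph_id = m, tp = cnt["tp"],
                            fp = cnt["fp"], fn = cnt["fn"],
                            row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  crit_label <- if (criterion == "center")
    sprintf("center distance <= %.2f x mean truth box side", radius_scale)
  else sprintf("IoU >= %.2f", iou_threshold)
  counts <- c(tp = sum(tab$tp), fp = sum(tab$fp), fn = sum(tab$fn))
  list(report = compute_prf(counts["tp"], counts["fp"], counts["fn"],
                            crit_label),
       per_micrograph = tab, counts = counts)
}

#' Macro-average evaluation reports across datasets
#'
#' The arithmetic mean of per-dataset precision, recall and F1 — the
#' "Average" row convention when reporting several benchmark datasets
#' side by side.
#'
#' @param reports List of `eval_report` objects.
#' @return data.frame with the per-dataset metrics and a final "average"
#'   row.
#' @export
average_reports <- function(reports) {
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(dataset = names(reports)[i] %||% as.character(i),
               precision = r$precision, recall = r$recall, f1 = r$f1)
  }))
  rbind(df, data.frame(dataset = "average",
                       precision = mean(df$precision),
                       recall = mean(df$recall), f1 = mean(df$f1)))
}

#' Convert a read STAR table to a pick data.frame
#'
#' @param star data.frame from [read_star()].
#' @export
picks_from_star <- function(star) {
  data.frame(micrograph_name = star$rlnMicrographName,
             x = star$rlnCoordinateX, y = star$rlnCoordinateY,
             score = star$rlnAutopickFigureOfMerit,
             w = NA_real_, h = NA_real_, stringsAsFactors = FALSE)
}
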