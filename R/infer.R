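#' Inference configuration
#'
#' @param score_threshold Minimum foreground probability for a pick, or
#'   `NULL` to use the threshold calibrated on the validation split during
#'   training (falling back to 0.5 for uncalibrated models).
#' @param dedup_radius Duplicate-suppression radius as a fraction of the
#'   mean ground-truth box side learned at training time; grouped
#'   one-to-many training deliberately produces duplicate detections, so
#'   inference suppresses any pick whose center falls within this radius of
#'   an already-accepted higher-scoring pick.
#' @param group_mode "all_merged" pools predictions from every query group
#'   before deduplication; "first_group" keeps only group 1.
#' @export
infer_config <- function(score_threshold = NULL, dedup_radius = 0.5,
                         group_mode = c("all_merged", "first_group")) {
  if (!is.null(score_threshold))
    stopifnot(score_threshold >= 0, score_threshold <= 1)
  stopifnot(dedup_radius >= 0)
  structure(list(score_threshold = score_threshold,
                 dedup_radius = dedup_radius,
                 group_mode = match.arg(group_mode)),
            class = "gtpick_infer_config")
}

## greedy score-descending center suppression; returns indices kept
dedup_centers <- function(x, y, scores, radius) {
  ord <- order(-scores)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all((x[keep] - x[i])^2 + (y[keep] - y[i])^2 > radius^2))
      keep <- c(keep, i)
  }
  sort(keep)
}

#' Pick particles in a micrograph
#'
#' Runs the detector on the (resized) micrograph, keeps final-layer
#' predictions with score at or above the threshold, applies the group mode
#' and duplicate suppression, and maps box centers back to ORIGINAL
#' micrograph pixel coordinates.
#'
#' @param model A trained `gtpick_model` (with `input_size` and
#'   `mean_box_side` attached by [train_detector()]).
#' @param record A [micrograph()].
#' @param cfg An [infer_config()].
#' @return data.frame of picks: `micrograph_name`, `x`, `y` (pixel centers,
#'   origin top-left), `score`, `w`, `h` (box size in pixels). Possibly
#'   zero rows.
#' @export
pick <- function(model, record, cfg = infer_config()) {
  input_size <- model$input_size %||% 640L
  threshold <- cfg$score_threshold %||% model$score_threshold %||% 0.5
  img <- record$image
  if (abs(mean(img)) > 1e-8 || abs(stats::sd(img) - 1) > 1e-6)
    img <- standardize_image(img)
  if (nrow(img) != input_size || ncol(img) != input_size)
    img <- resize_image(img, input_size, input_size)
  preds <- model_forward_single(model, img, training = FALSE)$preds
  final <- preds[[length(preds)]]
  sel <- final$scores >= threshold
  if (cfg$group_mode == "first_group") sel <- sel & model$group_of == 1L
  idx <- which(sel)
  empty <- data.frame(micrograph_name = character(0), x = numeric(0),
                      y = numeric(0), score = numeric(0), w = numeric(0),
                      h = numeric(0), stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)
  boxes <- final$boxes[idx, , drop = FALSE]
  scores <- final$scores[idx]
  x <- boxes[, 1] * record$width
  y <- boxes[, 2] * record$height
  mean_side_px <- (model$mean_box_side %||% 0.1) *
    (record$width + record$height) / 2
  keep <- dedup_centers(x, y, scores, cfg$dedup_radius * mean_side_px)
  data.frame(micrograph_name = record$micrograph_id,
             x = x[keep], y = y[keep], score = scores[keep],
             w = boxes[keep, 3] * record$width,
             h = boxes[keep, 4] * record$height,
             stringsAsFactors = FALSE)
}

#' Pick particles across micrographs and export a STAR file
#'
#' @param model A trained model.
#' @param records List of [micrograph()] records.
#' @param cfg [infer_config()].
#' @param out_star Optional STAR output path.
#' @return Combined pick data.frame (invisibly writes the STAR file when
#'   `out_star` is given).
#' @export
pick_dataset <- function(model, records, cfg = infer_config(),
                         out_star = NULL) {
  picks <- do.call(rbind, lapply(records, function(r) pick(model, r, cfg)))
  if (is.null(picks)) picks <- pick(model, records[[1]], infer_config(1))
  message("picked ", nrow(picks), " particles across ", length(records),
          " micrographs")
  if (!is.null(out_star)) write_star(particles_to_star_df(picks), out_star)
  picks
}

`%||%` <- function(a, b) if (is.null(a)) b else a
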