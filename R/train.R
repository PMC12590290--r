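#' Training configuration
#'
#' Defaults follow the full-size training recipe: 640 px inputs, AdamW with
#' learning rate 1e-4 (backbone 1e-5), weight decay 1e-4, batch size 2,
#' Xavier initialization for non-backbone weights. The seed covers
#' parameter initialization, data order, and augmentation draws, so a fixed
#' seed reproduces the loss history exactly on CPU.
#'
#' @param input_size Model input side in pixels (images are resized whole).
#' @param lr_main,lr_backbone Learning rates for non-backbone / backbone
#'   parameters.
#' @param weight_decay Decoupled (AdamW) weight decay.
#' @param batch_size Images per optimizer step.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param augment_flips Random horizontal/vertical flips during training.
#' @param loss [loss_weights()].
#' @param focal_alpha,focal_gamma Focal-loss parameters.
#' @param objectness_aux Add a dense auxiliary objective during training: a
#'   per-cell objectness head on the encoder memory is supervised with
#'   "does a particle center fall in this cell" (focal loss). This trains
#'   the backbone and encoder features directly and speeds up convergence;
#'   it does not change the detector's predictions.
#' @param objectness_weight Weight of the auxiliary objectness term.
#' @export
train_config <- function(input_size = 640L, lr_main = 1e-4,
                         lr_backbone = 1e-5, weight_decay = 1e-4,
                         batch_size = 2L, epochs = 20L, seed = 1L,
                         augment_flips = TRUE, loss = loss_weights(),
                         focal_alpha = 0.25, focal_gamma = 2,
                         objectness_aux = TRUE, objectness_weight = 1) {
  stopifnot(lr_main > 0, lr_backbone > 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 1, objectness_weight >= 0)
  structure(list(input_size = as.integer(input_size), lr_main = lr_main,
                 lr_backbone = lr_backbone, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment_flips = isTRUE(augment_flips), loss = loss,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 objectness_aux = isTRUE(objectness_aux),
                 objectness_weight = objectness_weight),
            class = "gtpick_train_config")
}

## ---- trainable-parameter bookkeeping ---------------------------------------
## Trainable leaves are numeric vectors/matrices in the nested parameter
## list, excluding frozen-normalization buffers (any node named "norm") and
## structural scalars.

NON_TRAINABLE_LEAF <- c("k", "c_in", "c_out", "stride", "eps", "name",
                        "frozen")

get_path <- function(x, path) {
  for (p in path) x <- if (grepl("^[0-9]+$", p)) x[[as.integer(p)]] else x[[p]]
  x
}

assign_path <- function(x, path, value) {
  p <- path[1]
  key <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
  if (length(path) == 1) {
    x[[key]] <- value
  } else {
    x[[key]] <- assign_path(x[[key]], path[-1], value)
  }
  x
}

## handle unnamed stacks (enc/dec/blocks/stages are unnamed lists)
collect_paths <- function(params) {
  walk <- function(x, prefix) {
    out <- list()
    if (!is.list(x)) {
      return(list(prefix))
    }
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      if (nm %in% c("norm", NON_TRAINABLE_LEAF)) next
      child <- x[[i]]
      if (is.list(child)) {
        out <- c(out, walk(child, c(prefix, nm)))
      } else if (is.numeric(child)) {
        out <- c(out, list(c(prefix, nm)))
      }
    }
    out
  }
  walk(params, character(0))
}

## ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params, paths) {
  lapply(paths, function(p) {
    v <- get_path(params, p)
    list(m = v * 0, v = v * 0)
  })
}

adamw_step <- function(params, grads, state, paths, lrs, weight_decay,
                       t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    g <- get_path(grads, p)
    if (is.null(g)) next
    w <- get_path(params, p)
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[i]] <- st
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    w <- w - lrs[i] * (upd + weight_decay * w)
    params <- assign_path(params, p, w)
  }
  list(params = params, state = state)
}

## ---- loss over a batch, wired through the network --------------------------

## images: list of standardized matrices; targets: list of T x 4 matrices.
## Returns summed-over-layers loss breakdown (averaged over the batch) and
## parameter gradients.
model_loss_and_grads <- function(model, images, targets, cfg,
                                 with_grad = TRUE) {
  B <- length(images)
  L <- length(model$params$dec)
  sup_layers <- if (model$config$aux_loss) seq_len(L) else L
  acc <- c(l_cls = 0, l_l1 = 0, l_giou = 0)
  l_obj <- 0
  n_matched <- 0L
  total_grads <- NULL
  for (b in seq_len(B)) {
    fwd <- model_forward_single(model, images[[b]], training = with_grad,
                                keep_cache = with_grad)
    dpreds <- vector("list", L)
    for (l in sup_layers) {
      pl <- fwd$preds[[l]]
      dl <- detection_loss(pl$scores, pl$boxes, targets[[b]],
                           model$group_of, cfg$loss, cfg$focal_alpha,
                           cfg$focal_gamma, with_grad = with_grad)
      if (!is.finite(dl$l_total))
        stop("non-finite loss at layer ", l, " (batch item ", b, ")")
      acc <- acc + c(dl$l_cls, dl$l_l1, dl$l_giou) / B
      if (l == L) n_matched <- n_matched + dl$n_matched
      if (with_grad)
        dpreds[[l]] <- list(dscores = dl$dscores / B, dboxes = dl$dboxes / B)
    }
    dobj <- NULL
    if (isTRUE(cfg$objectness_aux) && cfg$objectness_weight > 0) {
      lab <- cell_occupancy(targets[[b]], fwd$grid["H"], fwd$grid["W"])
      l_obj_b <- focal_loss(fwd$objectness, lab, cfg$focal_alpha,
                            cfg$focal_gamma)
      l_obj <- l_obj + cfg$objectness_weight * l_obj_b / B
      if (with_grad)
        dobj <- cfg$objectness_weight / B *
          focal_loss_grad(fwd$objectness, lab, cfg$focal_alpha,
                          cfg$focal_gamma)
    }
    if (with_grad) {
      g <- model_backward_single(model, fwd, dpreds, dobj = dobj)
      total_grads <- if (is.null(total_grads)) g else add_grads(total_grads, g)
    }
  }
  breakdown <- total_loss(acc["l_cls"], acc["l_l1"], acc["l_giou"],
                          cfg$loss, n_matched)
  breakdown$l_obj <- l_obj
  list(breakdown = breakdown, grads = total_grads)
}

## logical occupancy label per feature cell: TRUE iff a ground-truth center
## falls inside the cell (column-major, row index fastest)
cell_occupancy <- function(targets, H, W) {
  lab <- rep(FALSE, H * W)
  targets <- rbind(targets)
  if (nrow(targets) > 0) {
    ci <- pmin(H - 1, floor(targets[, 2] * H))
    cj <- pmin(W - 1, floor(targets[, 1] * W))
    lab[cj * H + ci + 1] <- TRUE
  }
  lab
}

## ---- training loop ---------------------------------------------------------

#' Train a particle detector
#'
#' Builds a model (unless one is supplied) and optimizes the composite
#' Focal + L1 + GIoU objective with AdamW, using group-wise one-to-many
#' Hungarian assignment for supervision. Per-epoch loss components are
#' recorded; the checkpoint with the best validation F1 (at the default
#' center-distance criterion) is retained. Fully seeded: the same seed
#' yields the same loss history on CPU.
#'
#' @param data_train,data_val Lists of samples, each `list(record, boxes)`
#'   with `record` a [micrograph()] and `boxes` a normalized ground-truth
#'   matrix (e.g. from [synthetic_benchmark()] or [load_coco_dataset()]).
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @param infer_cfg [infer_config()] used for validation picking.
#' @param model Optional pre-built model (its config wins).
#' @param verbose Print per-epoch progress.
#' @return A `gtpick_model` (best validation checkpoint) with `history`
#'   (per-epoch data.frame of loss components and validation F1),
#'   `input_size` and `mean_box_side` attached.
#' @export
train_detector <- function(data_train, data_val = list(),
                           model_cfg = model_config(),
                           cfg = train_config(),
                           infer_cfg = infer_config(),
                           model = NULL, verbose = TRUE) {
  if (length(data_train) == 0) stop("empty training dataset")
  set.seed(cfg$seed)
  if (is.null(model)) model <- build_model(model_cfg)
  model$input_size <- cfg$input_size
  sides <- unlist(lapply(data_train, function(s)
    if (nrow(s$boxes) > 0) (s$boxes[, 3] + s$boxes[, 4]) / 2))
  model$mean_box_side <- if (length(sides)) mean(sides) else 0.1

  paths <- collect_paths(model$params)
  is_backbone <- vapply(paths, function(p) p[1] == "backbone", logical(1))
  lrs <- ifelse(is_backbone, cfg$lr_backbone, cfg$lr_main)
  state <- adamw_init(model$params, paths)

  n <- length(data_train)
  history <- list()
  best_f1 <- -Inf
  best_model <- model
  t_step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep <- c(l_cls = 0, l_l1 = 0, l_giou = 0, l_total = 0, l_obj = 0)
    n_batches <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      batch <- lapply(data_train[idx], prepare_sample, cfg = cfg,
                      training = TRUE)
      lg <- model_loss_and_grads(model,
                                 lapply(batch, `[[`, "image"),
                                 lapply(batch, `[[`, "boxes"), cfg)
      t_step <- t_step + 1L
      st <- adamw_step(model$params, lg$grads, state, paths, lrs,
                       cfg$weight_decay, t_step)
      model$params <- st$params
      state <- st$state
      ep <- ep + c(lg$breakdown$l_cls, lg$breakdown$l_l1,
                   lg$breakdown$l_giou, lg$breakdown$l_total,
                   lg$breakdown$l_obj)
      n_batches <- n_batches + 1L
    }
    ep <- ep / n_batches
    val_f1 <- NA_real_
    if (length(data_val) > 0) {
      val_f1 <- validation_f1(model, data_val, infer_cfg)
      if (val_f1 >= best_f1) {
        best_f1 <- val_f1
        best_model <- model
      }
    } else {
      best_model <- model
    }
    history[[epoch]] <- data.frame(epoch = epoch, l_cls = ep["l_cls"],
                                   l_l1 = ep["l_l1"], l_giou = ep["l_giou"],
                                   l_total = ep["l_total"], l_obj = ep["l_obj"],
                                   val_f1 = val_f1, row.names = NULL)
    if (verbose)
      message(sprintf(
        "epoch %3d  cls %.4f  l1 %.4f  giou %.4f  total %.4f  val F1 %s",
        epoch, ep["l_cls"], ep["l_l1"], ep["l_giou"], ep["l_total"],
        ifelse(is.na(val_f1), "-", sprintf("%.3f", val_f1))))
  }
  best_model$history <- do.call(rbind, history)
  if (length(data_val) > 0)
    best_model$score_threshold <- calibrate_threshold(best_model, data_val,
                                                      infer_cfg)
  best_model
}

#' Calibrate the pick score threshold on held-out data
#'
#' Sweeps the score threshold and returns the value maximizing pooled F1
#' (ties resolved toward the lower threshold, i.e. higher recall).
#' [train_detector()] runs this on the validation split and stores the
#' result in the checkpoint; [pick()] uses it when no explicit threshold is
#' configured.
#'
#' @param model Trained model.
#' @param data_val Validation samples (`list(record, boxes)` each).
#' @param infer_cfg [infer_config()] supplying dedup radius and group mode.
#' @param grid Candidate thresholds.
#' @return Best threshold (scalar).
#' @export
calibrate_threshold <- function(model, data_val,
                                infer_cfg = infer_config(),
                                grid = seq(0.15, 0.9, by = 0.05)) {
  input_size <- model$input_size %||% 640L
  cached <- lapply(data_val, function(s) {
    img <- standardize_image(s$record$image)
    if (nrow(img) != input_size || ncol(img) != input_size)
      img <- resize_image(img, input_size, input_size)
    preds <- model_forward_single(model, img)$preds
    final <- preds[[length(preds)]]
    list(scores = final$scores, boxes = final$boxes, truth = s$boxes,
         w = s$record$width, h = s$record$height)
  })
  mean_side_px <- function(w, h) (model$mean_box_side %||% 0.1) * (w + h) / 2
  best_thr <- 0.5; best_f1 <- -Inf
  for (thr in grid) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (cc in cached) {
      sel <- cc$scores >= thr
      if (infer_cfg$group_mode == "first_group")
        sel <- sel & model$group_of == 1L
      idx <- which(sel)
      x <- cc$boxes[idx, 1] * cc$w
      y <- cc$boxes[idx, 2] * cc$h
      keep <- dedup_centers(x, y, cc$scores[idx],
                            infer_cfg$dedup_radius * mean_side_px(cc$w, cc$h))
      picks <- data.frame(x = x[keep], y = y[keep],
                          score = cc$scores[idx][keep])
      cnt <- match_picks_single(picks, cc$truth, cc$w, cc$h)
      tp <- tp + cnt["tp"]; fp <- fp + cnt["fp"]; fn <- fn + cnt["fn"]
    }
    f1 <- compute_prf(tp, fp, fn)$f1
    if (f1 > best_f1) { best_f1 <- f1; best_thr <- thr }
  }
  best_thr
}

validation_f1 <- function(model, data_val, infer_cfg) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (s in data_val) {
    picks <- pick(model, s$record, infer_cfg)
    m <- match_picks_single(picks, s$boxes, s$record$width, s$record$height)
    tp <- tp + m["tp"]; fp <- fp + m["fp"]; fn <- fn + m["fn"]
  }
  compute_prf(tp, fp, fn)$f1
}

## standardize + resize + (training) flips; boxes are normalized so a pure
## resize leaves them unchanged and flips mirror the centers
prepare_sample <- function(sample, cfg, training) {
  img <- sample$record$image
  if (abs(mean(img)) > 1e-8 || abs(stats::sd(img) - 1) > 1e-6)
    img <- standardize_image(img)
  boxes <- sample$boxes
  if (nrow(img) != cfg$input_size || ncol(img) != cfg$input_size)
    img <- resize_image(img, cfg$input_size, cfg$input_size)
  if (training && cfg$augment_flips) {
    fl <- stats::runif(2) < 0.5
    r <- flip_sample(img, boxes, horizontal = fl[1], vertical = fl[2])
    img <- r$image; boxes <- r$boxes
  }
  list(image = img, boxes = boxes)
}

#' Resize an image with bilinear interpolation
#'
#' @param image Numeric matrix (rows = y).
#' @param height,width Output size in pixels.
#' @export
resize_image <- function(image, height, width) {
  EBImage::resize(image, w = height, h = width)
}

#' Flip an image and its normalized boxes
#'
#' Flipping twice restores the original; box centers mirror consistently
#' with the image (`cx -> 1 - cx` for horizontal, `cy -> 1 - cy` for
#' vertical).
#'
#' @param image Numeric matrix.
#' @param boxes Normalized center-form box matrix (possibly zero rows).
#' @param horizontal,vertical Which axes to flip.
#' @export
flip_sample <- function(image, boxes, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    if (nrow(boxes) > 0) boxes[, 1] <- 1 - boxes[, 1]
  }
  if (vertical) {
    image <- image[rev(seq_len(nrow(image))), , drop = FALSE]
    if (nrow(boxes) > 0) boxes[, 2] <- 1 - boxes[, 2]
  }
  list(image = image, boxes = boxes)
}

#' Load a COCO-annotated image directory as a training dataset
#'
#' @param coco_path COCO JSON path.
#' @param image_root Directory holding the referenced images.
#' @return List of samples `list(record, boxes)`.
#' @export
load_coco_dataset <- function(coco_path, image_root) {
  annos <- read_coco(coco_path)
  lapply(seq_len(nrow(annos$images)), function(i) {
    id <- annos$images$micrograph_id[i]
    rec <- read_micrograph(file.path(image_root, id))
    list(record = rec, boxes = boxes_for(annos, id))
  })
}
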