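#' Detector configuration
#'
#' Architecture hyperparameters of the set-prediction particle detector.
#' The decoder holds `groups * queries_per_group` object queries; each query
#' owns a learnable normalized 2D reference point whose sinusoidal embedding
#' conditions cross-attention and anchors its box regression.
#'
#' @param hidden_dim Transformer channel width C (divisible by `n_heads`
#'   and by 4 for the positional code).
#' @param n_heads Attention heads.
#' @param n_encoder_layers,n_decoder_layers Encoder / decoder depth.
#' @param groups Number of query groups G; each ground-truth particle can be
#'   assigned one query per group (one-to-many across groups).
#' @param queries_per_group Queries per group Qg; total queries Q = G * Qg.
#' @param dropout Dropout rate applied before each LayerNorm during training.
#' @param ffn_dim Feed-forward hidden width (default 4 * hidden_dim).
#' @param backbone One of "resnet101", "resnet50", "tiny".
#' @param backbone_frozen_stats Use frozen normalization statistics in the
#'   backbone (no batch statistics are ever computed).
#' @param temperature Positional-encoding frequency base.
#' @param box_size_prior Initial box side (normalized) encoded into the box
#'   head's bias so early predictions start near the expected particle size.
#' @param pos_memory_keys Add the grid positional code to the cross-attention
#'   keys (queries carry their reference-point code, so attention aligns
#'   query anchors with grid positions from the first step); values stay
#'   purely content-based.
#' @param pos_attention_bias Add a trainable-gain spatial bias to the
#'   cross-attention logits: the inner product between each query's
#'   reference-point code and each grid cell's positional code (scaled by
#'   1/sqrt(C)), so attention is focused near the reference point from the
#'   start of training rather than having to discover locality.
#' @param refine_references Dynamic reference points: each decoder layer
#'   after the first anchors its box regression and cross-attention at the
#'   previous layer's predicted centers (detached), so references track the
#'   current box estimate layer by layer.
#' @param reference_mode Where layer-1 reference points come from.
#'   `"proposal"` (default): the centers of the top-scoring cells of the
#'   per-image objectness map, assigned to queries in rank order
#'   interleaved across groups, so references sit on candidate particles
#'   before any decoding (requires the objectness head, which
#'   [train_config()]'s auxiliary loss supervises). `"learned"`: each query
#'   owns a data-independent learnable 2D point.
#' @param aux_loss Supervise every decoder layer (not only the last).
#' @return A list of class `gtpick_config`.
#' @export
model_config <- function(hidden_dim = 256L, n_heads = 8L,
                         n_encoder_layers = 6L, n_decoder_layers = 6L,
                         groups = 3L, queries_per_group = 100L,
                         dropout = 0.1, ffn_dim = 4L * hidden_dim,
                         backbone = "resnet101",
                         backbone_frozen_stats = TRUE,
                         temperature = 20, box_size_prior = 0.1,
                         pos_memory_keys = TRUE, pos_attention_bias = TRUE,
                         refine_references = TRUE,
                         reference_mode = c("proposal", "learned"),
                         aux_loss = TRUE) {
  stopifnot(hidden_dim %% n_heads == 0, hidden_dim %% 4 == 0,
            n_heads >= 1, n_decoder_layers >= 1,
            groups >= 1, queries_per_group >= 1,
            dropout >= 0, dropout < 1)
  reference_mode <- match.arg(reference_mode)
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              n_heads = as.integer(n_heads),
              n_encoder_layers = as.integer(n_encoder_layers),
              n_decoder_layers = as.integer(n_decoder_layers),
              groups = as.integer(groups),
              queries_per_group = as.integer(queries_per_group),
              dropout = dropout, ffn_dim = as.integer(ffn_dim),
              backbone = backbone,
              backbone_frozen_stats = isTRUE(backbone_frozen_stats),
              temperature = temperature,
              box_size_prior = box_size_prior,
              pos_memory_keys = isTRUE(pos_memory_keys),
              pos_attention_bias = isTRUE(pos_attention_bias),
              refine_references = isTRUE(refine_references),
              reference_mode = reference_mode,
              aux_loss = isTRUE(aux_loss))
  class(cfg) <- "gtpick_config"
  cfg
}

#' Compact configuration for CPU-scale runs
#'
#' A small detector (tiny convolutional backbone at stride 16, C = 64, one
#' encoder and two decoder layers, two query groups of ten) used by the test
#' suite and the synthetic benchmark.
#' @param ... Overrides passed to [model_config()].
#' @export
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_dim = 64L, n_heads = 4L, n_encoder_layers = 1L,
         n_decoder_layers = 2L, groups = 2L, queries_per_group = 10L,
         dropout = 0, ffn_dim = 256L, backbone = "tiny"),
    list(...))
  do.call(model_config, args)
}

encoder_layer_params <- function(C, ffn_dim) {
  list(attn = mha_params(C), ln1 = layernorm_params(C),
       ffn = ffn_params(C, ffn_dim), ln2 = layernorm_params(C))
}

decoder_layer_params <- function(C, ffn_dim) {
  list(self_attn = mha_params(C), ln1 = layernorm_params(C),
       cross_attn = mha_params(C, share_qk = TRUE),
       ln2 = layernorm_params(C),
       ffn = ffn_params(C, ffn_dim), ln3 = layernorm_params(C),
       pos_scale = 1)    # trainable gain of the reference-point attention bias
}

#' Build a detector with freshly initialized weights
#'
#' Non-backbone weights use Xavier initialization; the backbone uses He
#' initialization (it is trained from scratch unless a checkpoint is
#' loaded). Initialization draws from the session RNG, so seed beforehand
#' for reproducible models.
#'
#' @param config A [model_config()].
#' @return A list of class `gtpick_model` with elements `params`, `config`,
#'   `group_of` (query index to group id) and `Q`.
#' @export
build_model <- function(config = model_config()) {
  C <- config$hidden_dim
  Q <- config$groups * config$queries_per_group
  params <- list(
    backbone = backbone_params(config$backbone, config$backbone_frozen_stats),
    proj = linear_params(backbone_out_channels(config$backbone), C),
    enc = lapply(seq_len(config$n_encoder_layers), function(i)
      encoder_layer_params(C, config$ffn_dim)),
    dec = lapply(seq_len(config$n_decoder_layers), function(i)
      decoder_layer_params(C, config$ffn_dim)),
    query_embed = xavier_init(Q, C),
    ref_raw = matrix(stats::qlogis(stats::runif(Q * 2, 0.05, 0.95)), Q, 2),
    obj_head = linear_params(C, 1L),
    class_head = linear_params(C, 1L),
    box_head = list(fc1 = linear_params(C, C), fc2 = linear_params(C, C),
                    fc3 = linear_params(C, 4L)))
  # start early boxes at the configured size prior
  params$box_head$fc3$b[3:4] <- stats::qlogis(config$box_size_prior)
  model <- list(params = params, config = config,
                group_of = rep(seq_len(config$groups),
                               each = config$queries_per_group),
                Q = Q)
  class(model) <- "gtpick_model"
  model
}

box_head_forward <- function(q, p) {
  f1 <- linear_forward(q, p$fc1); r1 <- relu_forward(f1$out)
  f2 <- linear_forward(r1$out, p$fc2); r2 <- relu_forward(f2$out)
  f3 <- linear_forward(r2$out, p$fc3)
  list(out = f3$out,
       cache = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache,
                    r2 = r2$cache, f3 = f3$cache))
}

box_head_backward <- function(dout, p, cache) {
  b3 <- linear_backward(dout, p$fc3, cache$f3)
  d2 <- relu_backward(b3$dx, cache$r2)
  b2 <- linear_backward(d2, p$fc2, cache$f2)
  d1 <- relu_backward(b2$dx, cache$r1)
  b1 <- linear_backward(d1, p$fc1, cache$f1)
  list(dx = b1$dx,
       grads = list(fc1 = b1$grads, fc2 = b2$grads, fc3 = b3$grads))
}

encoder_forward <- function(z, params, config, training) {
  caches <- vector("list", length(params))
  for (l in seq_along(params)) {
    p <- params[[l]]
    at <- mha_forward(z, z, z, p$attn, config$n_heads)
    d1 <- dropout_forward(at$out, config$dropout, training)
    l1 <- layernorm_forward(z + d1$out, p$ln1)
    ff <- ffn_forward(l1$out, p$ffn)
    d2 <- dropout_forward(ff$out, config$dropout, training)
    l2 <- layernorm_forward(l1$out + d2$out, p$ln2)
    caches[[l]] <- list(at = at$cache, d1 = d1$cache, l1 = l1$cache,
                        ff = ff$cache, d2 = d2$cache, l2 = l2$cache)
    z <- l2$out
  }
  list(out = z, cache = caches)
}

encoder_backward <- function(dz, params, caches) {
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    p <- params[[l]]; cc <- caches[[l]]
    g2 <- layernorm_backward(dz, p$ln2, cc$l2)
    dd2 <- dropout_backward(g2$dx, cc$d2)
    gff <- ffn_backward(dd2, p$ffn, cc$ff)
    dl1 <- g2$dx + gff$dx
    g1 <- layernorm_backward(dl1, p$ln1, cc$l1)
    dd1 <- dropout_backward(g1$dx, cc$d1)
    gat <- mha_backward(dd1, p$attn, cc$at)
    dz <- g1$dx + gat$dq_in + gat$dk_in + gat$dv_in
    grads[[l]] <- list(attn = gat$grads, ln1 = g1$grads,
                       ffn = gff$grads, ln2 = g2$grads)
  }
  list(dz = dz, grads = grads)
}

## One decoder layer: masked (grouped) self-attention, reference-conditioned
## cross-attention against the encoder memory, feed-forward; each sublayer
## wrapped in dropout + residual + LayerNorm.
decoder_layer_forward <- function(q, memory, kmem, pref, mask, p, config,
                                  training, pos_bias = NULL) {
  sa <- mha_forward(q, q, q, p$self_attn, config$n_heads, mask)
  d1 <- dropout_forward(sa$out, config$dropout, training)
  l1 <- layernorm_forward(q + d1$out, p$ln1)
  # reference-point attention bias: the (scaled) inner product between each
  # query's reference code and each grid cell's positional code is added to
  # the cross-attention logits, focusing attention around the reference
  cross_mask <- if (is.null(pos_bias)) NULL else p$pos_scale * pos_bias
  ca <- mha_forward(l1$out + pref, kmem, memory, p$cross_attn, config$n_heads,
                    mask = cross_mask)
  d2 <- dropout_forward(ca$out, config$dropout, training)
  l2 <- layernorm_forward(l1$out + d2$out, p$ln2)
  ff <- ffn_forward(l2$out, p$ffn)
  d3 <- dropout_forward(ff$out, config$dropout, training)
  l3 <- layernorm_forward(l2$out + d3$out, p$ln3)
  list(out = l3$out,
       cache = list(sa = sa$cache, d1 = d1$cache, l1 = l1$cache,
                    ca = ca$cache, d2 = d2$cache, l2 = l2$cache,
                    ff = ff$cache, d3 = d3$cache, l3 = l3$cache,
                    pos_bias = pos_bias))
}

decoder_layer_backward <- function(dout, p, cache) {
  g3 <- layernorm_backward(dout, p$ln3, cache$l3)
  dd3 <- dropout_backward(g3$dx, cache$d3)
  gff <- ffn_backward(dd3, p$ffn, cache$ff)
  dl2 <- g3$dx + gff$dx
  g2 <- layernorm_backward(dl2, p$ln2, cache$l2)
  dd2 <- dropout_backward(g2$dx, cache$d2)
  gca <- mha_backward(dd2, p$cross_attn, cache$ca)
  dl1 <- g2$dx + gca$dq_in
  g1 <- layernorm_backward(dl1, p$ln1, cache$l1)
  dd1 <- dropout_backward(g1$dx, cache$d1)
  gsa <- mha_backward(dd1, p$self_attn, cache$sa)
  grads <- list(self_attn = gsa$grads, ln1 = g1$grads,
                cross_attn = gca$grads, ln2 = g2$grads,
                ffn = gff$grads, ln3 = g3$grads)
  dbias <- NULL
  if (!is.null(cache$pos_bias)) {
    grads$pos_scale <- sum(gca$dmask * cache$pos_bias)
    dbias <- p$pos_scale * gca$dmask       # gradient on the unscaled bias
  }
  list(dq = g1$dx + gsa$dq_in + gsa$dk_in + gsa$dv_in,
       dkmem = gca$dk_in, dvmem = gca$dv_in, dpref = gca$dq_in,
       dbias = dbias, grads = grads)
}

## Convenience wrapper running a full decoder stack with a FIXED reference
## encoding (no per-layer refinement); used by the layer-level tests.
decoder_forward <- function(q, memory, pref, mask, params, config, training,
                            memory_pos = NULL) {
  kmem <- if (is.null(memory_pos)) memory else memory + memory_pos
  caches <- vector("list", length(params))
  outputs <- vector("list", length(params))
  for (l in seq_along(params)) {
    dl <- decoder_layer_forward(q, memory, kmem, pref, mask, params[[l]],
                                config, training)
    q <- dl$out
    outputs[[l]] <- q
    caches[[l]] <- dl$cache
  }
  list(outputs = outputs, cache = caches)
}

## Full forward pass for ONE standardized image (matrix, rows = y).
## Returns per-decoder-layer predictions and, when keep_cache, everything
## needed for the backward pass.
model_forward_single <- function(model, image, training = FALSE,
                                 keep_cache = FALSE) {
  cfg <- model$config
  pp <- model$params
  H <- nrow(image); W <- ncol(image)
  if (H < backbone_stride(cfg$backbone) || W < backbone_stride(cfg$backbone))
    stop("image smaller than the backbone's total stride")
  x <- matrix(as.vector(image), H * W, 1)
  bb <- backbone_forward(x, H, W, pp$backbone)
  pr <- linear_forward(bb$out, pp$proj)
  pos <- positional_encoding(bb$H, bb$W, cfg$hidden_dim, cfg$temperature)
  z0 <- pr$out + pos
  enc <- encoder_forward(z0, pp$enc, cfg, training)
  memory <- enc$out
  kmem <- if (isTRUE(cfg$pos_memory_keys)) memory + pos else memory
  mask <- if (cfg$groups > 1) group_mask(model$group_of) else NULL
  # per-cell objectness read directly off the encoder memory (used for the
  # auxiliary dense supervision during training and available as a
  # diagnostic map at inference)
  obj <- linear_forward(memory, pp$obj_head)

  L <- length(pp$dec)
  q <- pp$query_embed
  if (identical(cfg$reference_mode, "proposal")) {
    # content-conditioned reference proposals: slot s of EVERY group anchors
    # at the objectness cell of rank s, so each candidate cell receives one
    # query per group — the one-to-many supervision pattern — and groups
    # never have to chase targets their anchors do not cover
    ranks <- rep(seq_len(cfg$queries_per_group), cfg$groups)
    ord <- order(-as.vector(obj$out))
    cells <- ord[ranks]
    ci <- (cells - 1) %% bb$H          # row (y) index, 0-based
    cj <- (cells - 1) %/% bb$H         # col (x) index
    ref_xy <- cbind((cj + 0.5) / bb$W, (ci + 0.5) / bb$H)
    ref_logit <- stats::qlogis(ref_xy)  # detached: no grad through top-k
    anchor_is_param <- FALSE
  } else {
    ref_logit <- pp$ref_raw          # anchor in logit space, per layer
    anchor_is_param <- TRUE          # layer-1 anchor IS the learnable point
  }
  preds <- vector("list", L)
  dec_caches <- vector("list", L)
  head_caches <- vector("list", L)
  layer_info <- vector("list", L)
  use_bias <- !identical(cfg$pos_attention_bias, FALSE)
  for (l in seq_len(L)) {
    refs_l <- sigmoid(ref_logit)
    pe_l <- point_encoding(refs_l, cfg$hidden_dim, cfg$temperature)
    pos_bias_l <- if (use_bias) tcrossprod(pe_l$E, pos) / sqrt(cfg$hidden_dim)
    dl <- decoder_layer_forward(q, memory, kmem, pe_l$E, mask, pp$dec[[l]],
                                cfg, training, pos_bias = pos_bias_l)
    q <- dl$out
    cls <- linear_forward(q, pp$class_head)
    bh <- box_head_forward(q, pp$box_head)
    raw <- bh$out
    center_logit <- raw[, 1:2, drop = FALSE] + ref_logit
    cxy <- sigmoid(center_logit)
    wh <- sigmoid(raw[, 3:4, drop = FALSE])
    boxes <- cbind(cx = cxy[, 1], cy = cxy[, 2], w = wh[, 1], h = wh[, 2])
    preds[[l]] <- list(scores = as.vector(sigmoid(cls$out)),
                       logits = as.vector(cls$out),
                       boxes = boxes,
                       reference_points = refs_l)
    dec_caches[[l]] <- dl$cache
    head_caches[[l]] <- list(cls = cls$cache, box = bh$cache)
    layer_info[[l]] <- list(anchor_is_param = anchor_is_param,
                            refs = refs_l, pe = pe_l, q_out = q)
    if (isTRUE(cfg$refine_references) && l < L) {
      # dynamic reference points: the next layer anchors at this layer's
      # predicted centers (treated as constants in the backward pass)
      ref_logit <- center_logit
      anchor_is_param <- FALSE
    }
  }
  res <- list(preds = preds, grid = c(H = bb$H, W = bb$W),
              objectness = as.vector(sigmoid(obj$out)))
  if (keep_cache)
    res$cache <- list(bb = bb$cache, pr = pr$cache, enc = enc$cache,
                      dec = dec_caches, heads = head_caches,
                      layers = layer_info, pos = pos, obj = obj$cache)
  res
}

## Backward pass for one image given per-layer gradients with respect to the
## class LOGITS (Q) and the PRE-SIGMOID box head outputs plus the reference
## anchoring, expressed as gradients on (scores, boxes) via chain rule
## applied here. dpreds: list per layer of list(dscores (Q), dboxes (Q x 4));
## layers with NULL contribute nothing.
model_backward_single <- function(model, fwd, dpreds, dobj = NULL) {
  cfg <- model$config
  pp <- model$params
  cache <- fwd$cache
  L <- length(pp$dec)
  head_grads <- NULL
  dec_grads <- vector("list", L)
  dref_raw <- matrix(0, model$Q, 2)
  dmem <- NULL
  dq <- NULL                        # gradient flowing into layer l's output
  for (l in rev(seq_len(L))) {
    info <- cache$layers[[l]]
    dout <- matrix(0, model$Q, cfg$hidden_dim)
    if (!is.null(dq)) dout <- dout + dq
    dp <- dpreds[[l]]
    if (!is.null(dp)) {
      pl <- fwd$preds[[l]]
      dlogit <- dp$dscores * pl$scores * (1 - pl$scores)
      draw <- matrix(0, model$Q, 4)
      draw[, 1] <- dp$dboxes[, 1] * pl$boxes[, 1] * (1 - pl$boxes[, 1])
      draw[, 2] <- dp$dboxes[, 2] * pl$boxes[, 2] * (1 - pl$boxes[, 2])
      draw[, 3] <- dp$dboxes[, 3] * pl$boxes[, 3] * (1 - pl$boxes[, 3])
      draw[, 4] <- dp$dboxes[, 4] * pl$boxes[, 4] * (1 - pl$boxes[, 4])
      # anchored centers: cx = sigmoid(raw_x + anchor_logit_x); the anchor
      # receives gradient only where it is the learnable point itself
      # (refined anchors are detached constants)
      if (info$anchor_is_param)
        dref_raw <- dref_raw + draw[, 1:2, drop = FALSE]
      gc_ <- linear_backward(matrix(dlogit, ncol = 1), pp$class_head,
                             cache$heads[[l]]$cls)
      gb <- box_head_backward(draw, pp$box_head, cache$heads[[l]]$box)
      dout <- dout + gc_$dx + gb$dx
      hg <- list(class_head = gc_$grads, box_head = gb$grads)
      head_grads <- if (is.null(head_grads)) hg else add_grads(head_grads, hg)
    }
    bl <- decoder_layer_backward(dout, pp$dec[[l]], cache$dec[[l]])
    dec_grads[[l]] <- bl$grads
    dmem_l <- bl$dkmem + bl$dvmem
    dmem <- if (is.null(dmem)) dmem_l else dmem + dmem_l
    if (info$anchor_is_param) {
      dpe <- bl$dpref
      if (!is.null(bl$dbias))
        dpe <- dpe + (bl$dbias %*% cache$pos) / sqrt(cfg$hidden_dim)
      dref <- cbind(rowSums(dpe * info$pe$dE_dx),
                    rowSums(dpe * info$pe$dE_dy))
      dref_raw <- dref_raw + dref * info$refs * (1 - info$refs)
    }
    dq <- bl$dq
  }

  obj_grads <- NULL
  if (!is.null(dobj)) {
    s <- fwd$objectness
    gobj <- linear_backward(matrix(dobj * s * (1 - s), ncol = 1),
                            pp$obj_head, cache$obj)
    dmem <- dmem + gobj$dx
    obj_grads <- gobj$grads
  }
  genc <- encoder_backward(dmem, pp$enc, cache$enc)
  gpr <- linear_backward(genc$dz, pp$proj, cache$pr)
  gbb <- backbone_backward(gpr$dx, pp$backbone, cache$bb)

  list(backbone = gbb$grads, proj = gpr$grads, enc = genc$grads,
       dec = dec_grads, query_embed = dq, ref_raw = dref_raw,
       obj_head = obj_grads,
       class_head = head_grads$class_head, box_head = head_grads$box_head)
}

## elementwise sum of two congruent nested gradient lists; NULL entries act
## as zeros (assignment guarded so a NULL result never deletes an element)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) {
    r <- add_grads(a[[i]], b[[i]])
    if (!is.null(r)) a[[i]] <- r
  }
  a
}

scale_grads <- function(a, s) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- scale_grads(a[[nm]], s)
    a
  } else if (is.numeric(a)) {
    a * s
  } else a
}

#' Run the detector on a batch of images
#'
#' @param model A `gtpick_model`.
#' @param images A list of standardized image matrices (or a single matrix).
#' @param training Logical; enables dropout.
#' @return Per-image list of per-decoder-layer predictions, each a list with
#'   `scores` (length Q) and `boxes` (Q x 4 normalized center-form matrix).
#'   In eval mode the forward pass is deterministic for fixed weights.
#' @export
model_forward <- function(model, images, training = FALSE) {
  if (is.matrix(images)) images <- list(images)
  lapply(images, function(im)
    model_forward_single(model, im, training = training)$preds)
}

#' Save / load a model checkpoint
#'
#' Checkpoints round-trip exactly: a reloaded model produces bitwise-equal
#' eval-mode outputs.
#' @param model A `gtpick_model` (optionally with training extras attached).
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gtpick_model"))
  model
}
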