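## Backbone feature extractors. Two families are provided behind one
## interface:
##   * "tiny"      — four 3x3 stride-2 conv blocks (stride 16), small enough
##                   to train on a CPU; used throughout the test suite.
##   * "resnet101" / "resnet50" — standard bottleneck residual networks at
##                   stride 32, the full-size configuration.
## All normalization layers use frozen statistics (fixed mean/var and fixed
## affine), so no batch statistics are ever computed and train/eval forward
## passes are identical — the stability choice for tiny detection batches.
## backbone_forward returns the final feature map as a (H*W x C) token
## matrix plus its grid size; backbone_backward mirrors it exactly.

TINY_CHANNELS <- c(16, 32, 64, 64)

backbone_stride <- function(name) {
  switch(name, tiny = 16L, resnet50 = 32L, resnet101 = 32L,
         stop("unknown backbone: ", name))
}

backbone_out_channels <- function(name) {
  switch(name, tiny = TINY_CHANNELS[length(TINY_CHANNELS)],
         resnet50 = 2048L, resnet101 = 2048L,
         stop("unknown backbone: ", name))
}

backbone_params <- function(name, frozen_stats = TRUE) {
  if (name == "tiny") {
    c_in <- 1L
    blocks <- lapply(TINY_CHANNELS, function(c_out) {
      b <- list(conv = conv_params(3L, c_in, c_out),
                norm = if (frozen_stats) frozen_norm_params(c_out))
      c_in <<- c_out
      b
    })
    return(list(name = name, blocks = blocks, frozen = frozen_stats))
  }
  depths <- switch(name,
                   resnet50 = c(3L, 4L, 6L, 3L),
                   resnet101 = c(3L, 4L, 23L, 3L),
                   stop("unknown backbone: ", name))
  widths <- c(64L, 128L, 256L, 512L)
  stem <- list(conv = conv_params(7L, 1L, 64L),
               norm = if (frozen_stats) frozen_norm_params(64L))
  c_in <- 64L
  stages <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- vector("list", depths[s])
    for (b in seq_len(depths[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      blocks[[b]] <- bottleneck_params(c_in, widths[s], stride, frozen_stats)
      c_in <- widths[s] * 4L
    }
    stages[[s]] <- blocks
  }
  list(name = name, stem = stem, stages = stages, frozen = frozen_stats)
}

conv_norm_relu_forward <- function(x, H, W, p, stride, pad, relu = TRUE) {
  cv <- conv_forward(x, H, W, p$conv, stride, pad)
  out <- cv$out
  nc <- NULL
  if (!is.null(p$norm)) {
    nf <- frozen_norm_forward(out, p$norm)
    out <- nf$out
    nc <- nf$cache
  }
  rc <- NULL
  if (relu) {
    rf <- relu_forward(out)
    out <- rf$out
    rc <- rf$cache
  }
  list(out = out, H = cv$H, W = cv$W,
       cache = list(conv = cv$cache, norm = nc, relu = rc))
}

conv_norm_relu_backward <- function(dout, p, cache) {
  if (!is.null(cache$relu)) dout <- relu_backward(dout, cache$relu)
  if (!is.null(cache$norm)) dout <- frozen_norm_backward(dout, cache$norm)
  cb <- conv_backward(dout, p$conv, cache$conv)
  list(dx = cb$dx, grads = list(conv = cb$grads))
}

bottleneck_params <- function(c_in, width, stride, frozen_stats) {
  out_ch <- width * 4L
  p <- list(
    b1 = list(conv = conv_params(1L, c_in, width),
              norm = if (frozen_stats) frozen_norm_params(width)),
    b2 = list(conv = conv_params(3L, width, width),
              norm = if (frozen_stats) frozen_norm_params(width)),
    b3 = list(conv = conv_params(1L, width, out_ch),
              norm = if (frozen_stats) frozen_norm_params(out_ch)),
    stride = stride)
  if (stride != 1L || c_in != out_ch)
    p$down <- list(conv = conv_params(1L, c_in, out_ch),
                   norm = if (frozen_stats) frozen_norm_params(out_ch))
  p
}

bottleneck_forward <- function(x, H, W, p) {
  f1 <- conv_norm_relu_forward(x, H, W, p$b1, 1L, 0L)
  f2 <- conv_norm_relu_forward(f1$out, f1$H, f1$W, p$b2, p$stride, 1L)
  f3 <- conv_norm_relu_forward(f2$out, f2$H, f2$W, p$b3, 1L, 0L, relu = FALSE)
  if (!is.null(p$down)) {
    sc <- conv_norm_relu_forward(x, H, W, p$down, p$stride, 0L, relu = FALSE)
    short <- sc$out; sc_cache <- sc$cache
  } else {
    short <- x; sc_cache <- NULL
  }
  pre <- f3$out + short
  rf <- relu_forward(pre)
  list(out = rf$out, H = f3$H, W = f3$W,
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                    sc = sc_cache, relu = rf$cache,
                    H1 = f1$H, W1 = f1$W))
}

bottleneck_backward <- function(dout, p, cache) {
  dpre <- relu_backward(dout, cache$relu)
  g3 <- conv_norm_relu_backward(dpre, p$b3, cache$f3)
  g2 <- conv_norm_relu_backward(g3$dx, p$b2, cache$f2)
  g1 <- conv_norm_relu_backward(g2$dx, p$b1, cache$f1)
  dx <- g1$dx
  grads <- list(b1 = g1$grads, b2 = g2$grads, b3 = g3$grads)
  if (!is.null(p$down)) {
    gd <- conv_norm_relu_backward(dpre, p$down, cache$sc)
    dx <- dx + gd$dx
    grads$down <- gd$grads
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

backbone_forward <- function(x, H, W, p) {
  if (p$name == "tiny") {
    caches <- vector("list", length(p$blocks))
    for (i in seq_along(p$blocks)) {
      f <- conv_norm_relu_forward(x, H, W, p$blocks[[i]], 2L, 1L)
      x <- f$out; H <- f$H; W <- f$W
      caches[[i]] <- f$cache
    }
    return(list(out = x, H = H, W = W, cache = list(blocks = caches)))
  }
  stem <- conv_norm_relu_forward(x, H, W, p$stem, 2L, 3L)
  mp <- maxpool_forward(stem$out, stem$H, stem$W, 3L, 2L, 1L)
  x <- mp$out; H <- mp$H; W <- mp$W
  stage_caches <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- p$stages[[s]]
    bc <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      f <- bottleneck_forward(x, H, W, blocks[[b]])
      x <- f$out; H <- f$H; W <- f$W
      bc[[b]] <- f$cache
    }
    stage_caches[[s]] <- bc
  }
  list(out = x, H = H, W = W,
       cache = list(stem = stem$cache, mp = mp$cache, stages = stage_caches))
}

backbone_backward <- function(dout, p, cache) {
  if (p$name == "tiny") {
    grads <- vector("list", length(p$blocks))
    for (i in rev(seq_along(p$blocks))) {
      g <- conv_norm_relu_backward(dout, p$blocks[[i]], cache$blocks[[i]])
      dout <- g$dx
      grads[[i]] <- g$grads
    }
    return(list(grads = list(blocks = grads)))
  }
  stage_grads <- vector("list", 4L)
  for (s in 4:1) {
    blocks <- p$stages[[s]]
    bg <- vector("list", length(blocks))
    for (b in rev(seq_along(blocks))) {
      g <- bottleneck_backward(dout, blocks[[b]], cache$stages[[s]][[b]])
      dout <- g$dx
      bg[[b]] <- g$grads
    }
    stage_grads[[s]] <- bg
  }
  dmp <- maxpool_backward(dout, cache$mp)
  gstem <- conv_norm_relu_backward(dmp, p$stem, cache$stem)
  list(grads = list(stem = gstem$grads, stages = stage_grads))
}
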