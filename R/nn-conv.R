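## 2D convolution via im2col + matrix multiply, with cached gather indices.
## Images are stored as (H*W) x C matrices in column-major spatial order:
## pixel (row i, col j) of an H x W image sits at flat index (j-1)*H + i.
## Weights are (k*k*Cin) x Cout with the patch offset fastest, then channel.

.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, k, stride, pad) {
  key <- paste(H, W, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  io <- rep(seq_len(Ho), times = Wo)           # output rows, column-major
  jo <- rep(seq_len(Wo), each = Ho)
  i0 <- (io - 1) * stride + 1
  j0 <- (jo - 1) * stride + 1
  di <- rep(0:(k - 1), times = k)              # patch offsets, row fastest
  dj <- rep(0:(k - 1), each = k)
  # (Ho*Wo) x (k*k) gather matrix of flat indices into the padded image
  cols <- outer(i0, di, "+") + outer(j0 - 1, dj, "+") * Hp
  interior <- as.vector(outer(seq_len(H) + pad,
                              (seq_len(W) + pad - 1) * Hp, "+"))
  res <- list(cols = cols, interior = interior,
              Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .conv_idx_cache[[key]] <- res
  res
}

conv_params <- function(k, c_in, c_out, init = he_init) {
  list(W = init(k * k * c_in, c_out), b = numeric(c_out),
       k = k, c_in = c_in, c_out = c_out)
}

pad_image <- function(x, H, W, idx) {
  if (idx$Hp == H && idx$Wp == W) return(x)
  xp <- matrix(0, idx$Hp * idx$Wp, ncol(x))
  xp[idx$interior, ] <- x
  xp
}

conv_forward <- function(x, H, W, p, stride, pad) {
  idx <- conv_indices(H, W, p$k, stride, pad)
  xp <- pad_image(x, H, W, idx)
  P <- nrow(idx$cols); K <- ncol(idx$cols)
  A <- xp[as.vector(idx$cols), , drop = FALSE]        # (P*K) x Cin
  colm <- matrix(A, P, K * p$c_in)                    # patch fastest, then ch
  out <- sweep(colm %*% p$W, 2, p$b, "+")
  list(out = out, H = idx$Ho, W = idx$Wo,
       cache = list(colm = colm, idx = idx, K = K, P = P,
                    Hin = H, Win = W))
}

conv_backward <- function(dout, p, cache) {
  idx <- cache$idx
  dW <- crossprod(cache$colm, dout)
  db <- colSums(dout)
  dcol <- dout %*% t(p$W)                             # P x (K*Cin)
  dA <- matrix(dcol, cache$P * cache$K, p$c_in)
  grp <- as.vector(idx$cols)
  rs <- rowsum(dA, group = grp)
  dxp <- matrix(0, idx$Hp * idx$Wp, p$c_in)
  dxp[as.integer(rownames(rs)), ] <- rs
  dx <- dxp[idx$interior, , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

## Frozen normalization: per-channel affine with fixed statistics and fixed
## scale/shift; no batch statistics are ever computed, so train and eval
## behave identically. All four buffers are constants (never optimized).
frozen_norm_params <- function(C, eps = 1e-5) {
  list(mean = numeric(C), var = rep(1, C), g = rep(1, C), b = numeric(C),
       eps = eps)
}

frozen_norm_forward <- function(x, p) {
  scale <- p$g / sqrt(p$var + p$eps)
  shift <- p$b - p$mean * scale
  out <- sweep(sweep(x, 2, scale, "*"), 2, shift, "+")
  list(out = out, cache = list(scale = scale))
}

frozen_norm_backward <- function(dout, cache) {
  sweep(dout, 2, cache$scale, "*")
}

## 2D max pooling (used by the residual backbone stem)
maxpool_forward <- function(x, H, W, k, stride, pad) {
  idx <- conv_indices(H, W, k, stride, pad)
  xp <- pad_image(x, H, W, idx)
  # padded positions hold 0; inputs can be negative, so pad with -Inf
  if (idx$Hp != H || idx$Wp != W) {
    mask <- rep(TRUE, idx$Hp * idx$Wp)
    mask[idx$interior] <- FALSE
    xp[mask, ] <- -Inf
  }
  P <- nrow(idx$cols)
  C <- ncol(x)
  out <- matrix(0, P, C)
  arg <- matrix(0L, P, C)
  for (ch in seq_len(C)) {
    patch <- matrix(xp[as.vector(idx$cols), ch], P, ncol(idx$cols))
    w <- max.col(patch, ties.method = "first")
    arg[, ch] <- idx$cols[cbind(seq_len(P), w)]
    out[, ch] <- patch[cbind(seq_len(P), w)]
  }
  list(out = out, H = idx$Ho, W = idx$Wo,
       cache = list(arg = arg, idx = idx))
}

maxpool_backward <- function(dout, cache) {
  idx <- cache$idx
  C <- ncol(dout)
  dxp <- matrix(0, idx$Hp * idx$Wp, C)
  for (ch in seq_len(C)) {
    rs <- rowsum(dout[, ch], group = cache$arg[, ch])
    dxp[as.integer(rownames(rs)), ch] <- dxp[as.integer(rownames(rs)), ch] + rs
  }
  dxp[idx$interior, , drop = FALSE]
}
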