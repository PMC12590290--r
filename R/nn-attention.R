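## Multi-head scaled dot-product attention with full forward/backward.
## q_in:  nq x C query-side input
## k_in:  nk x C key-side input
## v_in:  nk x C value-side input
## mask:  optional nq x nk additive matrix (0 = attend, -Inf-like = blocked),
##        used for the block-diagonal grouped decoder self-attention.
## Scaling is 1/sqrt(C / n_heads).

MASK_NEG <- -1e9

## share_qk: initialize Wk identical to Wq. The attention logit between a
## query carrying positional code p and a key carrying code p' then contains
## (p Wq) . (p' Wq) — a positive-semidefinite bilinear form that peaks when
## p = p' — so positional alignment guides attention from the first step
## instead of emerging only after training decorrelates two random maps.
## The two matrices remain independent parameters after initialization.
mha_params <- function(C, init = xavier_init, share_qk = FALSE) {
  Wq <- init(C, C)
  list(Wq = Wq, bq = numeric(C),
       Wk = if (share_qk) Wq else init(C, C), bk = numeric(C),
       Wv = init(C, C), bv = numeric(C),
       Wo = init(C, C), bo = numeric(C))
}

mha_forward <- function(q_in, k_in, v_in, p, n_heads, mask = NULL) {
  C <- ncol(q_in)
  stopifnot(C %% n_heads == 0)
  hd <- C / n_heads
  Q <- sweep(q_in %*% p$Wq, 2, p$bq, "+")
  K <- sweep(k_in %*% p$Wk, 2, p$bk, "+")
  V <- sweep(v_in %*% p$Wv, 2, p$bv, "+")
  O <- matrix(0, nrow(q_in), C)
  A_list <- vector("list", n_heads)
  scale <- 1 / sqrt(hd)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * hd + 1):(h * hd)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale
    if (!is.null(mask)) S <- S + mask
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- sweep(O %*% p$Wo, 2, p$bo, "+")
  list(out = out,
       cache = list(q_in = q_in, k_in = k_in, v_in = v_in,
                    Q = Q, K = K, V = V, O = O, A = A_list,
                    n_heads = n_heads, scale = scale))
}

mha_backward <- function(dout, p, cache) {
  n_heads <- cache$n_heads
  C <- ncol(cache$Q)
  hd <- C / n_heads
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$Q), C)
  dK <- matrix(0, nrow(cache$K), C)
  dV <- matrix(0, nrow(cache$V), C)
  dmask <- matrix(0, nrow(cache$Q), nrow(cache$K))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * hd + 1):(h * hd)
    A <- cache$A[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    # softmax backward, row-wise
    dS <- A * (dA - rowSums(dA * A))
    dmask <- dmask + dS
    dS <- dS * cache$scale
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  grads <- list(
    Wq = crossprod(cache$q_in, dQ), bq = colSums(dQ),
    Wk = crossprod(cache$k_in, dK), bk = colSums(dK),
    Wv = crossprod(cache$v_in, dV), bv = colSums(dV),
    Wo = dWo, bo = dbo)
  list(dq_in = dQ %*% t(p$Wq),
       dk_in = dK %*% t(p$Wk),
       dv_in = dV %*% t(p$Wv),
       dmask = dmask,
       grads = grads)
}

## Block-diagonal additive mask restricting self-attention to within-group
## interactions; group_of maps query index -> group id.
group_mask <- function(group_of) {
  n <- length(group_of)
  m <- matrix(MASK_NEG, n, n)
  same <- outer(group_of, group_of, "==")
  m[same] <- 0
  m
}
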