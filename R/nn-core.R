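## Minimal dense-layer compute engine: every primitive exposes a forward pass
## returning (out, cache) and a matching backward pass returning gradients of
## all inputs and parameters. Tensors are plain matrices (tokens x channels);
## batching is handled by the caller looping over images. All functions are
## internal: user-facing entry points live in model.R / train.R.

xavier_init <- function(n_in, n_out) {
  # Glorot uniform, the initialization used for all non-backbone weights
  a <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out)
}

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

linear_params <- function(n_in, n_out, init = xavier_init) {
  list(W = init(n_in, n_out), b = numeric(n_out))
}

linear_forward <- function(x, p) {
  out <- x %*% p$W
  out <- sweep(out, 2, p$b, "+")
  list(out = out, cache = list(x = x))
}

linear_backward <- function(dout, p, cache) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = list(mask = x > 0))
relu_backward <- function(dout, cache) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

layernorm_params <- function(C) list(g = rep(1, C), b = numeric(C))

layernorm_forward <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2, p$g, "*")
  out <- sweep(out, 2, p$b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_backward <- function(dout, p, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  C <- ncol(dout)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, p$g, "*")
  # per-row: dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, grads = list(g = dg, b = db))
}

## Inverted dropout; the mask is drawn from the session RNG so training runs
## are reproducible under a fixed seed. p = 0 or eval mode is the identity.
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, cache = list(mask = NULL)))
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

## Two-layer feed-forward block (Linear -> ReLU -> Linear)
ffn_params <- function(C, hidden) {
  list(fc1 = linear_params(C, hidden), fc2 = linear_params(hidden, C))
}

ffn_forward <- function(x, p) {
  f1 <- linear_forward(x, p$fc1)
  r <- relu_forward(f1$out)
  f2 <- linear_forward(r$out, p$fc2)
  list(out = f2$out, cache = list(f1 = f1$cache, r = r$cache, f2 = f2$cache))
}

ffn_backward <- function(dout, p, cache) {
  b2 <- linear_backward(dout, p$fc2, cache$f2)
  dr <- relu_backward(b2$dx, cache$r)
  b1 <- linear_backward(dr, p$fc1, cache$f1)
  list(dx = b1$dx, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}
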