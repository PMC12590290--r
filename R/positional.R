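## Trigonometric positional codes. A grid code assigns every feature-map cell
## a C-dim vector: the first C/2 channels encode the (normalized) row
## coordinate and the last C/2 the column coordinate, each as interleaved
## sin/cos pairs over a geometric ladder of frequencies (the transformer
## "sinusoidal" family). The same family embeds the decoder's 2D reference
## points, so grid features and query anchors live in one positional space.

## sin/cos code of scalar coordinates in [0, 1], n_feats channels
## (interleaved sin, cos); returns value and d/dcoord for backprop into
## learnable reference points.
sincos_embed <- function(coord, n_feats, temperature) {
  stopifnot(n_feats %% 2 == 0)
  n_freq <- n_feats / 2
  omega <- 2 * pi / temperature^((seq_len(n_freq) - 1) / n_freq)
  ang <- outer(coord, omega)                       # n x n_freq
  E <- matrix(0, length(coord), n_feats)
  dE <- matrix(0, length(coord), n_feats)
  even <- seq(1, n_feats, by = 2)
  odd <- even + 1
  E[, even] <- sin(ang)
  E[, odd] <- cos(ang)
  dE[, even] <- sweep(cos(ang), 2, omega, "*")
  dE[, odd] <- sweep(-sin(ang), 2, omega, "*")
  list(E = E, dE = dE)
}

#' Sinusoidal 2D positional encoding for a feature grid
#'
#' @param H,W Feature-map height and width in cells.
#' @param C Channel count; must be divisible by 4 (half the channels per
#'   axis, sin/cos interleaved within each half).
#' @param temperature Frequency-ladder base (default 20, suited to the small
#'   normalized-coordinate range).
#' @return `(H*W) x C` matrix in column-major spatial order (row index
#'   fastest), all values in `[-1, 1]`.
#' @export
positional_encoding <- function(H, W, C, temperature = 20) {
  if (C %% 4 != 0) stop("channel count must be divisible by 4")
  i <- rep(seq_len(H) - 1, times = W) / H          # normalized row coord
  j <- rep(seq_len(W) - 1, each = H) / W           # normalized col coord
  half <- C / 2
  cbind(sincos_embed(i, half, temperature)$E,
        sincos_embed(j, half, temperature)$E)
}

## Embedding of normalized (x, y) reference points into the same code space;
## returns E (Q x C) plus per-coordinate derivatives for the backward pass.
point_encoding <- function(points, C, temperature = 20) {
  if (C %% 4 != 0) stop("channel count must be divisible by 4")
  half <- C / 2
  ey <- sincos_embed(points[, 2], half, temperature)
  ex <- sincos_embed(points[, 1], half, temperature)
  list(E = cbind(ey$E, ex$E),
       dE_dy = cbind(ey$dE, matrix(0, nrow(points), half)),
       dE_dx = cbind(matrix(0, nrow(points), half), ex$dE))
}
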