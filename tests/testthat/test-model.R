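test_that("positional encoding is bounded, anchored at the origin, injective", {
  pe <- positional_encoding(20, 20, 64)
  expect_true(all(pe >= -1 & pe <= 1))
  # grid position (0,0): every sine channel 0, every cosine channel 1
  origin <- pe[1, ]
  expect_equal(unname(origin[seq(1, 64, by = 2)]), rep(0, 32))
  expect_equal(unname(origin[seq(2, 64, by = 2)]), rep(1, 32))
  expect_equal(anyDuplicated(round(pe, 10)), 0L)
  # injective on grids up to 50 x 50
  pe50 <- positional_encoding(50, 50, 64)
  expect_equal(anyDuplicated(round(pe50, 10)), 0L)
  expect_error(positional_encoding(4, 4, 10), "divisible by 4")
})

test_that("backbones produce the stride-implied grid", {
  set.seed(51)
  m <- build_model(tiny_config())
  img <- matrix(rnorm(128 * 128), 128, 128)
  fwd <- gtpick:::model_forward_single(m, img)
  expect_equal(unname(fwd$grid), c(8, 8))   # 128 / 16
  expect_error(gtpick:::model_forward_single(m, matrix(0, 8, 8)), "stride")

  bp <- gtpick:::backbone_params("resnet101")
  x <- matrix(rnorm(64 * 64), 64 * 64, 1)
  bb <- gtpick:::backbone_forward(x, 64L, 64L, bp)
  expect_equal(c(bb$H, bb$W), c(2L, 2L))    # 64 / 32
  expect_equal(ncol(bb$out), 2048L)
})

test_that("frozen normalization never exposes batch statistics to training", {
  set.seed(52)
  m <- build_model(micro_model_config())
  # no frozen-norm buffer is a trainable leaf
  paths <- gtpick:::collect_paths(m$params)
  expect_false(any(vapply(paths, function(p) "norm" %in% p, logical(1))))
  # identical normalization on two different batches in training mode
  p <- gtpick:::frozen_norm_params(4)
  x1 <- matrix(rnorm(40), 10, 4); x2 <- matrix(rnorm(40) * 5 + 3, 10, 4)
  f1 <- gtpick:::frozen_norm_forward(x1, p)
  f2 <- gtpick:::frozen_norm_forward(x2, p)
  # outputs are the same fixed affine map of their inputs (identity up to
  # the variance-epsilon factor at initialization)
  expect_equal(f1$out, x1, tolerance = 1e-4)
  expect_equal(f2$out, x2, tolerance = 1e-4)
})

test_that("a zero-layer encoder is the identity", {
  z <- matrix(rnorm(12 * 8), 12, 8)
  out <- gtpick:::encoder_forward(z, list(), tiny_config(), training = FALSE)
  expect_identical(out$out, z)
})

test_that("uniform attention averages the values", {
  C <- 8
  p <- gtpick:::mha_params(C)
  p$Wq[] <- 0; p$Wk[] <- 0; p$bq[] <- 0; p$bk[] <- 0
  p$Wv <- diag(C); p$bv[] <- 0
  p$Wo <- diag(C); p$bo[] <- 0
  qin <- matrix(rnorm(3 * C), 3, C)
  mem <- matrix(rnorm(10 * C), 10, C)
  out <- gtpick:::mha_forward(qin, mem, mem, p, 2)$out
  expect_equal(out, matrix(colMeans(mem), 3, C, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("single-query self-attention reduces to the projection path", {
  set.seed(53)
  C <- 8
  p <- gtpick:::mha_params(C)
  q <- matrix(rnorm(C), 1, C)
  out <- gtpick:::mha_forward(q, q, q, p, 2)$out
  # attention weight is 1, so out = (q Wv + bv) Wo + bo
  v <- q %*% p$Wv + matrix(p$bv, 1)
  expect_equal(out, v %*% p$Wo + matrix(p$bo, 1), tolerance = 1e-12)
})

test_that("grouped decoding isolates groups and equals per-group runs", {
  set.seed(54)
  C <- 16; Q <- 8; G <- 2
  cfg <- tiny_config(hidden_dim = C, n_heads = 2L, n_decoder_layers = 1L,
                     groups = G, queries_per_group = Q / G, ffn_dim = 32L)
  params <- gtpick:::decoder_layer_params(C, 32L)
  group_of <- rep(1:G, each = Q / G)
  mask <- gtpick:::group_mask(group_of)
  q <- matrix(rnorm(Q * C), Q, C)
  mem <- matrix(rnorm(20 * C), 20, C)
  pref <- matrix(rnorm(Q * C), Q, C)

  full <- gtpick:::decoder_forward(q, mem, pref, mask, list(params), cfg,
                                   training = FALSE)$outputs[[1]]
  # oracle: run each group through the same layer independently
  for (g in 1:G) {
    idx <- which(group_of == g)
    solo <- gtpick:::decoder_forward(q[idx, ], mem, pref[idx, ], NULL,
                                     list(params), cfg,
                                     training = FALSE)$outputs[[1]]
    expect_equal(full[idx, ], solo, tolerance = 1e-10)
  }
  # zeroing group 2's content leaves group 1's output unchanged
  q2 <- q; q2[group_of == 2, ] <- 0
  full2 <- gtpick:::decoder_forward(q2, mem, pref, mask, list(params), cfg,
                                    training = FALSE)$outputs[[1]]
  expect_equal(full2[group_of == 1, ], full[group_of == 1, ],
               tolerance = 1e-12)
  # G = 1 degenerates to an unmasked layer
  one <- gtpick:::decoder_forward(q, mem, pref,
                                  gtpick:::group_mask(rep(1L, Q)),
                                  list(params), cfg, FALSE)$outputs[[1]]
  none <- gtpick:::decoder_forward(q, mem, pref, NULL, list(params), cfg,
                                   FALSE)$outputs[[1]]
  expect_equal(one, none, tolerance = 1e-10)
})

test_that("prediction heads anchor boxes at reference points", {
  set.seed(55)
  m <- build_model(micro_model_config(reference_mode = "learned"))
  m$params$box_head$fc1$W[] <- 0; m$params$box_head$fc1$b[] <- 0
  m$params$box_head$fc2$W[] <- 0; m$params$box_head$fc2$b[] <- 0
  m$params$box_head$fc3$W[] <- 0; m$params$box_head$fc3$b[] <- 0
  m$params$ref_raw[] <- 0        # sigmoid(0) = 0.5: all anchors at center
  img <- matrix(rnorm(64 * 64), 64, 64)
  fwd <- gtpick:::model_forward_single(m, img)
  for (pl in fwd$preds) {
    expect_equal(unname(pl$boxes[, 1]), rep(0.5, m$Q))
    expect_equal(unname(pl$boxes[, 2]), rep(0.5, m$Q))
  }
})

test_that("predictions satisfy the score and box range contracts", {
  set.seed(56)
  m <- build_model(micro_model_config())
  for (rep in 1:3) {
    img <- matrix(rnorm(64 * 64, sd = runif(1, 0.5, 3)), 64, 64)
    preds <- model_forward(m, img)[[1]]
    expect_length(preds, length(m$params$dec))   # one set per decoder layer
    final <- preds[[length(preds)]]
    expect_length(final$scores, m$Q)
    expect_true(all(final$scores > 0 & final$scores < 1))
    expect_true(all(final$boxes[, 1:2] > 0 & final$boxes[, 1:2] < 1))
    expect_true(all(final$boxes[, 3:4] > 0 & final$boxes[, 3:4] <= 1))
  }
  expect_equal(m$Q, m$config$groups * m$config$queries_per_group)
})

test_that("eval-mode forward is deterministic and checkpoints round-trip", {
  set.seed(57)
  m <- build_model(micro_model_config(dropout = 0.2))
  img <- matrix(rnorm(64 * 64), 64, 64)
  p1 <- model_forward(m, img)[[1]]
  p2 <- model_forward(m, img)[[1]]
  expect_identical(p1, p2)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(model_forward(m2, img)[[1]], p1)
  unlink(ck)
})
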