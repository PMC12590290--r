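test_that("flips are involutions and mirror boxes consistently", {
  set.seed(81)
  img <- matrix(rnorm(40 * 30), 30, 40)
  boxes <- random_norm_boxes(4)
  f1 <- flip_sample(img, boxes, horizontal = TRUE, vertical = TRUE)
  f2 <- flip_sample(f1$image, f1$boxes, horizontal = TRUE, vertical = TRUE)
  expect_identical(f2$image, img)
  expect_equal(f2$boxes, boxes)
  fh <- flip_sample(img, boxes, horizontal = TRUE)
  expect_equal(fh$boxes[, 1], 1 - boxes[, 1])
  expect_equal(fh$boxes[, 2], boxes[, 2])
})

test_that("pure resizing leaves normalized boxes untouched", {
  set.seed(82)
  g <- generate_micrograph(sim_config(seed = 1L), 1)
  s <- list(record = g$record,
            boxes = as.matrix(g$annos$annotations[, c("cx", "cy", "w", "h")]))
  cfg <- train_config(input_size = 64L, augment_flips = FALSE)
  prep <- gtpick:::prepare_sample(s, cfg, training = TRUE)
  expect_equal(dim(prep$image), c(64L, 64L))
  expect_equal(prep$boxes, s$boxes)
})

test_that("resizing preserves feature positions to sub-pixel accuracy", {
  big <- matrix(0, 1024, 1024)
  big[496:528, 751:783] <- 1       # bright square centered near (767, 512)
  small <- resize_image(big, 128, 128)
  peak <- which(small == max(small), arr.ind = TRUE)[1, ]
  # source center (row 512, col 767) should land at ~(64, 95.9); the peak
  # pixel is quantized, so allow 1.5 destination pixels
  expect_lt(abs(peak["row"] - 512 / 8), 1.5)
  expect_lt(abs(peak["col"] - 767 / 8), 1.5)
})

test_that("duplicate suppression keeps the higher-scoring center", {
  keep <- gtpick:::dedup_centers(c(10, 10, 50), c(10, 10, 50),
                                 c(0.8, 0.9, 0.5), radius = 5)
  expect_equal(keep, c(2L, 3L))
  # zero radius keeps everything
  keep2 <- gtpick:::dedup_centers(c(10, 10.5), c(10, 10), c(0.8, 0.9), 0)
  expect_equal(length(keep2), 2L)
})

test_that("picking respects threshold, bounds and group modes", {
  set.seed(83)
  m <- build_model(micro_model_config())
  m$input_size <- 64L
  m$mean_box_side <- 0.12
  g <- generate_micrograph(sim_config(image_size = 96L, seed = 2L), 1)
  # impossible threshold: empty but well-formed result
  none <- pick(m, g$record, infer_config(score_threshold = 1))
  expect_equal(nrow(none), 0L)
  # threshold 0: all surviving picks lie inside the micrograph
  all_p <- pick(m, g$record, infer_config(score_threshold = 0,
                                          dedup_radius = 0))
  expect_true(all(all_p$x >= 0 & all_p$x < g$record$width))
  expect_true(all(all_p$y >= 0 & all_p$y < g$record$height))
  expect_equal(nrow(all_p), m$Q)
  # centers map back through the resize as pure scaling
  fwd <- gtpick:::model_forward_single(
    m, resize_image(standardize_image(g$record$image), 64, 64))
  final <- fwd$preds[[length(fwd$preds)]]
  expect_equal(sort(all_p$x), sort(final$boxes[, 1] * g$record$width),
               tolerance = 1e-9)
  # first-group mode only emits group-1 queries
  g1 <- pick(m, g$record, infer_config(score_threshold = 0, dedup_radius = 0,
                                       group_mode = "first_group"))
  expect_equal(nrow(g1), m$config$queries_per_group)
})

test_that("training is deterministic under a fixed seed", {
  data <- lapply(1:6, function(i) {
    g <- generate_micrograph(sim_config(image_size = 64L,
                                        n_particles = c(3L, 6L), seed = 4L), i)
    list(record = g$record,
         boxes = as.matrix(g$annos$annotations[, c("cx", "cy", "w", "h")]))
  })
  cfg <- micro_model_config()
  tcfg <- train_config(input_size = 64L, lr_main = 1e-3, lr_backbone = 1e-3,
                       epochs = 2L, batch_size = 2L, seed = 123L)
  m1 <- suppressWarnings(train_detector(data, list(), model_cfg = cfg,
                                        cfg = tcfg, verbose = FALSE))
  m2 <- suppressWarnings(train_detector(data, list(), model_cfg = cfg,
                                        cfg = tcfg, verbose = FALSE))
  expect_identical(m1$history, m2$history)
  expect_true(all(is.finite(m1$history$l_total)))
  img <- standardize_image(data[[1]]$record$image)
  expect_identical(model_forward(m1, img), model_forward(m2, img))
})

test_that("training rejects an empty dataset", {
  expect_error(train_detector(list(), list(), model_cfg = micro_model_config(),
                              cfg = train_config(input_size = 64L)),
               "empty")
})

test_that("a tiny model overfits a single micrograph", {
  # trainability check: 200 steps on one image must drive the objective far
  # below its starting value (the GIoU term keeps a slow tail, so the
  # asymptote is not zero at this step count)
  g <- generate_micrograph(sim_config(seed = 5L), 3)
  s <- list(record = g$record,
            boxes = as.matrix(g$annos$annotations[, c("cx", "cy", "w", "h")]))
  tcfg <- train_config(input_size = 128L, lr_main = 1e-3, lr_backbone = 1e-3,
                       epochs = 200L, batch_size = 1L, seed = 1L,
                       augment_flips = FALSE)
  m <- suppressWarnings(train_detector(list(s), list(), model_cfg = tiny_config(),
                                       cfg = tcfg, verbose = FALSE))
  h <- m$history
  expect_lt(h$l_total[200], 0.25 * h$l_total[1])
  expect_lt(mean(h$l_total[181:200]), mean(h$l_total[1:20]) / 3)
  expect_true(all(is.finite(h$l_total)))
})
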