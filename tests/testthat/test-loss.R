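test_that("focal loss matches direct scalar evaluation", {
  # single foreground query at p = 0.5, alpha 0.25, gamma 2:
  # 0.25 * (1 - 0.5)^2 * (-log 0.5) = 0.25 * 0.25 * log 2
  expect_equal(focal_loss(0.5, TRUE, alpha = 0.25, gamma = 2, n_matched = 1),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  # perfectly classified queries contribute ~0
  expect_lt(focal_loss(1 - 1e-12, TRUE, n_matched = 1), 1e-6)
  expect_lt(focal_loss(1e-12, FALSE, n_matched = 1), 1e-6)
  expect_error(focal_loss(0.5, TRUE, alpha = 1.5), "alpha")
})

test_that("focal loss at gamma 0, alpha 0.5 is half the cross-entropy", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    p <- runif(n, 0.01, 0.99)
    fg <- runif(n) < 0.4
    nm <- max(1, sum(fg))
    expect_equal(focal_loss(p, fg, alpha = 0.5, gamma = 0, n_matched = nm),
                 0.5 * binary_cross_entropy(p, fg) / nm, tolerance = 1e-10)
  }
})

test_that("L1 box loss matches hand arithmetic and is homogeneous", {
  expect_equal(l1_box_loss(cbind(0.5, 0.5, 0.2, 0.2),
                           cbind(0.5, 0.5, 0.2, 0.2)), 0)
  expect_equal(l1_box_loss(cbind(0.5, 0.5, 0.2, 0.2),
                           cbind(0.4, 0.5, 0.2, 0.3)), 0.2)
  set.seed(42)
  pred <- random_norm_boxes(5); tgt <- random_norm_boxes(5)
  base <- l1_box_loss(pred, tgt)
  expect_equal(l1_box_loss(tgt + 2 * (pred - tgt), tgt), 2 * base,
               tolerance = 1e-12)
})

test_that("GIoU loss matches the geometry oracle and stays in [0, 2]", {
  b <- cbind(0.5, 0.5, 0.2, 0.2)
  expect_equal(giou_loss(b, b), 0)
  # the hand-geometry disjoint pair: giou = -7/9 so loss = 16/9
  pred <- cbind(0.05, 0.05, 0.1, 0.1)   # corners (0,0,.1,.1)
  tgt <- cbind(0.25, 0.25, 0.1, 0.1)    # corners (.2,.2,.3,.3)
  expect_equal(giou_loss(pred, tgt), 16 / 9, tolerance = 1e-12)
  set.seed(43)
  for (rep in 1:10) {
    pred <- random_norm_boxes(100); tgt <- random_norm_boxes(100)
    v <- 1 - giou(gtpick:::norm_box_corners(pred),
                  gtpick:::norm_box_corners(tgt))
    expect_true(all(v >= 0 & v <= 2))
  }
})

test_that("total loss is the exact weighted sum", {
  w <- loss_weights(2, 5, 2)
  lb <- total_loss(0.1, 0.2, 0.3, w)
  expect_equal(lb$l_total, 0.2 + 1.0 + 0.6)
  expect_equal(total_loss(0.7, 0.9, 0.4, loss_weights(0, 5, 0))$l_total,
               5 * 0.9)
  expect_error(loss_weights(-1, 5, 2))
  expect_error(loss_weights(0, 0, 0))
})

test_that("detection loss gradients agree with finite differences", {
  set.seed(44)
  group_of <- rep(1:2, each = 4)
  scores <- runif(8, 0.1, 0.9)
  boxes <- random_norm_boxes(8)
  targets <- random_norm_boxes(3)
  dl <- detection_loss(scores, boxes, targets, group_of, with_grad = TRUE)
  expect_equal(dl$l_total,
               loss_weights()$lambda_cls * dl$l_cls +
                 loss_weights()$lambda_l1 * dl$l_l1 +
                 loss_weights()$lambda_giou * dl$l_giou)
  fB <- function(bv) detection_loss(scores, matrix(bv, 8, 4), targets,
                                    group_of)$l_total
  num <- matrix(numeric_gradient(fB, as.vector(boxes), h = 1e-5), 8, 4)
  expect_lt(max(abs(num - dl$dboxes)) / max(abs(num)), 1e-4)
  fS <- function(sv) detection_loss(sv, boxes, targets, group_of)$l_total
  numS <- numeric_gradient(fS, scores, h = 1e-5)
  expect_lt(max(abs(numS - dl$dscores)) / max(abs(numS)), 1e-4)
})

test_that("training objective decreases on a fixed toy batch", {
  set.seed(45)
  cfg <- micro_model_config()
  model <- build_model(cfg)
  img <- matrix(rnorm(64 * 64), 64, 64)
  targets <- rbind(c(0.3, 0.4, 0.2, 0.2), c(0.7, 0.6, 0.2, 0.2))
  tcfg <- train_config(input_size = 64L, lr_main = 1e-3, lr_backbone = 1e-3,
                       epochs = 1L, batch_size = 1L, augment_flips = FALSE)
  paths <- gtpick:::collect_paths(model$params)
  state <- gtpick:::adamw_init(model$params, paths)
  lrs <- rep(1e-3, length(paths))
  losses <- numeric(50)
  for (t in 1:50) {
    lg <- gtpick:::model_loss_and_grads(model, list(img), list(targets), tcfg)
    losses[t] <- lg$breakdown$l_total
    st <- gtpick:::adamw_step(model$params, lg$grads, state, paths, lrs,
                              tcfg$weight_decay, t)
    model$params <- st$params
    state <- st$state
  }
  expect_true(all(is.finite(losses)))
  expect_lt(losses[50], losses[1])
})
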