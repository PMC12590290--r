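test_that("precision/recall/F1 arithmetic matches reported benchmark rows", {
  # F1 printed from its P and R at 3-decimal half-up rounding
  cases <- list(c(0.643, 0.450, 0.529), c(0.618, 0.443, 0.516),
                c(0.621, 0.434, 0.511),
                c(0.449, 0.681, 0.541), c(0.560, 0.440, 0.493))
  for (cs in cases) {
    f1 <- 2 * cs[1] * cs[2] / (cs[1] + cs[2])
    expect_equal(round_half_up(f1, 3), cs[3])
  }
  r <- compute_prf(tp = 9, fp = 5, fn = 11)
  expect_equal(r$precision, 9 / 14)
  expect_equal(r$recall, 9 / 20)
  expect_equal(r$f1, 2 * (9 / 14) * (9 / 20) / (9 / 14 + 9 / 20))
  z <- compute_prf(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
})

test_that("macro averaging reproduces the multi-dataset average row", {
  recalls <- c(0.681, 0.609, 0.535, 0.440, 0.850, 0.460)
  reports <- lapply(recalls, function(r) {
    tp <- round(r * 1000)
    compute_prf(tp = tp, fp = 500, fn = 1000 - tp)
  })
  avg <- average_reports(reports)
  expect_equal(round_half_up(avg$recall[nrow(avg)], 3), 0.596)
})

make_truth <- function(centers, side, size = 100) {
  n <- nrow(centers)
  images <- data.frame(id = 1L, micrograph_id = "m.mrc",
                       width = size, height = size, stringsAsFactors = FALSE)
  annotations <- data.frame(micrograph_id = rep("m.mrc", n),
                            cx = centers[, 1] / size, cy = centers[, 2] / size,
                            w = side / size, h = side / size,
                            category_id = 1L, stringsAsFactors = FALSE)
  annotation_set(annotations, images)
}

make_picks <- function(xy, scores) {
  n <- nrow(xy)
  data.frame(micrograph_name = rep("m.mrc", n), x = xy[, 1],
             y = xy[, 2], score = scores, w = rep(NA_real_, n),
             h = rep(NA_real_, n), stringsAsFactors = FALSE)
}

test_that("greedy center matching counts toy scenes correctly", {
  truth <- make_truth(rbind(c(20, 20), c(60, 60)), side = 16)
  # exact hits
  exact <- make_picks(rbind(c(20, 20), c(60, 60)), c(0.9, 0.8))
  expect_equal(unname(match_picks(exact, truth)), c(2L, 0L, 0L))
  # 3 preds, 2 truths, 2 within radius -> (2, 1, 0)
  picks <- make_picks(rbind(c(21, 19), c(58, 62), c(90, 90)),
                      c(0.9, 0.8, 0.7))
  expect_equal(unname(match_picks(picks, truth)), c(2L, 1L, 0L))
  # empty predictions: all truths are misses
  none <- make_picks(matrix(numeric(0), 0, 2), numeric(0))
  expect_equal(unname(match_picks(none, truth)), c(0L, 0L, 2L))
  # a pred outside the radius is a false positive even if nearest
  far <- make_picks(rbind(c(35, 20)), 0.9)   # 15 px from truth, radius 8
  expect_equal(unname(match_picks(far, truth)), c(0L, 1L, 2L))
})

test_that("a prediction claims each truth at most once (score order)", {
  truth <- make_truth(rbind(c(50, 50)), side = 20)
  dup <- make_picks(rbind(c(50, 50), c(52, 50)), c(0.6, 0.9))
  cnt <- match_picks(dup, truth)
  expect_equal(unname(cnt), c(1L, 1L, 0L))
})

test_that("IoU-mode matching works when picks carry boxes", {
  truth <- make_truth(rbind(c(50, 50)), side = 20)
  picks <- data.frame(micrograph_name = "m.mrc", x = 52, y = 50,
                      score = 0.9, w = 20, h = 20, stringsAsFactors = FALSE)
  expect_equal(unname(match_picks(picks, truth, criterion = "iou")),
               c(1L, 0L, 0L))
  off <- transform(picks, x = 75)
  expect_equal(unname(match_picks(off, truth, criterion = "iou")),
               c(0L, 1L, 1L))
})

test_that("counts pool over micrographs before metric computation", {
  images <- data.frame(id = 1:2, micrograph_id = c("a.mrc", "b.mrc"),
                       width = 100L, height = 100L, stringsAsFactors = FALSE)
  annotations <- data.frame(
    micrograph_id = c("a.mrc", "b.mrc", "b.mrc"),
    cx = c(0.2, 0.4, 0.8), cy = c(0.2, 0.4, 0.8), w = 0.16, h = 0.16,
    category_id = 1L, stringsAsFactors = FALSE)
  truth <- annotation_set(annotations, images)
  picks <- data.frame(
    micrograph_name = c("a.mrc", "b.mrc", "b.mrc"),
    x = c(20, 40, 60), y = c(20, 40, 60), score = c(0.9, 0.9, 0.8),
    w = NA_real_, h = NA_real_, stringsAsFactors = FALSE)
  ev <- evaluate_dataset(picks, truth)
  expect_equal(unname(ev$counts), c(2L, 1L, 1L))
  expect_equal(ev$report$precision, 2 / 3)
  expect_equal(ev$report$recall, 2 / 3)
  expect_equal(nrow(ev$per_micrograph), 2L)
  # invariants: tp + fn = truths, tp + fp = preds
  expect_equal(ev$counts[["tp"]] + ev$counts[["fn"]], 3L)
  expect_equal(ev$counts[["tp"]] + ev$counts[["fp"]], 3L)
})

test_that("evaluation invariants hold on random scenes", {
  set.seed(71)
  for (rep in 1:10) {
    n_t <- sample(0:6, 1); n_p <- sample(0:6, 1)
    truth <- make_truth(cbind(runif(n_t, 10, 90), runif(n_t, 10, 90)),
                        side = 14)
    picks <- make_picks(cbind(runif(n_p, 10, 90), runif(n_p, 10, 90)),
                        runif(n_p))
    ev <- evaluate_dataset(picks, truth)
    expect_equal(ev$counts[["tp"]] + ev$counts[["fn"]], n_t)
    expect_equal(ev$counts[["tp"]] + ev$counts[["fp"]], n_p)
    r <- ev$report
    if (r$precision + r$recall > 0) {
      expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
      expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
    }
  }
})
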