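test_that("confusion counts match an element-by-element loop oracle", {
  ident <- array(c(rep(1, 50), rep(0, 14)), dim = c(4, 4, 4))
  cc <- confusion_counts(ident, ident)
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(50, 0, 0))
  cc2 <- confusion_counts(array(0, dim = c(4, 4, 4)), ident)
  expect_equal(c(cc2$TP, cc2$FP, cc2$FN), c(0, 0, 50))

  set.seed(9)
  for (rep in 1:10) {
    pred <- array(as.numeric(runif(1000) > 0.5), dim = c(10, 10, 10))
    truth <- array(as.numeric(runif(1000) > 0.6), dim = c(10, 10, 10))
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(pred)) {          # brute-force voxel loop
      if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
      if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
      if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    }
    cc <- confusion_counts(pred, truth)
    expect_equal(c(cc$TP, cc$FP, cc$FN), c(tp, fp, fn))
  }
  expect_error(confusion_counts(array(1, dim = c(2, 2, 2)),
                                array(1, dim = c(2, 2, 3))), "shape")
})

test_that("dsc evaluates 2TP/(FP + 2TP + FN) and is symmetric", {
  cts <- function(tp, fp, fn)
    structure(list(TP = tp, FP = fp, FN = fn), class = "confusion_counts")
  expect_equal(dsc(cts(50, 0, 0)), 1.0)
  expect_equal(dsc(cts(0, 10, 10)), 0.0)
  expect_equal(dsc(cts(30, 10, 10)), 0.75)      # 60 / 80
  expect_error(dsc(cts(0, 0, 0)), "empty")

  set.seed(10)
  a <- array(as.numeric(runif(512) > 0.5), dim = c(8, 8, 8))
  b <- array(as.numeric(runif(512) > 0.5), dim = c(8, 8, 8))
  expect_equal(dsc(a, b), dsc(b, a))
  # DSC equals 1 - soft Dice loss for binary fields as eps -> 0
  expect_equal(dsc(a, b), 1 - soft_dice_loss(a, b, eps = 1e-12),
               tolerance = 1e-9)
})

test_that("Bland-Altman bias and limits match hand arithmetic", {
  ba0 <- bland_altman(c(100, 200, 300), c(100, 200, 300))
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)

  # percent differences {-2, 0, +2}: sample SD 2 -> limits +/- 3.92
  make_auto <- function(m, d) m * (1 + d / 200) / (1 - d / 200)
  manual <- c(100, 150, 200)
  auto <- make_auto(manual, c(-2, 0, 2))
  ba <- bland_altman(auto, manual)
  expect_equal(ba$bias, 0, tolerance = 1e-9)
  expect_equal(ba$loa_upper, 3.92, tolerance = 1e-9)
  expect_equal(ba$loa_lower, -3.92, tolerance = 1e-9)

  # sign convention: auto > manual everywhere -> positive bias
  ba2 <- bland_altman(c(110, 210), c(100, 200))
  expect_gt(ba2$bias, 0)
  expect_error(bland_altman(100, 100), "two pairs")
  expect_error(bland_altman(c(-1, 2), c(1, 2)), "positive")
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(11)
  manual <- rep(500, 4000)
  d <- rnorm(4000, mean = -0.2, sd = 6.9)
  auto <- manual * (1 + d / 200) / (1 - d / 200)
  ba <- bland_altman(auto, manual)
  cover <- mean(ba$pct_diff >= ba$loa_lower & ba$pct_diff <= ba$loa_upper)
  expect_lt(abs(cover - 0.95), 0.02)
})
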