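test_that("soft Dice loss matches hand evaluation", {
  m <- array(0, dim = c(8, 8, 8)); m[1:4, , ] <- 1
  expect_lt(soft_dice_loss(m, m), 1e-3)                 # perfect overlap
  expect_gt(soft_dice_loss(1 - m, m), 0.99)             # disjoint
  p <- array(0.5, dim = c(8, 8, 8))
  # p = 0.5 everywhere, mask half-full: 1 - 2*0.25N / (0.5N + 0.5N) = 0.5
  expect_equal(soft_dice_loss(p, m, eps = 1e-9), 0.5, tolerance = 1e-6)
  expect_error(soft_dice_loss(array(0.5, dim = c(4, 4, 4)), m), "shape")
})

test_that("dice gradient vanishes (at the logit level) at a perfect prediction", {
  # the gradient that reaches the weights passes through the sigmoid:
  # dL/dz = dL/dp * p(1-p), which vanishes as the prediction saturates
  # towards the correct binary mask
  m <- array(0, dim = c(6, 6, 6)); m[2:4, 2:4, 2:4] <- 1
  z <- (2 * m - 1) * 12                     # near-perfect logits
  p <- 1 / (1 + exp(-z))
  gp <- soft_dice_loss(p, m, eps = 1e-12, gradient = TRUE)$grad
  expect_lt(max(abs(gp * p * (1 - p))), 1e-4)
  # loss bounded in [0, 1] for arbitrary probabilities
  set.seed(1)
  for (i in 1:20) {
    p <- array(runif(216), dim = c(6, 6, 6))
    l <- soft_dice_loss(p, m)
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("make_folds partitions subjects with near-equal test sizes", {
  ids <- sprintf("S%02d", 1:90)
  folds <- make_folds(ids, 6, seed = 3)
  expect_length(folds, 6)
  for (f in folds) {
    expect_length(f$train_ids, 75)
    expect_length(f$test_ids, 15)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test_ids")), ids)
  expect_identical(make_folds(ids, 6, seed = 3), folds)
  # uneven n: sizes differ by at most one
  f2 <- make_folds(ids[1:20], 3, seed = 1)
  sizes <- lengths(lapply(f2, `[[`, "test_ids"))
  expect_lte(diff(range(sizes)), 1)
  expect_error(make_folds(ids[1:4], 6), "exceeds")
})

test_that("training reduces the loss and is seed-deterministic", {
  samples <- list(tiny_sample(1), tiny_sample(2))
  cfg <- train_config(learning_rate = 1e-3, epochs = 8, seed = 5)
  fit <- train_model(samples, cfg, desk_net_spec())
  expect_length(fit$loss_history, 8)
  expect_lt(fit$loss_history[8], fit$loss_history[1])
  fit2 <- train_model(samples, cfg, desk_net_spec())
  expect_equal(fit$loss_history, fit2$loss_history, tolerance = 1e-12)
  expect_error(train_model(list(), cfg), "at least one")
})

test_that("a single sample can be memorized", {
  s <- tiny_sample(3)
  cfg <- train_config(learning_rate = 1e-3, epochs = 100, seed = 6)
  fit <- train_model(list(s), cfg, desk_net_spec())
  pred <- predict_mask(fit$network, s$x)
  expect_gte(dsc(pred$mask, s$mask), 0.95)
})

test_that("learning-rate sweep selects the argmin and covers the grid", {
  samples <- list(tiny_sample(4))
  cfg <- train_config(seed = 7)
  sw <- learning_rate_sweep(samples, grid = c(1e-2, 1e-4), epochs = 3,
                            config = cfg, spec = desk_net_spec())
  expect_equal(nrow(sw$table), 2)
  expect_true(all(is.finite(sw$table$final_loss)))
  expect_equal(sw$selected,
               sw$table$rate[which.min(sw$table$final_loss)])
  one <- learning_rate_sweep(samples, grid = 1e-3, epochs = 2,
                             config = cfg, spec = desk_net_spec())
  expect_equal(one$selected, 1e-3)
})

test_that("cross-validation audits ids and reports every subject", {
  subjects <- lapply(1:4, function(i) desk_subject(i, seed = 60 + i))
  cv <- cross_validate(subjects, k = 2,
                       config = train_config(learning_rate = 1e-3,
                                             epochs = 2, seed = 8),
                       spec = desk_net_spec())
  expect_equal(nrow(cv$per_subject), 4)
  expect_setequal(cv$per_subject$subject_id, sprintf("P%d", 1:4))
  expect_equal(nrow(cv$per_fold), 2)
  expect_equal(sum(cv$per_fold$n_test), 4)
  expect_true(all(cv$per_subject$dsc >= 0 & cv$per_subject$dsc <= 1))
  for (f in cv$folds)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
})
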