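test_that("output shape equals input shape and values lie in (0, 1)", {
  net <- build_network(desk_net_spec(), seed = 1)
  for (shape in list(c(16L, 16L, 16L), c(32L, 32L, 16L), c(32L, 32L, 48L))) {
    y <- net_forward(net, array(runif(prod(shape)), dim = shape))$y
    expect_identical(dim(y), shape)
    expect_true(all(y > 0 & y < 1))
  }
})

test_that("indivisible input shapes raise a configuration error", {
  net <- build_network(desk_net_spec(), seed = 1)
  expect_error(net_forward(net, array(0, dim = c(90, 96, 192))),
               "divisible by 16")
  expect_equal(network_depth(desk_net_spec()), 4L)
})

test_that("the architecture reduces the paper input to a 6x6x12 bottleneck", {
  # full-size input at reduced width: identical topology and resolution
  # schedule, full-width forward is too slow for a CPU test suite
  net <- build_network(desk_net_spec(0.125), seed = 1)
  x <- array(runif(96 * 96 * 192, 0, 1), dim = c(96, 96, 192))
  fw <- net_forward(net, x, cache = TRUE)
  expect_identical(dim(fw$y), c(96L, 96L, 192L))
  expect_true(all(fw$y > 0 & fw$y < 1))
  first_up <- Filter(function(op) op$kind == "up2", net$ops)[[1]]
  bottleneck_dim <- dim(fw$Tn[[first_up$a]])[1:3]
  expect_identical(bottleneck_dim, c(6L, 6L, 12L))
})

test_that("zeroed final layer gives probability 0.5 everywhere", {
  net <- build_network(desk_net_spec(), seed = 2)
  logits_op <- net$ops[[length(net$ops) - 1L]]
  expect_identical(logits_op$kind, "conv3")
  net$params[[logits_op$id]]$w[] <- 0
  net$params[[logits_op$id]]$b[] <- 0
  x <- array(runif(16^3), dim = c(16, 16, 16))
  pred <- predict_mask(net, x, threshold = 0.5)
  expect_true(all(pred$probabilities == 0.5))
  expect_true(all(pred$mask == 1))       # 0.5 >= 0.5
  # a 1x1x1 conv mapping 1 -> 1 channel with bias holds two parameters
  tiny <- build_network(network_spec(width_multiplier = 1e-6), seed = 1)
  lo <- tiny$ops[[length(tiny$ops) - 1L]]
  p <- tiny$params[[lo$id]]
  expect_equal(length(p$w) + length(p$b), 2L)
})

test_that("threshold 1.0 on a strictly sub-1 field gives an empty mask", {
  net <- build_network(desk_net_spec(), seed = 3)
  x <- array(runif(16^3), dim = c(16, 16, 16))
  pred <- predict_mask(net, x, threshold = 1.0)
  expect_true(max(pred$probabilities) < 1)
  expect_equal(sum(pred$mask), 0)
})

test_that("parameter counts scale ~quadratically with width", {
  n1 <- count_parameters(build_network(network_spec(1), seed = 1))
  n05 <- count_parameters(build_network(network_spec(0.5), seed = 1))
  ratio <- n1 / n05
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.5)
  # identical builds agree
  expect_equal(n1, count_parameters(build_network(network_spec(1), seed = 9)))
})

test_that("fixed weights and input give identical outputs across runs", {
  net <- build_network(desk_net_spec(), seed = 4)
  x <- array(runif(16^3), dim = c(16, 16, 16))
  expect_identical(net_forward(net, x)$y, net_forward(net, x)$y)
  net2 <- set_weights(build_network(desk_net_spec(), seed = 99),
                      get_weights(net))
  expect_identical(net_forward(net2, x)$y, net_forward(net, x)$y)
})

test_that("a trained network is approximately translation-covariant", {
  # invariant scaled to the desk crop: a 4-voxel in-plane shift of the
  # input moves the predicted mask centroid by 4 +/- 2 voxels.  The
  # network is trained WITH shift augmentation — without it the model
  # learns the phantom's absolute position (all training masks are
  # centred) and the covariance property degrades, which is precisely
  # why the training recipe includes random translations.
  subs <- lapply(1:3, function(i) desk_subject(i, seed = 60 + i))
  aug <- augmentation_spec(n_random_transforms = 3, max_shift_inplane = 5L,
                           max_shift_outplane = 2L,
                           scale_range_inplane = c(-0.1, 0.1),
                           scale_range_outplane = c(-0.1, 0.1), seed = 1)
  ts <- build_training_set(lapply(subs, `[[`, "pair"), aug)
  samples <- lapply(seq_len(ts$n_samples),
                    function(i) materialize_sample(ts, i))
  fit <- train_model(samples,
                     train_config(learning_rate = 1e-3, epochs = 10, seed = 2),
                     desk_net_spec())
  held <- desk_subject(9, seed = 77)          # held-out subject
  crop <- held$pair$right
  shifted <- apply_transform(crop, list(shift = c(4L, 0L, 0L),
                                        scale = c(1, 1, 1)))
  p1 <- predict_mask(fit$network, crop)
  p2 <- predict_mask(fit$network, shifted)
  expect_gt(dsc(p1$mask, crop$mask), 0.8)
  centroid <- function(m) colMeans(which(m == 1, arr.ind = TRUE))
  delta <- centroid(p2$mask) - centroid(p1$mask)
  expect_lt(abs(delta[1] - 4), 2)
  expect_lt(max(abs(delta[2:3])), 2)
})
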