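test_that("sampled transforms respect the configured bounds", {
  spec <- augmentation_spec(seed = 1)
  set.seed(1)
  draws <- replicate(10000, sample_transform(spec), simplify = FALSE)
  sh <- t(vapply(draws, `[[`, integer(3), "shift"))
  sc <- t(vapply(draws, `[[`, numeric(3), "scale"))
  expect_true(all(abs(sh[, 1:2]) <= 6))
  expect_true(all(abs(sh[, 3]) <= 24))
  expect_true(all(sc[, 1] >= 0.75 & sc[, 1] <= 1.25))
  expect_true(all(sc[, 3] >= 0.5 & sc[, 3] <= 1.5))
  expect_identical(sc[, 1], sc[, 2])     # shared in-plane factor
  # bounds are actually explored
  expect_gt(max(sh[, 3]), 20); expect_lt(min(sh[, 3]), -20)
})

test_that("zero-bound spec always yields the identity transform", {
  spec <- augmentation_spec(max_shift_inplane = 0, max_shift_outplane = 0,
                            scale_range_inplane = c(0, 0),
                            scale_range_outplane = c(0, 0))
  set.seed(2)
  tr <- sample_transform(spec)
  expect_identical(tr$shift, c(0L, 0L, 0L))
  expect_identical(tr$scale, c(1, 1, 1))
})

test_that("same seed gives the same transform sequence", {
  spec <- augmentation_spec(seed = 5)
  seq1 <- psoasvol:::with_seed(5, replicate(20, sample_transform(spec),
                                            simplify = FALSE))
  seq2 <- psoasvol:::with_seed(5, replicate(20, sample_transform(spec),
                                            simplify = FALSE))
  expect_identical(seq1, seq2)
})

test_that("identity parameters leave the crop voxelwise unchanged", {
  s <- desk_subject(3, seed = 44)
  out <- apply_transform(s$pair$right,
                         list(shift = c(0L, 0L, 0L), scale = c(1, 1, 1)))
  expect_identical(out$intensities, s$pair$right$intensities)
})

test_that("pure shifts preserve interior mask volume; scaling scales it", {
  m <- array(0, dim = c(32, 32, 32))
  m[12:20, 12:20, 12:20] <- 1
  crop <- muscle_crop(m * 0.7, m, side = "right")
  shifted <- apply_transform(crop, list(shift = c(3L, 0L, 0L),
                                        scale = c(1, 1, 1)))
  expect_equal(sum(shifted$mask), sum(m))
  expect_true(all(shifted$mask %in% c(0, 1)))

  scaled <- apply_transform(crop, list(shift = c(0L, 0L, 0L),
                                       scale = c(1, 1, 1.10)))
  # analytic oracle: volume scales by the out-of-plane factor
  expect_lt(abs(sum(scaled$mask) - 1.10 * sum(m)) / (1.10 * sum(m)), 0.05)
  expect_true(all(scaled$mask %in% c(0, 1)))
})

test_that("sample-count formula holds: 2 x 2 x (1 + n) per subject", {
  s <- desk_subject(4, seed = 45)
  for (cfg in list(c(1, 7, 32), c(1, 0, 4), c(3, 2, 36))) {
    subs <- rep(list(s$pair), cfg[1])
    ts <- build_training_set(subs,
                             augmentation_spec(n_random_transforms = cfg[2],
                                               seed = 3))
    expect_equal(ts$n_samples, cfg[3])
  }
})

test_that("materialized samples are binary-masked and seeded deterministically", {
  s <- desk_subject(5, seed = 46)
  spec <- augmentation_spec(n_random_transforms = 2, seed = 11)
  ts1 <- build_training_set(list(s$pair), spec)
  ts2 <- build_training_set(list(s$pair), spec)
  expect_identical(ts1$samples, ts2$samples)
  for (i in seq_len(ts1$n_samples)) {
    sm <- materialize_sample(ts1, i)
    expect_true(all(sm$mask %in% c(0, 1)))
    expect_identical(dim(sm$intensities), dim(s$pair$right$intensities))
  }
})

test_that("missing masks are rejected", {
  sp <- desk_phantom_spec(seed = 47)
  ph <- generate_phantom(sp, 10, 12, seed = 47)
  pair <- prepare_subject(ph$volume, ph$landmarks,
                          crop_shape = c(32L, 32L, 16L))
  expect_error(build_training_set(list(pair), augmentation_spec()),
               "mask")
})
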