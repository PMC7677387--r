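test_that("centred crop equals direct subvolume extraction (oracle)", {
  set.seed(5)
  arr <- array(runif(40 * 36 * 50), dim = c(40, 36, 50))
  vol <- dixon_volume(arr)
  lm <- c(20, 18, 25)
  crop <- crop_to_roi(vol, lm, crop_shape = c(16, 16, 16),
                      anchor_frac = c(0.5, 0.5, 0.5))
  # direct extraction: landmark sits at index round(0.5 * 15) = 8 (0-based)
  o <- lm - 8
  oracle <- arr[(o[1] + 1):(o[1] + 16), (o[2] + 1):(o[2] + 16),
                (o[3] + 1):(o[3] + 16)]
  expect_identical(crop$intensities, oracle)
  expect_identical(crop$source_offset, as.integer(o))
})

test_that("out-of-bounds regions are zero-padded, shape is preserved", {
  vol <- dixon_volume(array(1, dim = c(10, 10, 10)))
  crop <- crop_to_roi(vol, c(0, 0, 0), crop_shape = c(16, 16, 16))
  expect_identical(dim(crop$intensities), c(16L, 16L, 16L))
  expect_true(mean(crop$intensities == 0) > 0.5)
  expect_error(crop_to_roi(vol, c(10, 0, 0)), "outside")
})

test_that("re-embedding at source_offset and re-cropping is the identity", {
  set.seed(6)
  arr <- array(runif(30^3), dim = c(30, 30, 30))
  vol <- dixon_volume(arr)
  crop <- crop_to_roi(vol, c(4, 25, 14), crop_shape = c(16, 16, 16))
  emb <- embed_crop(crop$intensities, crop$source_offset, dim(arr))
  crop2 <- crop_to_roi(dixon_volume(emb), c(4, 25, 14),
                       crop_shape = c(16, 16, 16))
  expect_identical(crop2$intensities, crop$intensities)
})

test_that("normalization maps the 99th percentile to one", {
  expect_equal(unique(as.vector(
    normalize_intensity(array(7, dim = c(5, 5, 5))))), 1)

  x <- array(as.numeric(1:10000), dim = c(10, 10, 100))
  y <- normalize_intensity(x)
  # brute-force sort oracle: type-7 p99 of 1..10000 is 9900.01
  expect_equal(quantile(as.numeric(1:10000), 0.99, names = FALSE), 9900.01)
  expect_equal(y[which(x == 9900)], 9900 / 9900.01, tolerance = 1e-12)
  expect_equal(y[which(x == 4950)], 4950 / 9900.01, tolerance = 1e-12)
  expect_true(all(y >= 0 & y <= 1))

  # a single extreme spike is clipped; the rest is scaled by the same p99
  set.seed(7)
  base <- array(runif(20^3, 1, 2), dim = c(20, 20, 20))
  spiked <- base; spiked[1, 1, 1] <- 100 * max(base)
  p99_spiked <- quantile(spiked, 0.99, names = FALSE)
  y <- normalize_intensity(spiked)
  expect_equal(y[1, 1, 1], 1)
  expect_equal(y[2:20, , ], pmin(base[2:20, , ] / p99_spiked, 1),
               tolerance = 1e-12)

  expect_error(normalize_intensity(array(0, dim = c(4, 4, 4))), "degenerate")
})

test_that("normalization is idempotent up to clipping", {
  set.seed(8)
  x <- array(runif(16^3), dim = c(16, 16, 16))
  y <- normalize_intensity(x)
  z <- normalize_intensity(y)
  expect_true(all(z >= 0 & z <= 1))
  sub <- y < quantile(y, 0.99)          # sub-p99 ordering unchanged
  expect_identical(order(y[sub]), order(z[sub]))
})

test_that("reflection is an involution and relabels the side", {
  s <- desk_subject(1, seed = 41)
  left <- s$pair$left                    # already reflected by prepare_subject
  expect_identical(left$side, "right")
  expect_true(left$reflected)
  twice <- reflect_crop(reflect_crop(left))
  expect_identical(twice$intensities, left$intensities)
  expect_identical(twice$mask, left$mask)
  expect_identical(twice$side, left$side)
  back <- reflect_crop(left)
  expect_identical(back$side, "left")
  expect_false(back$reflected)
})

test_that("reflected left crop of a mirror-symmetric phantom equals right", {
  sp <- desk_phantom_spec(seed = 2, noise_sd = 0)
  ph <- generate_phantom(sp, 12, 12, seed = 2)
  pair <- prepare_subject(ph$volume, ph$landmarks,
                          masks = list(left = ph$left_mask,
                                       right = ph$right_mask),
                          crop_shape = c(32L, 32L, 16L))
  # identical geometry: reflected-left mask must match the right mask
  expect_identical(pair$left$mask, pair$right$mask)
  expect_equal(max(abs(pair$left$intensities - pair$right$intensities)), 0,
               tolerance = 1e-12)
})

test_that("prepared crops contain >= 95% of each side's mask", {
  s <- desk_subject(2, seed = 42)
  ph <- s$phantom
  expect_gte(sum(s$pair$left$mask) / sum(ph$left_mask$data), 0.95)
  expect_gte(sum(s$pair$right$mask) / sum(ph$right_mask$data), 0.95)
  # masks and intensities got the same transform: mask voxels are bright
  bright <- s$pair$right$intensities[s$pair$right$mask == 1]
  dark <- s$pair$right$intensities[s$pair$right$mask == 0]
  expect_gt(mean(bright), mean(dark) + 0.2)
})

test_that("subjects without masks are prepared without failure", {
  sp <- desk_phantom_spec(seed = 43)
  ph <- generate_phantom(sp, 10, 12, seed = 43)
  pair <- prepare_subject(ph$volume, ph$landmarks,
                          crop_shape = c(32L, 32L, 16L))
  expect_null(pair$left$mask)
  expect_null(pair$right$mask)
  pair2 <- prepare_subject(ph$volume, ph$landmarks,
                           crop_shape = c(32L, 32L, 16L))
  expect_identical(pair, pair2)          # deterministic
})
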