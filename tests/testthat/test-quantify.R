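test_that("mask volume is voxel count x voxel volume", {
  empty <- array(0, dim = c(10, 10, 10))
  expect_equal(mask_to_volume_ml(empty, c(1, 1, 1)), 0)
  cube <- array(1, dim = c(10, 10, 10))
  expect_equal(mask_to_volume_ml(cube, c(1, 1, 1)), 1.0)
  expect_equal(mask_to_volume_ml(cube, c(2.232, 2.232, 3.0)),
               2.232^2 * 3.0, tolerance = 1e-12)     # 14.945 ml
  expect_error(mask_to_volume_ml(cube * 0.5, c(1, 1, 1)), "binary")
})

test_that("volume additivity holds exactly for disjoint parts", {
  set.seed(12)
  whole <- array(as.numeric(runif(27e2) > 0.4), dim = c(9, 10, 30))
  part1 <- whole; part1[, , 16:30] <- 0
  part2 <- whole; part2[, , 1:15] <- 0
  v <- c(2.232, 2.232, 3)
  expect_identical(mask_to_volume_ml(part1, v) + mask_to_volume_ml(part2, v),
                   mask_to_volume_ml(whole, v))
})

test_that("IMI follows total/height^2 with cm auto-conversion", {
  expect_equal(compute_imi(800, 2.00), 200.0)
  # population means: 542.3 ml at 1.625 m -> 205.4 ml/m^2
  expect_equal(compute_imi(542.3, 1.625), 542.3 / 1.625^2, tolerance = 1e-12)
  expect_equal(round(compute_imi(542.3, 1.625), 1), 205.4)
  expect_equal(compute_imi(800, 176.2), compute_imi(800, 1.762))
  expect_error(compute_imi(800, 0), "positive")
})

test_that("quantify_subject assembles a consistent record", {
  # grid chosen so volumes are exact: 1 ml per voxel
  v <- c(10, 10, 10)
  lm <- array(0, dim = c(12, 12, 12)); lm[1:4, , 1:10] <- 1    # 480 ml
  rm_ <- array(0, dim = c(12, 12, 12)); rm_[9:12, , 1:11] <- 1 # 528 ml
  rec <- quantify_subject(lm, rm_, list(subject_id = "X", height_cm = 170,
                                        gender = "female"), voxel_mm = v)
  expect_equal(rec$left_ml, 480); expect_equal(rec$right_ml, 528)
  expect_equal(rec$total_ml, rec$left_ml + rec$right_ml)
  expect_equal(rec$lr_diff_ml, -48)       # negative: right larger
  expect_equal(rec$imi, compute_imi(1008, 1.70))
  expect_identical(rec$qc_flags, "")

  same <- quantify_subject(lm, lm * 0, list(subject_id = "Y"), voxel_mm = v)
  expect_equal(same$lr_diff_ml, 480)
  eq <- quantify_subject(lm, lm, list(subject_id = "Z"), voxel_mm = v)
  expect_equal(eq$lr_diff_ml, 0)
  expect_match(eq$qc_flags, "mask_overlap")   # identical masks overlap
})

test_that("ground-truth phantom masks quantify to the stored volumes", {
  s <- desk_subject(7, seed = 70)
  ph <- s$phantom
  rec <- quantify_subject(ph$left_mask, ph$right_mask,
                          list(subject_id = ph$subject_id, height_cm = 165))
  expect_equal(rec$left_ml, ph$true_left_ml, tolerance = 1e-12)
  expect_equal(rec$right_ml, ph$true_right_ml, tolerance = 1e-12)
})

test_that("qc_screen flags bounds, asymmetry and outliers without dropping", {
  base <- data.frame(
    subject_id = sprintf("S%d", 1:8), gender = "female",
    left_ml = c(10, rep(270, 7)), right_ml = c(10, 270, 270, 270, 270,
                                               270, 135, 270),
    stringsAsFactors = FALSE)
  base$total_ml <- base$left_ml + base$right_ml
  base$lr_diff_ml <- base$left_ml - base$right_ml
  base$qc_flags <- ""
  out <- qc_screen(base, qc_config(min_ml = 100, max_ml = 800,
                                   max_asymmetry_fraction = 0.25,
                                   outlier_z = 2))
  expect_equal(nrow(out), 8)                       # nothing dropped
  expect_match(out$qc_flags[1], "volume_bounds")
  # left 270 / right 135: |135| / 202.5 = 0.667 > 0.25
  expect_match(out$qc_flags[7], "asymmetry")
  expect_true(all(out$qc_pass[c(2:6, 8)]))

  ident <- base[rep(2, 5), ]; ident$qc_flags <- ""
  out2 <- qc_screen(ident, qc_config())
  expect_true(all(out2$qc_pass))                   # identical records: clean
  expect_error(qc_config(min_ml = 500, max_ml = 100), "below")
})
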