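test_that("normality gate rejects skewed data and rejects degenerate input", {
  set.seed(13)
  skewed <- exp(rnorm(500))
  res <- normality_gate(skewed)
  expect_lt(res$p_value, 0.05)
  expect_true(res$effect$use_rank_tests)
  expect_error(normality_gate(rep(3, 50)), "constant")
  expect_error(normality_gate(1:2), "3 <= n")
})

test_that("spearman_rho matches its rank definition exhaustively at n = 5", {
  x <- 1:5
  perms <- do.call(rbind, lapply(combinat_perms(5), identity))
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    # classical formula 1 - 6*sum(d^2)/(n(n^2-1)) (no ties)
    oracle <- 1 - 6 * sum((x - rank(y))^2) / (5 * 24)
    expect_equal(spearman_rho(x, y)$effect$rho, oracle, tolerance = 1e-12)
  }
  expect_equal(spearman_rho(1:10, (1:10)^3)$effect$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3)$effect$rho, -1)
})

test_that("spearman_rho handles ties like the mid-rank oracle", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2.1, 1.0, 3.0, 3.0, 5.2, 4.9)
  oracle <- unname(cor.test(x, y, method = "spearman", exact = FALSE)$estimate)
  expect_equal(spearman_rho(x, y)$effect$rho, oracle, tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "variance")
})

test_that("rank-sum test: exact enumeration and identical-group symmetry", {
  # most extreme ranking: two tails out of C(6,3) = 20 -> p = 0.1
  res <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, 6)

  same <- rank_sum_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)

  set.seed(14)
  big <- rank_sum_test(rnorm(200), rnorm(200, mean = 3))
  expect_lt(big$p_value, 1e-6)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank test: exact enumeration, zeros, and shift power", {
  # differences {1,2,3}: W+ = 6 is one of two extreme patterns among 2^3
  res <- signed_rank_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(res$p_value, 0.25, tolerance = 1e-12)
  expect_equal(res$statistic, 6)
  expect_equal(res$effect$d, 2)

  expect_error(signed_rank_test(1:5, 1:5), "zero")

  set.seed(15)
  l <- rnorm(300); r <- l + rnorm(300, mean = 1, sd = 0.3)
  expect_lt(signed_rank_test(l, r)$p_value, 1e-10)
})

test_that("exact and approximate branches agree near the crossover", {
  set.seed(16)
  for (rep in 1:20) {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, 0, 1.5))
    p_ex <- rank_sum_test(a, b, exact_limit = 12)$p_value
    p_ap <- rank_sum_test(a, b, exact_limit = 0)$p_value
    expect_lt(abs(p_ex - p_ap), 0.02)
    l <- rnorm(12); r <- l + rnorm(12, mean = runif(1, -0.5, 0.5))
    p_ex <- signed_rank_test(l, r, exact_limit = 12)$p_value
    p_ap <- signed_rank_test(l, r, exact_limit = 0)$p_value
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
})

test_that("wilcoxon implementations agree with stats::wilcox.test", {
  set.seed(17)
  a <- rnorm(40); b <- rnorm(45, 0.4)
  expect_equal(rank_sum_test(a, b)$p_value,
               wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-10)
  l <- rnorm(40); r <- l + rnorm(40, 0.2)
  expect_equal(signed_rank_test(l, r)$p_value,
               wilcox.test(l, r, paired = TRUE, correct = TRUE,
                           exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("noiseless linear data is reproduced by the spline fit", {
  set.seed(18)
  age <- runif(200, 44, 82)
  imi <- 300 - 1.2 * age
  tf <- fit_age_trend(age, imi)
  expect_lt(max(abs(tf$fit - (300 - 1.2 * tf$grid))), 1e-6)
})

test_that("the male changepoint decline appears in the fitted derivative", {
  cm <- generate_cohort(cohort_params(), 2500, 2500, seed = 19)
  rec <- records_from_cohort(cm)
  trends <- fit_age_trend(rec$age_years, rec$imi, rec$gender)
  dmean <- function(tf, lo, hi)
    mean(tf$derivative[tf$grid >= lo & tf$grid <= hi], na.rm = TRUE)
  male_young <- dmean(trends$male, 45, 60)
  male_old <- dmean(trends$male, 65, 80)
  expect_lt(male_old, male_young)                 # acceleration after 62
  f_young <- dmean(trends$female, 45, 60)
  f_old <- dmean(trends$female, 65, 80)
  expect_lt(f_old, 0); expect_lt(f_young, 0)      # shallow steady decline
  expect_lt(abs(f_old / f_young), 2)
  expect_gt(abs(f_old / f_young), 0.5)
})

test_that("handedness association: null uniformity and shift power", {
  set.seed(20)
  pvals <- replicate(200, {
    n <- 400
    lr <- rnorm(n, -6.5, 16.1)
    hand <- ifelse(runif(n) < 0.89, "right", "left")
    handedness_association(data.frame(lr_diff_ml = lr, handedness = hand))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)

  cm <- generate_cohort(cohort_params(), 1000, 1000, seed = 21)
  rec <- records_from_cohort(cm)
  rec$lr_diff_ml[rec$handedness == "left"] <-
    rec$lr_diff_ml[rec$handedness == "left"] + 20   # planted association
  expect_lt(handedness_association(rec)$p_value, 0.01)

  expect_error(handedness_association(
    data.frame(lr_diff_ml = rnorm(10), handedness = "right")), "two")
})

test_that("analyze_cohort assembles the full battery", {
  cm <- generate_cohort(cohort_params(), 250, 250, seed = 22)
  an <- analyze_cohort(records_from_cohort(cm))
  expect_s3_class(an, "cohort_analysis")
  expect_lt(an$gender_total$p_value, 1e-10)
  expect_named(an$age_trend, c("female", "male"))
  expect_output(print(an), "Spearman")
})

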