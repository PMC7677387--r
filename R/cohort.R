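# Synthetic demographic cohorts with muscle-volume targets.
#
# The generative model works on the iliopsoas muscle index (IMI, ml/m^2)
# scale and derives total volume as IMI * height^2, which reproduces the
# reported marginal volume distributions and yields the reported
# volume-height rank correlation as an emergent property.  The IMI mean is
# a piecewise-linear function of age (changepoint for men) plus a linear
# BMI term plus Gaussian noise; slopes are solved analytically from the
# target Spearman correlations via the Gaussian rank-correlation identity
# rho_pearson = 2*sin(pi*rho_spearman/6).

default_gender_params <- function(gender) {
  if (gender == "female") {
    list(
      n_ref = 2496L,
      total_ml = c(mean = 542.3, sd = 72.1),
      height_cm = c(mean = 162.5, sd = 6.1),
      bmi = c(mean = 26.2, sd = 4.7), bmi_range = c(16.1, 55.2),
      age = c(mean = 63.3, sd = 8.3), age_range = c(44, 82),
      lr_diff_ml = c(mean = -6.5, sd = 16.1), lr_range = c(-96.9, 62.5),
      imi_age_rho = -0.11, changepoint_age = 62, pre_post_slope_ratio = 1,
      imi_bmi_rho = 0.47
    )
  } else {
    list(
      n_ref = 2504L,
      total_ml = c(mean = 814.5, sd = 125.4),
      height_cm = c(mean = 176.2, sd = 6.8),
      bmi = c(mean = 27.0, sd = 3.9), bmi_range = c(17.6, 50.9),
      age = c(mean = 63.3, sd = 8.4), age_range = c(44, 82),
      lr_diff_ml = c(mean = -7.3, sd = 22.8), lr_range = c(-95.6, 184.4),
      imi_age_rho = -0.31, changepoint_age = 62, pre_post_slope_ratio = 0.2,
      imi_bmi_rho = 0.48
    )
  }
}

#' Parameters for the synthetic cohort generator
#'
#' Defaults encode the study population: per-gender total-volume, height,
#' BMI and age distributions, left-minus-right asymmetry, the target
#' IMI-BMI and IMI-age Spearman correlations, and a male age-trend
#' changepoint at 62 years with a pre/post slope ratio < 1 (the decline
#' accelerates after the changepoint).  All continuous covariates are
#' sampled from truncated normals.
#'
#' @param female,male named lists overriding individual defaults (see
#'   source for field names)
#' @param handedness_p_right proportion of right-handed subjects
#'   (default 0.89; handedness is simulated independently of asymmetry)
#' @param seed integer seed fixing all draws
#' @return object of class `cohort_params`
#' @export
cohort_params <- function(female = list(), male = list(),
                          handedness_p_right = 0.89, seed = 1L) {
  fp <- modifyList(default_gender_params("female"), female)
  mp <- modifyList(default_gender_params("male"), male)
  for (p in list(fp, mp)) {
    if (p$total_ml["sd"] <= 0 || p$height_cm["sd"] <= 0 ||
        p$bmi["sd"] <= 0 || p$age["sd"] <= 0 || p$lr_diff_ml["sd"] <= 0)
      stop("all SDs must be positive")
    if (p$age_range[1] < 44 || p$age_range[2] > 82)
      stop("age range must lie within [44, 82]")
    if (abs(p$imi_age_rho) >= 1 || abs(p$imi_bmi_rho) >= 1)
      stop("correlation targets must lie in (-1, 1)")
  }
  if (handedness_p_right <= 0 || handedness_p_right >= 1)
    stop("handedness_p_right must be in (0, 1)")
  structure(list(female = fp, male = mp,
                 handedness_p_right = handedness_p_right,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# decreasing piecewise-linear age shape with unit post-changepoint slope
age_shape <- function(age, cp, ratio) {
  -(ratio * pmin(age - cp, 0) + pmax(age - cp, 0))
}

# deterministic per-gender coefficients of the IMI model
derive_imi_model <- function(p) {
  hm <- truncnorm_moments(p$height_cm["mean"], p$height_cm["sd"],
                          p$height_cm["mean"] - 4 * p$height_cm["sd"],
                          p$height_cm["mean"] + 4 * p$height_cm["sd"])
  h2_mean <- (hm$mean / 100)^2 + (hm$sd / 100)^2   # E[h^2], h in m
  mu_imi <- p$total_ml["mean"] / h2_mean
  cv_tot <- p$total_ml["sd"] / p$total_ml["mean"]
  cv_h <- hm$sd / hm$mean
  var_share <- cv_tot^2 - 4 * cv_h^2
  if (var_share <= 0)
    stop("total-volume SD too small relative to height SD")
  sigma_imi <- mu_imi * sqrt(var_share)

  am <- truncnorm_moments(p$age["mean"], p$age["sd"],
                          p$age_range[1], p$age_range[2])
  bm <- truncnorm_moments(p$bmi["mean"], p$bmi["sd"],
                          p$bmi_range[1], p$bmi_range[2])

  # moments of the age shape under the truncated age density
  grid <- seq(p$age_range[1], p$age_range[2], by = 0.02)
  w <- dnorm(grid, p$age["mean"], p$age["sd"]); w <- w / sum(w)
  g <- age_shape(grid, p$changepoint_age, p$pre_post_slope_ratio)
  g_mean <- sum(w * g)
  g_var <- sum(w * (g - g_mean)^2)
  age_mean <- sum(w * grid)
  cov_g_age <- sum(w * (g - g_mean) * (grid - age_mean))
  age_sd <- sqrt(sum(w * (grid - age_mean)^2))

  rho_p_age <- 2 * sin(pi * p$imi_age_rho / 6)
  rho_p_bmi <- 2 * sin(pi * p$imi_bmi_rho / 6)
  A <- rho_p_age * age_sd * sigma_imi / cov_g_age
  beta <- rho_p_bmi * sigma_imi / bm$sd
  var_eps <- sigma_imi^2 - A^2 * g_var - beta^2 * bm$sd^2
  if (var_eps <= 0)
    stop("correlation targets leave no residual IMI variance")
  list(mu_imi = mu_imi, sigma_imi = sigma_imi, A = A, beta = beta,
       sd_eps = sqrt(var_eps), g_mean = g_mean, bmi_mean_trunc = bm$mean,
       height_moments = hm)
}

generate_gender <- function(p, n, gender, p_right) {
  if (n == 0L) return(NULL)
  mod <- derive_imi_model(p)
  age <- rtruncnorm(n, p$age["mean"], p$age["sd"],
                    p$age_range[1], p$age_range[2])
  height <- rtruncnorm(n, p$height_cm["mean"], p$height_cm["sd"],
                       p$height_cm["mean"] - 4 * p$height_cm["sd"],
                       p$height_cm["mean"] + 4 * p$height_cm["sd"])
  bmi <- rtruncnorm(n, p$bmi["mean"], p$bmi["sd"],
                    p$bmi_range[1], p$bmi_range[2])
  eps <- rnorm(n, 0, mod$sd_eps)
  lr <- rtruncnorm(n, p$lr_diff_ml["mean"], p$lr_diff_ml["sd"],
                   p$lr_range[1], p$lr_range[2])
  handedness <- ifelse(runif(n) < p_right, "right", "left")

  g <- age_shape(age, p$changepoint_age, p$pre_post_slope_ratio)
  imi <- mod$mu_imi + mod$A * (g - mod$g_mean) +
    mod$beta * (bmi - mod$bmi_mean_trunc) + eps
  total <- imi * (height / 100)^2
  left <- (total + lr) / 2
  right <- (total - lr) / 2
  if (any(left <= 0) || any(right <= 0))
    stop("generated non-positive muscle volume; check parameters")
  data.frame(
    gender = gender, age_years = age, height_cm = height,
    weight_kg = bmi * (height / 100)^2, bmi = bmi, handedness = handedness,
    imi_target = imi, target_total_ml = total,
    target_left_ml = left, target_right_ml = right, lr_diff_ml = lr,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic demographic cohort
#'
#' Draws per-subject demographics and target left/right muscle volumes
#' whose joint distribution matches the configured population: marginal
#' means/SDs, right-larger-than-left asymmetry, positive volume-height and
#' IMI-BMI rank correlations, and a negative IMI-age trend that for men
#' steepens after the changepoint age.
#'
#' @param params a [cohort_params()]
#' @param n_female,n_male subjects per gender (either may be 0)
#' @param seed overrides `params$seed` when given
#' @return a data.frame with one row per subject: `subject_id`, `gender`,
#'   `age_years`, `height_cm`, `weight_kg`, `bmi`, `handedness`,
#'   `imi_target`, `target_total_ml`, `target_left_ml`, `target_right_ml`,
#'   `lr_diff_ml`
#' @export
generate_cohort <- function(params = cohort_params(), n_female, n_male,
                            seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  n_female <- as.integer(n_female); n_male <- as.integer(n_male)
  if (n_female < 0L || n_male < 0L || n_female + n_male < 1L)
    stop("need at least one subject")
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  tab <- with_seed(seed, {
    rbind(
      generate_gender(params$female, n_female, "female",
                      params$handedness_p_right),
      generate_gender(params$male, n_male, "male",
                      params$handedness_p_right)
    )
  })
  tab <- cbind(subject_id = sprintf("S%05d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}
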