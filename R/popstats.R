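# Population statistics: normality gating, rank-based tests, rank
# correlations, and spline age trends.
#
# The Wilcoxon tests are implemented here (exact permutation/sign-flip
# enumeration for small samples, tie- and continuity-corrected normal
# approximation otherwise) so that the small-sample branches are open to
# direct enumeration checks; all p-values are two-sided.

stat_result <- function(test_name, statistic, p_value, effect, n) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, effect = effect, n = n),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.3g (n = %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Downstream analyses select rank-based tests when the gate rejects
#' normality at the 0.05 level.
#' @param x numeric sample, 3 <= n <= 5000
#' @return a `stat_test_result` with `effect$use_rank_tests`
#' @export
normality_gate <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (sd(x) == 0) stop("degenerate input: sample is constant")
  sw <- shapiro.test(x)
  stat_result("shapiro_wilk", unname(sw$statistic), sw$p.value,
              list(use_rank_tests = sw$p.value < 0.05), n)
}

#' Spearman's rank correlation
#'
#' Product-moment correlation of mid-ranks (ties averaged), with a
#' two-sided t-approximation p-value.
#' @param x,y numeric vectors of equal length, n >= 3
#' @return a `stat_test_result`; `effect$rho` is the correlation
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero variance in ranks (constant input)")
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  stat_result("spearman", rho, min(1, p), list(rho = rho), n)
}

# tie term sum(t^3 - t) over tied groups
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided.  Exact permutation enumeration of all rank assignments when
#' `n_a + n_b <= exact_limit` (default 12, ties handled through mid-ranks);
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric samples
#' @param exact_limit total-n crossover to the approximation (default 12)
#' @return a `stat_test_result`; statistic is W, the rank sum of `a`
#' @export
rank_sum_test <- function(a, b, exact_limit = 12L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  n <- na + nb
  ew <- na * (n + 1) / 2
  if (n <= exact_limit) {
    combos <- combn(n, na)
    ws <- colSums(matrix(r[combos], nrow = na))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-9)
  } else {
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term(r) / (n * (n - 1)))
    z <- (w - ew - sign(w - ew) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  stat_result("wilcoxon_rank_sum", w, p,
              list(median_a = median(a), median_b = median(b),
                   mean_a = mean(a), mean_b = mean(b)),
              c(na, nb))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on `left - right`.  Zero differences are dropped, ties
#' mid-ranked; exact sign-flip enumeration when the number of non-zero
#' differences is `<= exact_limit` (default 12), else the tie- and
#' continuity-corrected normal approximation.  The reported effect `d` is
#' the mean difference over all pairs.
#'
#' @param left,right paired numeric vectors
#' @param exact_limit crossover to the approximation (default 12)
#' @return a `stat_test_result`; statistic is W+, the positive rank sum
#' @export
signed_rank_test <- function(left, right, exact_limit = 12L) {
  if (length(left) != length(right)) stop("pairs must have equal length")
  keep <- is.finite(left) & is.finite(right)
  d_all <- left[keep] - right[keep]
  d <- d_all[d_all != 0]
  n <- length(d)
  if (n < 1L) stop("all paired differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ew <- sum(r) / 2
  if (n <= exact_limit) {
    ws <- vapply(0:(2^n - 1), function(bits) {
      sum(r[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0])
    }, numeric(1))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-9)
  } else {
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term(r) / 48
    z <- (w - ew - sign(w - ew) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  stat_result("wilcoxon_signed_rank", w, p,
              list(d = mean(d_all), n_zero = sum(d_all == 0)),
              length(d_all))
}

#' Penalized cubic-spline age trend of IMI
#'
#' Fits `imi ~ s(age, bs = "cr", k = basis_dim)` (a generalized additive
#' model with cubic regression splines, smoothness chosen by GCV), per
#' gender when one is supplied, and evaluates the fitted mean and its
#' numerical first derivative on an age grid spanning the observed range.
#'
#' @param age,imi numeric vectors
#' @param gender optional factor splitting the fit
#' @param basis_dim spline basis dimension (default 10)
#' @param grid_length evaluation grid size (default 200)
#' @return object of class `trend_fit` (or named list of them per gender):
#'   `grid`, `fit`, `derivative`, `gam`
#' @export
fit_age_trend <- function(age, imi, gender = NULL, basis_dim = 10L,
                          grid_length = 200L) {
  if (!is.null(gender)) {
    out <- lapply(split(seq_along(age), gender), function(idx) {
      fit_age_trend(age[idx], imi[idx], NULL, basis_dim, grid_length)
    })
    return(out)
  }
  keep <- is.finite(age) & is.finite(imi)
  age <- age[keep]; imi <- imi[keep]
  if (length(age) < 20L) stop("need at least 20 observations per fit")
  df <- data.frame(age = age, imi = imi)
  g <- mgcv::gam(imi ~ s(age, bs = "cr", k = basis_dim), data = df,
                 method = "GCV.Cp")
  grid <- seq(min(age), max(age), length.out = grid_length)
  fit <- as.numeric(predict(g, newdata = data.frame(age = grid)))
  deriv <- c(NA, diff(fit) / diff(grid))
  structure(list(grid = grid, fit = fit, derivative = deriv, gam = g),
            class = "trend_fit")
}

#' Association between handedness and left-right volume asymmetry
#'
#' Rank-sum test of `lr_diff_ml` between right- and left-handed subjects.
#' @param records volume records with `handedness` and `lr_diff_ml`
#' @return a `stat_test_result`
#' @export
handedness_association <- function(records) {
  groups <- split(records$lr_diff_ml, records$handedness)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2L)
    stop("need at least two handedness groups")
  rank_sum_test(groups[["right"]], groups[["left"]])
}

#' Full population analysis of a volume-record table
#'
#' Runs the standard battery: Shapiro-Wilk gates, male-female rank-sum
#' comparisons of total volume and IMI, per-gender signed-rank tests of
#' left vs right, Spearman correlations (volume-height, IMI-BMI,
#' IMI-age), the handedness association, and per-gender spline age trends.
#'
#' @param records data.frame of volume records (see [quantify_subject()])
#' @return object of class `cohort_analysis`
#' @export
analyze_cohort <- function(records) {
  by_g <- split(records, records$gender)
  gate_n <- function(x) normality_gate(if (length(x) > 5000) {
    x[seq(1, length(x), length.out = 5000)]
  } else x)
  out <- list(
    n = nrow(records),
    normality = lapply(by_g, function(d) gate_n(d$total_ml)),
    gender_total = rank_sum_test(by_g$male$total_ml, by_g$female$total_ml),
    gender_imi = rank_sum_test(by_g$male$imi, by_g$female$imi),
    asymmetry = lapply(by_g, function(d)
      signed_rank_test(d$left_ml, d$right_ml)),
    volume_height = lapply(by_g, function(d)
      spearman_rho(d$total_ml, d$height_cm)),
    imi_bmi = lapply(by_g, function(d) spearman_rho(d$imi, d$bmi)),
    imi_age = lapply(by_g, function(d) spearman_rho(d$imi, d$age_years)),
    handedness = tryCatch(handedness_association(records),
                          error = function(e) NULL),
    age_trend = fit_age_trend(records$age_years, records$imi,
                              records$gender)
  )
  structure(out, class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>", x$n, "subjects\n")
  fmt_g <- function(lst, label, field = "rho") {
    vals <- vapply(lst, function(s) s$effect[[field]] %||% s$statistic,
                   numeric(1))
    cat(sprintf("  %s: %s\n", label,
                paste(sprintf("%s %.3f", names(vals), vals), collapse = ", ")))
  }
  cat(sprintf("  male vs female total volume: p = %.3g\n",
              x$gender_total$p_value))
  fmt_g(x$asymmetry, "L-R mean difference d (ml)", "d")
  fmt_g(x$volume_height, "Spearman rho(volume, height)")
  fmt_g(x$imi_bmi, "Spearman rho(IMI, BMI)")
  fmt_g(x$imi_age, "Spearman rho(IMI, age)")
  if (!is.null(x$handedness))
    cat(sprintf("  handedness vs asymmetry: p = %.3g\n",
                x$handedness$p_value))
  invisible(x)
}

#' Write the standard population figures as PDF files
#'
#' Asymmetry-by-gender boxplot, volume-height and IMI-BMI scatterplots,
#' and the per-gender spline age trend.
#' @param records volume records
#' @param dir output directory
#' @return character vector of written paths
#' @export
plot_cohort_figures <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  save_plot <- function(name, expr) {
    p <- file.path(dir, name)
    pdf(p, width = 6, height = 5)
    on.exit(dev.off(), add = TRUE)
    force(expr)
    paths <<- c(paths, p)
  }
  save_plot("asymmetry_by_gender.pdf",
            boxplot(lr_diff_ml ~ gender, data = records,
                    ylab = "left - right volume (ml)"))
  save_plot("volume_by_height.pdf", {
    cols <- ifelse(records$gender == "male", "steelblue", "indianred")
    plot(records$height_cm, records$total_ml, col = cols, pch = 16,
         cex = 0.4, xlab = "height (cm)", ylab = "total volume (ml)")
  })
  save_plot("imi_by_bmi.pdf", {
    cols <- ifelse(records$gender == "male", "steelblue", "indianred")
    plot(records$bmi, records$imi, col = cols, pch = 16, cex = 0.4,
         xlab = "BMI (kg/m^2)", ylab = "IMI (ml/m^2)")
  })
  save_plot("imi_by_age.pdf", {
    cols <- ifelse(records$gender == "male", "steelblue", "indianred")
    plot(records$age_years, records$imi, col = cols, pch = 16, cex = 0.3,
         xlab = "age (years)", ylab = "IMI (ml/m^2)")
    trends <- fit_age_trend(records$age_years, records$imi, records$gender)
    for (g in names(trends))
      lines(trends[[g]]$grid, trends[[g]]$fit, lwd = 2,
            col = if (g == "male") "navy" else "darkred")
  })
  paths
}
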