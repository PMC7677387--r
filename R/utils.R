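# shared internal helpers

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG with `seed`, runs `expr`, then restores the caller's RNG
#' state, so seeded generators do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a per-stage seed from a global seed
#'
#' Hashes the stage name onto the global seed so that pipeline stages are
#' independently reproducible.  Result is always in [1, 2^31 - 2].
#' @param seed integer global seed
#' @param stage character stage name
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147483646 + 1)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

is_binary_array <- function(x) {
  all(x == 0 | x == 1)
}

# mean and sd of a normal truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a = -Inf, b = Inf) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  dphi <- dnorm(al) - dnorm(be)
  m <- mu + sigma * dphi / Z
  t1 <- ifelse(is.finite(al), al * dnorm(al), 0)
  t2 <- ifelse(is.finite(be), be * dnorm(be), 0)
  v <- sigma^2 * (1 + (t1 - t2) / Z - (dphi / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# draw from a normal truncated to [a, b] by inverse-CDF sampling
rtruncnorm <- function(n, mu, sigma, a = -Inf, b = Inf) {
  pa <- pnorm(a, mu, sigma); pb <- pnorm(b, mu, sigma)
  qnorm(pa + runif(n) * (pb - pa), mu, sigma)
}
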