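#' Largest-remainder apportionment
#'
#' Splits `n` items across categories in proportion to `proportions`,
#' guaranteeing the integer counts sum exactly to `n`. Quotas are floored
#' and the remaining items go to the categories with the largest
#' fractional remainders (ties broken by position).
#'
#' @param n Total count to apportion.
#' @param proportions Non-negative weights; normalised internally.
#' @return Integer vector of counts, named like `proportions`.
#' @examples
#' apportion(742, c(ER = 193, TR = 338, PR = 211))
#' @export
apportion <- function(n, proportions) {
  stopifnot(length(n) == 1L, n >= 0, all(proportions >= 0), sum(proportions) > 0)
  p <- proportions / sum(proportions)
  quota <- n * p
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# One child seed per permutation so any single permutation can be re-run
# in isolation: set.seed(base), then draw n integers below 2^31.
spawn_seeds <- function(base_seed, n) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Truncated normal by rejection; vectorised over n.
rnorm_trunc <- function(n, mean, sd, lower, upper, max_tries = 1000L) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(out[bad], lower), upper)
  out
}

# Skew-normal draws via the convolution representation
# (delta|Z0| + sqrt(1-delta^2) Z1), truncated to [lower, upper] by rejection.
rskewnorm_trunc <- function(n, xi, omega, alpha, lower, upper) {
  delta <- alpha / sqrt(1 + alpha^2)
  draw <- function(m) {
    z0 <- abs(rnorm(m))
    z1 <- rnorm(m)
    xi + omega * (delta * z0 + sqrt(1 - delta^2) * z1)
  }
  out <- draw(n)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- draw(length(bad))
    bad <- which(out < lower | out > upper)
  }
  out
}

mae <- function(truth, pred) mean(abs(truth - pred))

#' Error of an age-blind mean predictor
#'
#' The mean absolute deviation of ages from their mean: the expected MAE of
#' a model that carries no age information and always predicts the sample
#' mean. Used as the no-signal reference when judging whether an ensemble
#' has learned anything.
#'
#' @param ages Numeric vector of chronological ages.
#' @return A single number, in years.
#' @export
null_model_mae <- function(ages) mean(abs(ages - mean(ages)))
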