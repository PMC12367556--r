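#' Exact two-sided binomial test computed in log space
#'
#' Minimum-likelihood ("minlike") two-sided exact binomial test: the p-value is
#' the sum of all outcome probabilities no larger than that of the observed
#' count, the convention used by sign-test summaries throughout adipose
#' remodelling analyses (e.g. concordant up/down gene or reaction counts
#' against a null of 0.5). All point masses are evaluated as log-probabilities
#' and summed by log-sum-exp, so p-values remain accurate far below the double
#' underflow limit (log10 p down to about -300 and beyond in log form).
#'
#' @param k integer number of successes, `0 <= k <= n`.
#' @param n integer number of trials.
#' @param p0 null success probability, in (0, 1). Default 0.5 (sign test).
#' @param tie_rel relative tolerance when comparing point masses to the
#'   observed mass, stabilising floating-point ties at the fringe.
#' @return An object of class `binom_test_result`: a list with `k`, `n`, `p0`,
#'   `p_two_sided` (capped at 1) and `log10_p` (exact even when
#'   `p_two_sided` underflows).
#' @examples
#' exact_binomial_two_sided(213, 333)$p_two_sided  # ~3.9e-07
#' exact_binomial_two_sided(6, 12)$p_two_sided     # central outcome -> 1
#' @export
exact_binomial_two_sided <- function(k, n, p0 = 0.5, tie_rel = 1e-7) {
  if (length(k) != 1L || length(n) != 1L || length(p0) != 1L)
    stop("k, n and p0 must be scalars")
  if (!is.finite(k) || !is.finite(n) || k != round(k) || n != round(n))
    stop("k and n must be integers")
  if (n < 0 || k < 0 || k > n) stop("require 0 <= k <= n")
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")

  lp <- stats::dbinom(0:n, n, p0, log = TRUE)
  obs <- lp[k + 1L]
  keep <- lp <= obs + log1p(tie_rel)
  ls <- logsumexp(lp[keep])
  ls <- min(ls, 0)
  structure(
    list(k = as.integer(k), n = as.integer(n), p0 = p0,
         p_two_sided = exp(ls), log10_p = ls / log(10)),
    class = "binom_test_result"
  )
}

#' @export
print.binom_test_result <- function(x, ...) {
  cat(sprintf("Exact binomial test (two-sided, minlike): k = %d, n = %d, p0 = %g\n",
              x$k, x$n, x$p0))
  cat(sprintf("  p = %.4g  (log10 p = %.4f)\n", x$p_two_sided, x$log10_p))
  invisible(x)
}

logsumexp <- function(v) {
  if (length(v) == 0L) return(-Inf)
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`,
#' the FDR procedure used for all multiple-comparison corrections in the
#' pipeline.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA`s are propagated.
#' @return adjusted p-values, same order and length as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1] at position(s): ",
                     paste(which(bad), collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with average-rank ties
#'
#' Pearson correlation of average ranks. The two-sided p-value uses the
#' t-approximation for n >= 10 and the exact conditional permutation null
#' (all n! label permutations) for n < 10, where the approximation is poor.
#' Constant input yields an explicitly flagged undefined result rather than a
#' silent zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n` and `defined` (FALSE when either input is
#'   constant, in which case `rho` and `p` are `NA`).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  # clamp tiny float excursions outside [-1, 1]
  rho <- max(-1, min(1, rho))
  if (n >= 10L) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    perms <- e1071::permutations(n)
    mrx <- rx - mean(rx)
    sy <- ry - mean(ry)
    denom <- sqrt(sum(mrx^2) * sum(sy^2))
    rho_null <- (matrix(sy[perms], nrow = nrow(perms)) %*% mrx) / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(1, p), n = n, defined = TRUE)
}
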