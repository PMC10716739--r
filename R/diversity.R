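# Hill-number alpha diversity: observed values and asymptotic
# (infinite-sample) estimators, plus the rank-correlation utility linking
# diversity to oxidation rates.

#' Observed Hill number of order q
#'
#' `q = 0` is species richness, `q = 1` the exponential of Shannon entropy,
#' `q = 2` the inverse Simpson index; other orders use the general form
#' `(sum p^q)^(1/(1-q))`.
#'
#' @param counts non-negative count vector with at least one positive entry.
#' @param q diversity order.
#' @return the Hill number (>= 1).
#' @export
#' @examples
#' hill_observed(c(10, 10, 10, 10), 1)  # 4
hill_observed <- function(counts, q) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (all(counts == 0)) stop("all counts are zero; diversity undefined")
  p <- counts[counts > 0] / sum(counts)
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Asymptotic Hill number of order q
#'
#' Infinite-sample estimators — the asymptotes that rarefaction/extrapolation
#' curves converge to:
#' \itemize{
#'   \item `q = 0`: Chao1, `S_obs + f1^2/(2 f2)` (bias-corrected
#'     `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`), with `f1`, `f2`
#'     the singleton and doubleton counts.
#'   \item `q = 1`: exponential of the Chao-Jost coverage-based entropy
#'     estimator (Chao, Wang & Jost 2013).
#'   \item `q = 2`: inverse of the minimum-variance unbiased Simpson
#'     estimator `sum x (x - 1) / (n (n - 1))`.
#' }
#'
#' @param counts non-negative integer count vector, total >= 2.
#' @param q diversity order, one of 0, 1, 2.
#' @return the estimated asymptotic Hill number.
#' @export
hill_asymptotic <- function(counts, q) {
  stopifnot(is.numeric(counts), all(counts >= 0), q %in% c(0, 1, 2))
  x <- counts[counts > 0]
  n <- sum(x)
  if (n < 2) stop("at least 2 individuals required")
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (q == 0) {
    s <- length(x)
    return(if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  if (q == 1) {
    # sum_{k=x}^{n-1} 1/k = digamma(n) - digamma(x)
    part1 <- sum(x / n * (digamma(n) - digamma(x)))
    A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
      else if (f1 > 0) 2 / ((n - 1) * (f1 - 1) + 2)
      else 1
    part2 <- 0
    if (f1 > 0 && A < 1) {
      r <- seq_len(n - 1)
      part2 <- f1 / n * (1 - A)^(1 - n) * (-log(A) - sum((1 - A)^r / r))
    }
    return(exp(part1 + part2))
  }
  est <- sum(x * (x - 1)) / (n * (n - 1))
  if (est == 0) stop("all species are singletons; unbiased Simpson estimator is zero")
  1 / est
}

#' Hill diversity table for a count matrix
#'
#' @param counts sample x ASV count matrix.
#' @param q diversity orders (default 0, 1, 2).
#' @return data.frame (sample_id, q, observed, asymptotic). The asymptotic
#'   column holds infinite-sample estimators, not size-specific
#'   rarefaction/extrapolation values.
#' @export
hill_diversity <- function(counts, q = c(0, 1, 2)) {
  validate_counts(counts)
  out <- expand.grid(sample_id = rownames(counts), q = q,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$observed <- mapply(function(s, qq) hill_observed(counts[s, ], qq),
                         out$sample_id, out$q)
  out$asymptotic <- mapply(function(s, qq) hill_asymptotic(counts[s, ], qq),
                           out$sample_id, out$q)
  out[order(out$sample_id, out$q), ]
}

#' Spearman rank correlation
#'
#' Average-rank tie handling with the t-distribution approximation for the
#' p-value; used to relate oxidation rates to abundance and alpha diversity.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector; Spearman correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
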