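#' Multivariate normal sample with exact empirical moments
#'
#' Draws an `n x q` Gaussian sample and transforms it so that its sample mean
#' equals `mean` and its sample covariance (denominator `n - 1`) equals `cov`
#' exactly, removing sampling variability in the first two moments. The raw
#' draws are demeaned, whitened with the inverse Cholesky factor of their own
#' sample covariance, recolored with the Cholesky factor of `cov`, and shifted
#' by `mean`. The result is Gaussian up to this moment-matching transform.
#'
#' @param n number of rows; must exceed `length(mean)` so the empirical
#'   covariance of the raw draws is nonsingular.
#' @param mean numeric vector of target sample means.
#' @param cov symmetric positive-definite target sample covariance matrix
#'   (a scalar is accepted for the univariate case).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return an `n x q` numeric matrix.
#' @examples
#' x <- rmvn_exact(200, c(3, 0.2), matrix(c(1, .15, .15, .25), 2), seed = 1)
#' max(abs(cov(x) - matrix(c(1, .15, .15, .25), 2))) # ~1e-16
#' @export
rmvn_exact <- function(n, mean, cov, seed = NULL) {
  mean <- as.numeric(mean)
  q <- length(mean)
  cov <- as.matrix(cov)
  if (!identical(dim(cov), c(q, q)) && !(q == 1L && length(cov) == 1L)) {
    stop("`cov` must be a ", q, "x", q, " matrix matching `mean`")
  }
  dim(cov) <- c(q, q)
  if (!is_symmetric_pd(cov)) {
    ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(
      "`cov` is not symmetric positive-definite (smallest eigenvalue %.3g)",
      min(ev)
    ))
  }
  if (n <= q) {
    stop("`n` must exceed the dimension (", q,
         "): whitening the raw draws is singular otherwise")
  }
  z <- with_seed(seed, matrix(stats::rnorm(n * q), n, q))
  zc <- sweep(z, 2, colMeans(z))
  rz <- chol(stats::cov(zc))
  rs <- chol(cov)
  x <- zc %*% backsolve(rz, rs)
  sweep(x, 2, mean, `+`)
}
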