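#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic functions in the package route through this so that a given
## seed yields bitwise-identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Counter-based child seeds: any single replication is regenerable in
## isolation from (master seed, replication index). Kept strictly below 2^31.
child_seed <- function(master, index) {
  master <- as.double(master)
  index <- as.double(index)
  m <- 2147483629 # largest prime < 2^31
  s <- (master %% m) * 48271 %% m
  s <- (s + index * 69621) %% m
  as.integer(s + 1)
}

is_symmetric_pd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

## Sample covariance with divisor n (the maximum-likelihood moment used by the
## discrepancy function), as opposed to stats::cov's divisor n - 1.
cov_ml <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
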