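#' Simulate one cohort sample from a growth population
#'
#' Draws per-individual true growth factors (and the covariate W, when the
#' population defines one) with *exactly* the population means and covariances
#' (see [rmvn_exact()]), then overlays independent Gaussian measurement noise
#' wave by wave so each observed repeated measure carries the population's
#' per-wave explained variance. The exact-moment transform applies to the
#' latent factors only; the noise is drawn stochastically, since sampling
#' variability of the observed measures is what the study quantifies.
#'
#' @param pop a [growth_population()].
#' @param n number of individuals (replicants).
#' @param seed integer seed; the sample is bitwise reproducible from
#'   `(pop, n, seed)`.
#' @param noise_rule `"per_wave"` scales the noise variance to the true-score
#'   variance at each wave (the default: R^2 holds at every wave);
#'   `"constant_wave1"` uses the wave-1 noise variance at all waves, a
#'   sensitivity dialect under which later waves are less noisy relative to
#'   their true-score spread.
#' @return an object of class `cohort_sample` with elements `true_factors`
#'   (`n x q`), `observed` (`n x T`), `w` (length-`n` vector or `NULL`),
#'   `noise_variances`, `mask` (missingness indicator, all `FALSE` initially),
#'   `population`, and `seed_record`.
#' @examples
#' s <- sample_cohort(linear_population(), n = 200, seed = 1)
#' colMeans(s$true_factors) # exactly c(3, 0.2)
#' @export
sample_cohort <- function(pop, n, seed = NULL,
                          noise_rule = c("per_wave", "constant_wave1")) {
  stopifnot(inherits(pop, "growth_population"))
  noise_rule <- match.arg(noise_rule)
  q <- pop$degree + 1L
  has_w <- !is.null(pop$covariate)

  if (has_w) {
    joint_cov <- augmented_factor_cov(pop$psi, pop$covariate)
    joint_mean <- c(pop$alpha, pop$covariate$mean)
    draws <- rmvn_exact(n, joint_mean, joint_cov, seed = seed)
    eta <- draws[, seq_len(q), drop = FALSE]
    w <- draws[, q + 1L]
  } else {
    eta <- rmvn_exact(n, pop$alpha, pop$psi, seed = seed)
    w <- NULL
  }
  colnames(eta) <- factor_names(pop$degree)

  noise_seed <- if (is.null(seed)) NULL else child_seed(seed, 1L)
  obs <- add_noise(eta, pop, seed = noise_seed, noise_rule = noise_rule)

  structure(
    list(
      true_factors = eta,
      observed = obs$observed,
      w = w,
      noise_variances = obs$noise_variances,
      mask = matrix(FALSE, n, ncol(obs$observed)),
      population = pop,
      seed_record = list(seed = seed, noise_seed = noise_seed,
                         noise_rule = noise_rule)
    ),
    class = "cohort_sample"
  )
}

factor_names <- function(degree) {
  c("intercept", "slope", "curvature")[seq_len(degree + 1L)]
}

#' Overlay per-wave Gaussian measurement noise on true trajectories
#'
#' The noise variance at wave `t` is `V_t * (1 - R^2) / R^2` where `V_t` is
#' the true-score variance at that wave, so that regressing the observed
#' measure on its true score explains `R^2` of the variance (with the default
#' `R^2 = 0.5`, noise variance equals true-score variance). `r2` may be set
#' to 1 to obtain noise-free observations.
#'
#' @param true_factors `n x q` matrix of true growth factors.
#' @param pop the generating [growth_population()].
#' @param seed optional integer seed.
#' @param r2 explained-variance target; defaults to the population's.
#' @param noise_rule see [sample_cohort()].
#' @return list with `observed` (`n x T`) and `noise_variances` (length `T`).
#' @export
add_noise <- function(true_factors, pop, seed = NULL, r2 = NULL,
                      noise_rule = c("per_wave", "constant_wave1")) {
  stopifnot(inherits(pop, "growth_population"))
  noise_rule <- match.arg(noise_rule)
  r2 <- r2 %||% pop$r2_per_wave
  if (r2 <= 0 || r2 > 1) stop("`r2` must be in (0, 1]")
  tt <- length(pop$time_codes)
  lam <- loading_matrix(pop$time_codes, pop$degree)
  v_true <- true_score_variances(pop)
  sigma2 <- v_true * (1 - r2) / r2
  if (noise_rule == "constant_wave1") sigma2 <- rep(sigma2[1], tt)
  if (any(sigma2 == 0) && r2 < 1) {
    warning("degenerate wave(s) with zero true-score variance: noise set to 0")
  }
  n <- nrow(true_factors)
  true_scores <- true_factors %*% t(lam)
  noise <- with_seed(
    seed,
    matrix(stats::rnorm(n * tt, sd = rep(sqrt(sigma2), each = n)), n, tt)
  )
  observed <- true_scores + noise
  colnames(observed) <- paste0("y", seq_len(tt))
  list(observed = observed, noise_variances = sigma2)
}

#' Draw a covariate with exact sample correlations to the growth factors
#'
#' Extends the exact-moment construction to the joint vector of growth
#' factors and W: given already-generated true factors, W is built as the
#' population-implied linear combination of the (whitened) factors plus an
#' orthogonalized residual, so its sample correlations with the designated
#' factors equal the specification exactly.
#'
#' @param true_factors `n x q` matrix with exact moments (from
#'   [rmvn_exact()]).
#' @param spec covariate list (`r_intercept`, `r_slope`, `mean`, `variance`).
#' @param psi the factor covariance the sample was generated under.
#' @param seed optional integer seed.
#' @return length-`n` numeric vector.
#' @export
sample_covariate <- function(true_factors, spec, psi, seed = NULL) {
  spec <- validate_covariate(spec, psi)
  n <- nrow(true_factors)
  q <- ncol(true_factors)
  joint <- augmented_factor_cov(psi, spec)
  ## conditional regression of W on the factors in the population
  b <- solve(joint[seq_len(q), seq_len(q)], joint[seq_len(q), q + 1L])
  v_res <- joint[q + 1L, q + 1L] -
    drop(crossprod(b, joint[seq_len(q), seq_len(q)] %*% b))
  etac <- sweep(true_factors, 2, colMeans(true_factors))
  z <- with_seed(seed, stats::rnorm(n))
  ## orthogonalize the residual against the factors and normalize its
  ## sample variance exactly, so cov(W, eta) is exactly joint[1:q, q+1]
  z <- stats::lm.fit(cbind(1, etac), z)$residuals
  z <- z / sqrt(sum(z^2) / (n - 1))
  drop(etac %*% b) + sqrt(v_res) * z + spec$mean
}

#' Impose missing data on a cohort sample
#'
#' `mcar` masks each cell independently at `rate`; `attrition` masks
#' monotonically — each individual still in the study drops out before the
#' next wave with per-wave hazard `rate`, and once missing stays missing.
#' Wave 1 is always observed under attrition. Masked cells are set to `NA`
#' in `observed`; `mask` records the pattern.
#'
#' @param sample a [sample_cohort()] result.
#' @param mechanism `"none"`, `"mcar"`, or `"attrition"`.
#' @param rate missingness/dropout probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return the modified `cohort_sample`.
#' @export
impose_missingness <- function(sample,
                               mechanism = c("none", "mcar", "attrition"),
                               rate = 0, seed = NULL) {
  stopifnot(inherits(sample, "cohort_sample"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)")
  n <- nrow(sample$observed)
  tt <- ncol(sample$observed)
  mask <- switch(
    mechanism,
    none = matrix(FALSE, n, tt),
    mcar = with_seed(seed, matrix(stats::runif(n * tt) < rate, n, tt)),
    attrition = with_seed(seed, {
      dropout <- matrix(stats::runif(n * (tt - 1)) < rate, n, tt - 1)
      m <- matrix(FALSE, n, tt)
      for (j in 2:tt) m[, j] <- m[, j - 1] | dropout[, j - 1]
      m
    })
  )
  sample$mask <- mask
  sample$observed[mask] <- NA_real_
  sample$mechanism <- mechanism
  sample
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf("Cohort sample: %d replicants x %d waves (%s population)\n",
              nrow(x$observed), ncol(x$observed), x$population$form))
  cat("Noise variances:", paste(format(x$noise_variances, digits = 4),
                                collapse = ", "), "\n")
  if (!is.null(x$w)) cat("External covariate W present\n")
  if (any(x$mask)) {
    cat(sprintf("Missing cells: %.1f%%\n", 100 * mean(x$mask)))
  }
  invisible(x)
}

#' Convert a cohort sample to a data frame
#'
#' @param x a `cohort_sample`.
#' @param row.names,optional unused, present for generic consistency.
#' @param format `"wide"` (`id, y1..yT[, w]`) or
#'   `"long"` (`id, wave, time, y[, w]`).
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.cohort_sample <- function(x, row.names = NULL, optional = FALSE,
                                        format = c("wide", "long"), ...) {
  format <- match.arg(format)
  n <- nrow(x$observed)
  tt <- ncol(x$observed)
  if (format == "wide") {
    d <- data.frame(id = seq_len(n), x$observed)
    if (!is.null(x$w)) d$w <- x$w
    return(d)
  }
  d <- data.frame(
    id = rep(seq_len(n), times = tt),
    wave = rep(seq_len(tt), each = n),
    time = rep(x$population$time_codes[seq_len(tt)], each = n),
    y = as.vector(x$observed)
  )
  if (!is.null(x$w)) d$w <- rep(x$w, times = tt)
  d[order(d$id, d$wave), , drop = FALSE]
}

#' Write a cohort sample to CSV
#'
#' @param sample a `cohort_sample`.
#' @param path output file path.
#' @param format `"wide"` or `"long"` (see
#'   [as.data.frame.cohort_sample()]).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sample, path, format = c("wide", "long")) {
  utils::write.csv(as.data.frame(sample, format = match.arg(format)),
                   path, row.names = FALSE)
  invisible(path)
}
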