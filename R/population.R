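#' Specify a population of latent growth trajectories
#'
#' A growth population is the generating model for the simulation study: a
#' polynomial functional form (linear or quadratic), the means `alpha` and
#' covariance matrix `psi` of the individual growth factors, the measurement
#' occasions, the per-wave explained-variance target for the observed scores,
#' and an optional external covariate W with fixed correlations to the
#' intercept and slope factors.
#'
#' Time is anchored at the first wave: `time_codes[1]` must be 0, so the
#' intercept is the wave-1 true score and, for quadratic trajectories, the
#' linear factor is the instantaneous slope (tangent) at wave 1.
#'
#' @param form `"linear"` (intercept + slope) or `"quadratic"`
#'   (intercept + instantaneous slope + curvature).
#' @param alpha numeric vector of factor means, length `degree + 1`.
#' @param psi factor covariance matrix; either a full symmetric matrix or the
#'   lower triangle (including the diagonal) listed row by row.
#' @param time_codes strictly increasing measurement occasions starting at 0;
#'   default `0:(n_waves - 1)` (unit spacing).
#' @param n_waves number of waves when `time_codes` is not given
#'   (default 5 for linear, 6 for quadratic).
#' @param r2_per_wave explained variance of each observed repeated measure,
#'   in (0, 1); default 0.50 (noise variance equals true-score variance).
#' @param covariate optional list with elements `r_intercept`, `r_slope`
#'   (correlations of W with the first two growth factors) and optionally
#'   `mean` (default 0) and `variance` (default 1).
#' @return an object of class `growth_population`.
#' @seealso [sample_cohort()], [linear_population()], [quadratic_population()]
#' @export
growth_population <- function(form = c("linear", "quadratic"),
                              alpha,
                              psi,
                              time_codes = NULL,
                              n_waves = NULL,
                              r2_per_wave = 0.5,
                              covariate = NULL) {
  form <- match.arg(form)
  degree <- if (form == "linear") 1L else 2L
  q <- degree + 1L
  alpha <- as.numeric(alpha)
  if (length(alpha) != q) {
    stop("`alpha` must have length ", q, " for a ", form, " population")
  }
  psi <- expand_lower_tri(psi, q)
  if (!is_symmetric_pd(psi)) {
    stop("`psi` must be symmetric positive-definite")
  }
  if (is.null(time_codes)) {
    n_waves <- n_waves %||% (if (form == "linear") 5L else 6L)
    time_codes <- seq(0, n_waves - 1)
  }
  time_codes <- as.numeric(time_codes)
  if (time_codes[1] != 0) {
    stop("`time_codes` must start at 0 (anchors the intercept at wave 1)")
  }
  if (any(diff(time_codes) <= 0)) {
    stop("`time_codes` must be strictly increasing")
  }
  if (length(time_codes) < q) {
    stop("need at least ", q, " waves for a ", form, " population")
  }
  if (!is.numeric(r2_per_wave) || length(r2_per_wave) != 1 ||
      r2_per_wave <= 0 || r2_per_wave >= 1) {
    stop("`r2_per_wave` must be a single value in (0, 1)")
  }
  if (!is.null(covariate)) {
    covariate <- validate_covariate(covariate, psi)
  }
  structure(
    list(
      form = form, degree = degree, alpha = alpha, psi = psi,
      time_codes = time_codes, r2_per_wave = r2_per_wave,
      covariate = covariate
    ),
    class = "growth_population"
  )
}

expand_lower_tri <- function(psi, q) {
  if (is.matrix(psi)) {
    if (!identical(dim(psi), c(q, q))) {
      stop("`psi` must be ", q, "x", q)
    }
    return((psi + t(psi)) / 2)
  }
  psi <- as.numeric(psi)
  if (length(psi) != q * (q + 1) / 2) {
    stop("`psi` must be a ", q, "x", q,
         " matrix or its lower triangle (length ", q * (q + 1) / 2, ")")
  }
  m <- matrix(0, q, q)
  m[upper.tri(m, diag = TRUE)] <- psi # row-by-row lower triangle fills t(m)
  m <- t(m)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

validate_covariate <- function(covariate, psi) {
  if (!is.list(covariate)) stop("`covariate` must be a list")
  r_int <- covariate$r_intercept %||% covariate$r_with_intercept %||% 0
  r_slp <- covariate$r_slope %||% covariate$r_with_slope %||% 0
  out <- list(
    r_intercept = as.numeric(r_int),
    r_slope = as.numeric(r_slp),
    mean = as.numeric(covariate$mean %||% 0),
    variance = as.numeric(covariate$variance %||% 1)
  )
  if (out$variance <= 0) stop("covariate `variance` must be positive")
  ## PD check of the augmented correlation matrix happens here so an invalid
  ## covariate spec is rejected at construction time, not at sampling time.
  augmented_factor_cov(psi, out)
  out
}

## Joint covariance matrix of (growth factors, W) implied by psi and the
## covariate correlations. Errors if the augmented correlation matrix is not
## positive-definite.
augmented_factor_cov <- function(psi, covariate) {
  q <- nrow(psi)
  sds <- sqrt(diag(psi))
  corr <- psi / tcrossprod(sds)
  r_w <- c(covariate$r_intercept, covariate$r_slope, rep(0, q - 2L))[seq_len(q)]
  caug <- rbind(cbind(corr, r_w), c(r_w, 1))
  ev <- eigen(caug, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      paste0("covariate correlations are incompatible with the factor ",
             "correlations: augmented correlation matrix has eigenvalue %.4g"),
      min(ev)
    ))
  }
  s <- c(sds, sqrt(covariate$variance))
  caug * tcrossprod(s)
}

#' Polynomial loading matrix of a latent curve model
#'
#' Column `j + 1` holds the measurement occasions raised to the power `j`,
#' for `j = 0, ..., degree`; with the default unit time codes the linear
#' column is `0, 1, 2, ...` and the quadratic column its squares.
#'
#' @param time_codes numeric vector of measurement occasions.
#' @param degree polynomial degree, 1 (linear) or 2 (quadratic).
#' @return a `length(time_codes) x (degree + 1)` matrix.
#' @examples
#' loading_matrix(0:2, 1)
#' @export
loading_matrix <- function(time_codes, degree) {
  if (!degree %in% c(1, 2)) {
    stop("unsupported functional form: degree must be 1 or 2")
  }
  if (length(time_codes) < degree + 1) {
    stop("need at least ", degree + 1, " waves for degree ", degree)
  }
  outer(as.numeric(time_codes), 0:degree, `^`)
}

#' Per-wave true-score variances implied by a growth population
#'
#' Element `t` is the `t`-th diagonal entry of `Lambda Psi Lambda'`, the
#' variance at wave `t` of the noise-free trajectory values. These variances
#' set the scale of the per-wave measurement noise (see [add_noise()]).
#'
#' @param pop a [growth_population()].
#' @param n_waves how many leading waves to evaluate (default: all).
#' @return numeric vector of length `n_waves`.
#' @export
true_score_variances <- function(pop, n_waves = length(pop$time_codes)) {
  stopifnot(inherits(pop, "growth_population"))
  if (n_waves > length(pop$time_codes)) {
    stop("population defines only ", length(pop$time_codes), " waves")
  }
  lam <- loading_matrix(pop$time_codes[seq_len(n_waves)], pop$degree)
  rowSums((lam %*% pop$psi) * lam)
}

#' Built-in linear growth population
#'
#' Individuals start at 3 on average and gain 0.2 units per wave, with
#' intercept variance 1, slope variance 0.25, and an intercept-slope
#' correlation of 0.3; five yearly waves and 50% explained variance per
#' observed measure.
#'
#' @param n_waves number of waves (default 5).
#' @param r2_per_wave per-wave explained variance (default 0.5).
#' @param covariate optional covariate spec, as in [growth_population()].
#' @return a `growth_population`.
#' @export
linear_population <- function(n_waves = 5, r2_per_wave = 0.5, covariate = NULL) {
  growth_population(
    form = "linear",
    alpha = c(3, 0.2),
    psi = matrix(c(1, 0.15, 0.15, 0.25), 2, 2),
    n_waves = n_waves,
    r2_per_wave = r2_per_wave,
    covariate = covariate
  )
}

#' Built-in quadratic ("emergent") growth population
#'
#' Trajectories rise initially (mean instantaneous slope 3 at wave 1) and
#' level off (mean curvature -0.2), over six waves. Factor variances are
#' (1, 0.5, 0.05); the intercept-slope covariance defaults to the raw value
#' 0.15 but can be set to the value implied by the standardized correlation
#' 0.3 (`intercept_slope_cov = "standardized"`), since the raw and
#' standardized forms of this covariance matrix conflict on that one entry.
#'
#' @param n_waves number of waves (default 6).
#' @param r2_per_wave per-wave explained variance (default 0.5).
#' @param intercept_slope_cov `"raw"` (0.15) or `"standardized"`
#'   (`0.3 * sqrt(0.5)`), or a number.
#' @return a `growth_population`.
#' @export
quadratic_population <- function(n_waves = 6, r2_per_wave = 0.5,
                                 intercept_slope_cov = c("raw", "standardized")) {
  c12 <- if (is.numeric(intercept_slope_cov)) {
    intercept_slope_cov
  } else {
    switch(match.arg(intercept_slope_cov),
           raw = 0.15,
           standardized = 0.3 * sqrt(0.5))
  }
  growth_population(
    form = "quadratic",
    alpha = c(3, 3, -0.2),
    psi = c(1, c12, 0.5, -0.022, -0.079, 0.05),
    n_waves = n_waves,
    r2_per_wave = r2_per_wave
  )
}

#' Read a growth population from a YAML or JSON configuration file
#'
#' Recognized keys: `form`, `alpha`, `psi` (lower-triangle list or nested
#' matrix), `time_codes`, `r2` (or `r2_per_wave`), `covariate`
#' (`r_intercept`, `r_slope`, `mean`, `variance`).
#'
#' @param path file path; format inferred from the extension
#'   (`.json` vs `.yaml`/`.yml`).
#' @return a `growth_population`.
#' @examples
#' cfg <- system.file("extdata", "linear-population.yaml",
#'                    package = "growthrecovery")
#' read_population(cfg)
#' @export
read_population <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  psi <- cfg$psi
  if (is.list(psi)) psi <- do.call(rbind, lapply(psi, as.numeric))
  growth_population(
    form = cfg$form,
    alpha = unlist(cfg$alpha),
    psi = if (is.matrix(psi)) psi else unlist(psi),
    time_codes = if (!is.null(cfg$time_codes)) unlist(cfg$time_codes),
    n_waves = cfg$n_waves,
    r2_per_wave = cfg$r2 %||% cfg$r2_per_wave %||% 0.5,
    covariate = cfg$covariate
  )
}

#' @export
print.growth_population <- function(x, ...) {
  cat(sprintf("Growth population: %s, %d waves (t = %s)\n",
              x$form, length(x$time_codes),
              paste(x$time_codes, collapse = ", ")))
  cat("Factor means (alpha): ", paste(format(x$alpha), collapse = ", "), "\n")
  cat("Factor covariance (psi):\n")
  print(x$psi)
  cat(sprintf("Explained variance per wave (R^2): %.2f\n", x$r2_per_wave))
  if (!is.null(x$covariate)) {
    cat(sprintf("Covariate W: r(int) = %.2f, r(slope) = %.2f\n",
                x$covariate$r_intercept, x$covariate$r_slope))
  }
  invisible(x)
}
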