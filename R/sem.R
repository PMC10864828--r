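#' Fit a latent change score or latent curve model by maximum likelihood
#'
#' Estimates a structural equation growth model on a complete balanced panel
#' (or, when observations are missing, by full-information maximum likelihood
#' over missingness patterns). Two parameterizations are supported:
#'
#' * `kind = "lcs"` — the two-wave latent change score model: the wave-2
#'   score regresses on the wave-1 score with a unit path and loads on a
#'   latent change factor with a unit loading. Residual variances are fixed
#'   to zero (with two waves the model is just identified: five observed
#'   moments, five structural parameters); the model reproduces the observed
#'   moments exactly and the change factor is the raw difference.
#' * `kind = "lcm"` — a latent curve model of polynomial `degree` (1 or 2)
#'   whose factors load on the repeated measures through the time codes
#'   (see [loading_matrix()]).
#'
#' The optimizer works on an unconstrained parameterization — factor means,
#' the Cholesky factor of the factor covariance matrix (log diagonal), and
#' log residual variances — and minimizes the normal-theory discrepancy
#' `F_ML = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p + (ybar - mu)' Sigma^-1
#' (ybar - mu)` with an analytic gradient. Convergence is declared at
#' gradient norm below `1e-6`; a non-converged fit is retried once from a
#' jittered start.
#'
#' When `include_covariate = TRUE`, the observed vector is augmented with the
#' external variable W, whose mean, variance, and covariances with every
#' growth factor are estimated simultaneously (W is modeled as an extra
#' factor with a unit loading and no residual).
#'
#' @param y an `n x T` numeric matrix of repeated measures, or a
#'   [sample_cohort()] object.
#' @param waves number of leading waves to use (defaults to all columns;
#'   models of an in-progress study always consume the earliest waves).
#' @param kind `"lcs"`, `"lcm"`, or `"auto"` (LCS when `waves == 2`,
#'   LCM otherwise).
#' @param degree polynomial degree for the LCM (1 or 2).
#' @param residuals residual-variance structure: `"free"` (one variance per
#'   wave, the default), `"equal"` (one shared variance), or `"zero"`
#'   (no measurement error; only valid for just-identified models where the
#'   number of waves equals the number of factors).
#' @param include_covariate estimate the W block simultaneously; requires
#'   `w` (or a cohort sample carrying one).
#' @param w optional length-`n` covariate vector when `y` is a matrix.
#' @param time_codes measurement occasions; default `0:(waves - 1)` or the
#'   population's when `y` is a cohort sample.
#' @param start optional numeric vector of starting values on the internal
#'   scale (advanced use).
#' @param control list of optimizer settings: `maxit` (default 500),
#'   `reltol` (default 1e-14), `grad_tol` (default 1e-6).
#' @return an object of class `growth_sem`; see [coef.growth_sem()],
#'   [predict.growth_sem()], [summary.growth_sem()].
#' @examples
#' s <- sample_cohort(linear_population(), n = 200, seed = 1)
#' fit <- growth_sem(s, waves = 3)
#' coef(fit)
#' @export
growth_sem <- function(y, waves = NULL,
                       kind = c("auto", "lcs", "lcm"),
                       degree = 1,
                       residuals = c("free", "equal", "zero"),
                       include_covariate = FALSE,
                       w = NULL,
                       time_codes = NULL,
                       start = NULL,
                       control = list()) {
  cl <- match.call()
  kind <- match.arg(kind)
  residuals_given <- !missing(residuals)
  residuals <- match.arg(residuals)

  sample_obj <- NULL
  if (inherits(y, "cohort_sample")) {
    sample_obj <- y
    if (include_covariate) {
      if (is.null(sample_obj$w)) stop("cohort sample carries no covariate W")
      w <- sample_obj$w
    }
    time_codes <- time_codes %||% sample_obj$population$time_codes
    y <- sample_obj$observed
  }
  y <- as.matrix(y)
  waves <- waves %||% ncol(y)
  if (waves > ncol(y)) stop("panel has only ", ncol(y), " waves")
  y <- y[, seq_len(waves), drop = FALSE]
  if (include_covariate && is.null(w)) {
    stop("`include_covariate = TRUE` requires a covariate vector `w`")
  }
  if (!is.null(w) && length(w) != nrow(y)) {
    stop("`w` must have one value per row of `y`")
  }
  time_codes <- (time_codes %||% seq(0, waves - 1))[seq_len(waves)]

  if (kind == "auto") kind <- if (waves == 2) "lcs" else "lcm"
  if (kind == "lcs") {
    if (waves != 2) stop("the latent change score model uses exactly 2 waves")
    if (residuals_given && residuals != "zero") {
      stop("two-wave LCS residual variances are fixed to zero ",
           "(free residuals are unidentified)")
    }
    residuals <- "zero"
    degree <- 1
    lambda <- matrix(c(1, 1, 0, 1), 2, 2) # intercept + latent change
    fnames <- c("intercept", "change")
  } else {
    if (!degree %in% c(1, 2)) stop("`degree` must be 1 or 2")
    q <- degree + 1L
    min_waves <- if (residuals == "zero") q else q + 1L
    if (waves < min_waves) {
      stop(sprintf(
        "a degree-%d latent curve model with '%s' residuals needs at least %d waves (got %d)",
        degree, residuals, min_waves, waves
      ))
    }
    if (residuals == "zero" && waves > q) {
      stop("residuals can be fixed to zero only in just-identified models ",
           "(waves == number of factors)")
    }
    lambda <- loading_matrix(time_codes, degree)
    fnames <- factor_names(degree)
  }

  spec <- make_spec(kind, lambda, fnames, residuals,
                    has_w = include_covariate, waves = waves,
                    time_codes = time_codes)

  x <- if (include_covariate) cbind(y, w = as.numeric(w)) else y
  fiml <- anyNA(x)
  data <- if (fiml) prepare_fiml(x) else prepare_complete(x, spec)

  ctrl <- list(maxit = 500, reltol = 1e-14, grad_tol = 1e-6)
  ctrl[names(control)] <- control

  par0 <- start %||% start_values(spec, x)
  opt <- optimize_fit(spec, data, par0, ctrl)

  build_fit(cl, spec, data, opt, x, sample_obj, fiml)
}

## ---- internal model-spec plumbing -----------------------------------------

make_spec <- function(kind, lambda, fnames, residuals, has_w, waves,
                      time_codes) {
  q <- ncol(lambda)
  m <- q + has_w
  p <- waves + has_w
  lam_aug <- if (has_w) {
    rbind(cbind(lambda, 0), c(rep(0, q), 1))
  } else {
    lambda
  }
  n_theta <- switch(residuals, free = waves, equal = 1L, zero = 0L)
  ltri <- which(lower.tri(diag(m), diag = TRUE))
  lmat_diag <- matrix(FALSE, m, m); diag(lmat_diag) <- TRUE
  list(
    kind = kind, residuals = residuals, has_w = has_w,
    waves = waves, q = q, m = m, p = p,
    lambda = lambda, lam_aug = lam_aug, fnames = fnames,
    time_codes = time_codes,
    n_theta = n_theta,
    i_alpha = seq_len(m),
    i_l = m + seq_len(m * (m + 1) / 2),
    i_tau = m + m * (m + 1) / 2 + seq_len(n_theta),
    ltri = ltri,
    ltri_diag = which(lmat_diag[ltri]),
    npar = m + m * (m + 1) / 2 + n_theta
  )
}

decode_par <- function(spec, par) {
  m <- spec$m
  alpha <- par[spec$i_alpha]
  lvec <- par[spec$i_l]
  ll <- matrix(0, m, m)
  ll[spec$ltri] <- lvec
  diag(ll) <- exp(diag(ll))
  psi <- tcrossprod(ll)
  theta <- switch(spec$residuals,
                  free = exp(par[spec$i_tau]),
                  equal = rep(exp(par[spec$i_tau]), spec$waves),
                  zero = rep(0, spec$waves))
  theta_pad <- c(theta, if (spec$has_w) 0)
  list(alpha = alpha, L = ll, psi = psi, theta = theta,
       theta_pad = theta_pad)
}

#' Model-implied mean vector and covariance matrix
#'
#' Maps a decoded parameter set through the growth-model structure:
#' `mu = Lambda alpha` and `Sigma = Lambda Psi Lambda' + Theta` (augmented
#' with the covariate block when present).
#'
#' @param spec internal model spec (as stored in a fitted `growth_sem`
#'   object's `$spec`).
#' @param alpha factor means (including the W mean when present).
#' @param psi factor covariance matrix (including the W block when present).
#' @param theta per-wave residual variances.
#' @return list with `mean` and `cov`.
#' @keywords internal
#' @export
implied_moments <- function(spec, alpha, psi, theta = NULL) {
  if (length(alpha) != spec$m || !identical(dim(as.matrix(psi)),
                                            c(spec$m, spec$m))) {
    stop("parameter dimensions do not match the model structure")
  }
  theta <- theta %||% rep(0, spec$waves)
  if (length(theta) == 1) theta <- rep(theta, spec$waves)
  if (length(theta) != spec$waves) {
    stop("`theta` must have one variance per wave")
  }
  theta_pad <- c(theta, if (spec$has_w) 0)
  mu <- drop(spec$lam_aug %*% alpha)
  sigma <- spec$lam_aug %*% psi %*% t(spec$lam_aug) + diag(theta_pad, spec$p)
  list(mean = mu, cov = sigma)
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' `F = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p + (ybar - mu)' Sigma^-1
#' (ybar - mu)`, the fitting function minimized by [growth_sem()] for
#' complete data (with `S` the divisor-`n` sample covariance). Zero when the
#' implied moments reproduce the observed moments exactly; returns a large
#' penalty when the implied covariance is numerically singular.
#'
#' @param implied_mean,implied_cov model-implied moments.
#' @param sample_mean,sample_cov observed moments (`sample_cov` must be
#'   positive-definite).
#' @return a nonnegative scalar.
#' @export
fml_discrepancy <- function(implied_mean, implied_cov, sample_mean,
                            sample_cov) {
  p <- length(sample_mean)
  rs <- tryCatch(chol(sample_cov), error = function(e) NULL)
  if (is.null(rs)) {
    stop("sample covariance matrix is singular: degenerate sample")
  }
  r <- tryCatch(chol(implied_cov), error = function(e) NULL)
  if (is.null(r)) return(1e10)
  siginv <- chol2inv(r)
  d <- sample_mean - implied_mean
  2 * sum(log(diag(r))) - 2 * sum(log(diag(rs))) +
    sum(sample_cov * siginv) - p + drop(crossprod(d, siginv %*% d))
}

prepare_complete <- function(x, spec) {
  n <- nrow(x)
  ybar <- colMeans(x)
  s <- cov_ml(x)
  rs <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(rs)) {
    stop("sample covariance matrix is singular: degenerate sample ",
         "(e.g., noise-free data with more waves than growth factors)")
  }
  list(type = "complete", n = n, p = ncol(x), ybar = ybar, s = s,
       logdet_s = 2 * sum(log(diag(rs))))
}

prepare_fiml <- function(x) {
  n <- nrow(x)
  obs <- !is.na(x)
  keep <- rowSums(obs) > 0
  if (!all(keep)) {
    warning(sum(!keep), " rows with no observed values dropped")
    x <- x[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
    n <- nrow(x)
  }
  key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), key)
  patterns <- lapply(groups, function(idx) {
    o <- which(obs[idx[1], ])
    xo <- x[idx, o, drop = FALSE]
    list(
      idx = idx, obs = o, n = length(idx),
      ybar = colMeans(xo),
      s = if (length(idx) > 1) cov_ml(xo) else
        matrix(0, length(o), length(o))
    )
  })
  list(type = "fiml", n = n, p = ncol(x), patterns = patterns, x = x,
       obs = obs)
}

## Objective and analytic gradient on the unconstrained scale. Returns the
## discrepancy (complete data: F_ML; missing data: mean casewise deviance
## core) and its gradient.
objective_grad <- function(spec, data, par) {
  dec <- decode_par(spec, par)
  mom <- implied_moments(spec, dec$alpha, dec$psi, dec$theta)
  mu <- mom$mean
  sigma <- mom$cov
  p <- spec$p

  if (data$type == "complete") {
    r <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(r)) {
      return(list(value = 1e10 + sum(par^2), grad = 2 * par))
    }
    siginv <- chol2inv(r)
    d <- data$ybar - mu
    sid <- siginv %*% d
    f <- 2 * sum(log(diag(r))) - data$logdet_s +
      sum(data$s * siginv) - p + drop(crossprod(d, sid))
    g_sigma <- siginv %*% (sigma - data$s - tcrossprod(d)) %*% siginv
    g_mu <- -2 * sid
  } else {
    f <- 0
    g_sigma <- matrix(0, p, p)
    g_mu <- numeric(p)
    for (pt in data$patterns) {
      o <- pt$obs
      sig_o <- sigma[o, o, drop = FALSE]
      r <- tryCatch(chol(sig_o), error = function(e) NULL)
      if (is.null(r)) {
        return(list(value = 1e10 + sum(par^2), grad = 2 * par))
      }
      siginv <- chol2inv(r)
      d <- pt$ybar - mu[o]
      sid <- siginv %*% d
      wt <- pt$n / data$n
      f <- f + wt * (2 * sum(log(diag(r))) + sum(pt$s * siginv) +
                       drop(crossprod(d, sid)))
      g_o <- siginv %*% (sig_o - pt$s - tcrossprod(d)) %*% siginv
      g_sigma[o, o] <- g_sigma[o, o] + wt * g_o
      g_mu[o] <- g_mu[o] - 2 * wt * sid
    }
  }

  ## chain rule to the unconstrained parameters
  lam <- spec$lam_aug
  g_alpha <- drop(crossprod(lam, g_mu))
  gp <- crossprod(lam, g_sigma %*% lam)
  gl_mat <- 2 * gp %*% dec$L
  gl <- gl_mat[spec$ltri]
  gl[spec$ltri_diag] <- gl[spec$ltri_diag] * diag(dec$L)
  g_tau <- switch(spec$residuals,
    free = dec$theta * diag(g_sigma)[seq_len(spec$waves)],
    equal = sum(dec$theta * diag(g_sigma)[seq_len(spec$waves)]),
    zero = numeric(0)
  )
  list(value = f, grad = c(g_alpha, gl, g_tau))
}

## Starting values from per-replicant least-squares trajectories.
start_values <- function(spec, x) {
  waves <- spec$waves
  y <- x[, seq_len(waves), drop = FALSE]
  lam <- spec$lambda
  q <- spec$q
  complete <- stats::complete.cases(y)
  rows_used <- which(complete)
  yc <- y[complete, , drop = FALSE]
  if (nrow(yc) < q + 2) {
    ## heavily incomplete panels: fall back to wave-wise imputation by means
    yc <- apply(y, 2, function(col) ifelse(is.na(col), mean(col, na.rm = TRUE),
                                           col))
    rows_used <- seq_len(nrow(y))
  }
  b <- yc %*% lam %*% solve(crossprod(lam))
  alpha0 <- colMeans(b)
  resid <- yc - b %*% t(lam)
  v_obs <- apply(yc, 2, stats::var)
  theta0 <- switch(spec$residuals,
    free = pmax(colMeans(resid^2), 0.05 * v_obs, 1e-8),
    equal = max(mean(resid^2), 0.05 * mean(v_obs), 1e-8),
    zero = numeric(0)
  )
  psi0 <- stats::cov(b)
  if (waves > q) {
    ## remove the OLS sampling contribution of the noise from cov(b)
    adj <- mean(theta0) * solve(crossprod(lam))
    psi0 <- psi0 - adj
  }
  if (spec$has_w) {
    w <- x[rows_used, waves + 1]
    ok <- !is.na(w)
    cw <- drop(stats::cov(b[ok, , drop = FALSE], w[ok]))
    psi0 <- rbind(cbind(psi0, cw), c(cw, stats::var(w[ok])))
    alpha0 <- c(alpha0, mean(w, na.rm = TRUE))
  }
  ev <- eigen(psi0, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-4 * max(abs(ev$values), 1e-4))
  psi0 <- ev$vectors %*% (ev$values * t(ev$vectors))
  l0 <- t(chol(psi0))
  diag(l0) <- log(diag(l0))
  c(alpha0, l0[spec$ltri], log(theta0))
}

optimize_fit <- function(spec, data, par0, ctrl) {
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- objective_grad(spec, data, par)
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) eval_at(par)$value
  gr <- function(par) eval_at(par)$grad

  run_once <- function(p0) {
    opt <- stats::optim(p0, fn, gr, method = "BFGS",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol))
    gnorm <- max(abs(gr(opt$par)))
    ## alternate polish passes: BFGS can stall short of the strict gradient
    ## criterion in flat directions (tiny factor variances); nlminb and a
    ## re-warmed BFGS usually finish the job
    cycles <- 0L
    while (gnorm > ctrl$grad_tol && cycles < 3L) {
      cycles <- cycles + 1L
      pol <- stats::nlminb(opt$par, fn, gr,
                           control = list(iter.max = ctrl$maxit,
                                          rel.tol = 1e-15))
      if (pol$objective <= opt$value + 1e-12) {
        opt$par <- pol$par
        opt$value <- pol$objective
      }
      re <- stats::optim(opt$par, fn, gr, method = "BFGS",
                         control = list(maxit = ctrl$maxit,
                                        reltol = ctrl$reltol))
      if (re$value <= opt$value + 1e-12) {
        opt$par <- re$par
        opt$value <- re$value
      }
      gnorm <- max(abs(gr(opt$par)))
    }
    list(par = opt$par, value = opt$value, counts = opt$counts,
         grad_norm = gnorm, converged = gnorm <= ctrl$grad_tol)
  }

  res <- run_once(par0)
  retries <- 0L
  if (!res$converged) {
    retries <- 1L
    jitter <- with_seed(1L, stats::rnorm(length(par0), sd = 0.1))
    res2 <- run_once(par0 + jitter)
    if (res2$converged || res2$value < res$value) res <- res2
  }
  res$retries <- retries
  res
}

build_fit <- function(cl, spec, data, opt, x, sample_obj, fiml) {
  dec <- decode_par(spec, opt$par)
  mom <- implied_moments(spec, dec$alpha, dec$psi, dec$theta)
  q <- spec$q
  names(dec$alpha) <- c(spec$fnames, if (spec$has_w) "w")
  dimnames(dec$psi) <- list(names(dec$alpha), names(dec$alpha))

  w_block <- NULL
  if (spec$has_w) {
    covs <- dec$psi[spec$m, seq_len(q)]
    cors <- covs / sqrt(dec$psi[spec$m, spec$m] * diag(dec$psi)[seq_len(q)])
    w_block <- list(mean = unname(dec$alpha[spec$m]),
                    variance = unname(dec$psi[spec$m, spec$m]),
                    cov = covs, cor = cors)
  }

  if (data$type == "complete") {
    discrepancy <- opt$value
    ll <- -data$n / 2 * (data$p * log(2 * pi) + data$logdet_s + data$p +
                           opt$value)
  } else {
    discrepancy <- opt$value
    n_obs <- sum(data$obs)
    ll <- -0.5 * (data$n * opt$value + log(2 * pi) * n_obs)
  }

  structure(
    list(
      call = cl,
      kind = spec$kind,
      degree = if (spec$kind == "lcs") 1L else spec$q - 1L,
      waves = spec$waves,
      n = data$n,
      spec = spec,
      alpha = dec$alpha[seq_len(q)],
      psi = dec$psi[seq_len(q), seq_len(q), drop = FALSE],
      theta = stats::setNames(dec$theta,
                              paste0("y", seq_len(spec$waves))),
      psi_full = dec$psi,
      alpha_full = dec$alpha,
      w_block = w_block,
      implied_mean = mom$mean,
      implied_cov = mom$cov,
      sample_mean = if (data$type == "complete") data$ybar else NULL,
      sample_cov = if (data$type == "complete") data$s else NULL,
      discrepancy = discrepancy,
      logLik = ll,
      fiml = fiml,
      convergence = list(converged = opt$converged,
                         grad_norm = opt$grad_norm,
                         iterations = unname(opt$counts[1]),
                         retries = opt$retries),
      par = opt$par,
      data = x,
      sample = sample_obj
    ),
    class = "growth_sem"
  )
}
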