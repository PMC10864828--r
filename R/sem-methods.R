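#' @export
print.growth_sem <- function(x, digits = 4, ...) {
  label <- if (x$kind == "lcs") {
    "Latent change score model (2 waves)"
  } else {
    sprintf("Latent curve model (degree %d, %d waves)", x$degree, x$waves)
  }
  cat(label, if (x$fiml) "[FIML, missing data]", "\n")
  cat("Factor means (alpha):\n")
  print(round(x$alpha, digits))
  cat("Factor covariance (psi):\n")
  print(round(x$psi, digits))
  if (x$spec$residuals != "zero") {
    cat("Residual variances (theta):\n")
    print(round(x$theta, digits))
  } else {
    cat("Residual variances fixed to zero\n")
  }
  if (!is.null(x$w_block)) {
    cat("Covariate W correlations:\n")
    print(round(x$w_block$cor, digits))
  }
  cat(sprintf("Discrepancy: %.6g | converged: %s (|grad| = %.2g)\n",
              x$discrepancy, x$convergence$converged,
              x$convergence$grad_norm))
  invisible(x)
}

#' Summarize a fitted growth model
#'
#' @param object a [growth_sem()] fit.
#' @param ... unused.
#' @return a `summary.growth_sem` list with the estimates, implied moments,
#'   discrepancy, and convergence record.
#' @export
summary.growth_sem <- function(object, ...) {
  structure(
    list(
      call = object$call, kind = object$kind, degree = object$degree,
      waves = object$waves, n = object$n,
      alpha = object$alpha, psi = object$psi, theta = object$theta,
      w_block = object$w_block,
      implied_mean = object$implied_mean, implied_cov = object$implied_cov,
      discrepancy = object$discrepancy, logLik = object$logLik,
      fiml = object$fiml,
      convergence = object$convergence
    ),
    class = "summary.growth_sem"
  )
}

#' @export
print.summary.growth_sem <- function(x, digits = 4, ...) {
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("%s, n = %d, log-likelihood = %.3f, F_ML = %.6g\n",
              if (x$kind == "lcs") "Latent change score model"
              else sprintf("Latent curve model (degree %d)", x$degree),
              x$n, x$logLik, x$discrepancy))
  cat("\nFixed effects (factor means):\n")
  print(round(x$alpha, digits))
  cat("\nRandom effects (factor covariance):\n")
  print(round(x$psi, digits))
  if (length(x$theta)) {
    cat("\nResidual variances:\n")
    print(round(x$theta, digits))
  }
  if (!is.null(x$w_block)) {
    cat("\nCovariate W block (covariances / correlations):\n")
    print(round(rbind(cov = x$w_block$cov, cor = x$w_block$cor), digits))
  }
  cat(sprintf("\nConverged: %s (|grad| = %.2g, retries = %d)\n",
              x$convergence$converged, x$convergence$grad_norm,
              x$convergence$retries))
  invisible(x)
}

#' Extract estimates from a growth model fit
#'
#' @param object a `growth_sem` fit.
#' @param what `"alpha"` (factor means, default), `"psi"`, `"theta"`, or
#'   `"all"` (named vector of every free parameter on the natural scale).
#' @param ... unused.
#' @return numeric vector or matrix.
#' @export
coef.growth_sem <- function(object, what = c("alpha", "psi", "theta", "all"),
                            ...) {
  what <- match.arg(what)
  switch(what,
    alpha = object$alpha,
    psi = object$psi,
    theta = object$theta,
    all = {
      psi <- object$psi_full
      nm <- outer(rownames(psi), colnames(psi),
                  function(a, b) paste0("psi[", a, ",", b, "]"))
      lt <- lower.tri(psi, diag = TRUE)
      c(
        stats::setNames(object$alpha_full,
                        paste0("alpha[", names(object$alpha_full), "]")),
        stats::setNames(psi[lt], nm[lt]),
        if (length(object$theta))
          stats::setNames(object$theta, paste0("theta[", names(object$theta),
                                               "]"))
      )
    }
  )
}

#' @export
logLik.growth_sem <- function(object, ...) {
  structure(object$logLik,
            df = object$spec$npar,
            nobs = object$n,
            class = "logLik")
}

#' Per-individual factor scores from a fitted growth model
#'
#' The default `"regression"` (empirical Bayes) method scores
#' `eta_i = alpha + Psi Lambda' Sigma^-1 (y_i - mu)`; `"bartlett"` scores are
#' the generalized-least-squares estimates
#' `(Lambda' Theta^-1 Lambda)^-1 Lambda' Theta^-1 y_i`, defined only when the
#' residual variances are free (positive). In the just-identified two-wave
#' change score model the regression scores reduce exactly to
#' `(y1, y2 - y1)`. With missing data, each individual is scored from their
#' observed waves. For covariate models, regression scores condition on W as
#' well; Bartlett scores use the repeated measures only.
#'
#' @param fit a [growth_sem()] fit.
#' @param method `"regression"` or `"bartlett"`.
#' @return an `n x q` matrix of class `factor_scores` with a `method`
#'   attribute; rows align with the input panel.
#' @export
factor_scores <- function(fit, method = c("regression", "bartlett")) {
  stopifnot(inherits(fit, "growth_sem"))
  method <- match.arg(method)
  if (!fit$convergence$converged) {
    warning("scoring a fit that did not meet the convergence criterion")
  }
  spec <- fit$spec
  q <- spec$q
  x <- fit$data

  if (method == "bartlett") {
    if (spec$residuals == "zero" || any(fit$theta <= 0)) {
      stop("Bartlett scores are undefined when residual variances are ",
           "fixed to zero")
    }
    lam <- spec$lambda
    th_inv <- 1 / fit$theta
    wmat <- solve(crossprod(lam, lam * th_inv)) %*% t(lam * th_inv)
    y <- x[, seq_len(spec$waves), drop = FALSE]
    if (anyNA(y)) {
      scores <- t(apply(y, 1, function(yi) {
        o <- which(!is.na(yi))
        if (length(o) < q) return(rep(NA_real_, q))
        lo <- lam[o, , drop = FALSE]
        drop(solve(crossprod(lo, lo * th_inv[o]),
                   crossprod(lo * th_inv[o], yi[o])))
      }))
    } else {
      scores <- y %*% t(wmat)
    }
  } else {
    mu <- fit$implied_mean
    sigma <- fit$implied_cov
    a <- fit$psi_full %*% t(spec$lam_aug)
    if (anyNA(x)) {
      scores <- t(apply(x, 1, function(xi) {
        o <- which(!is.na(xi))
        if (length(o) == 0) return(rep(NA_real_, spec$m))
        drop(a[, o, drop = FALSE] %*%
               solve(sigma[o, o, drop = FALSE], xi[o] - mu[o]))
      }))
      scores <- sweep(scores, 2, fit$alpha_full, `+`)
    } else {
      xc <- sweep(x, 2, mu)
      scores <- sweep(xc %*% solve(sigma, t(a)), 2, fit$alpha_full, `+`)
    }
    scores <- scores[, seq_len(q), drop = FALSE]
  }
  colnames(scores) <- spec$fnames
  structure(scores, method = method, class = c("factor_scores", "matrix",
                                               "array"))
}

#' Predict method: factor scores or fitted trajectories
#'
#' @param object a `growth_sem` fit.
#' @param newdata optional panel matrix (same wave layout) to score; defaults
#'   to the fitting data.
#' @param type `"scores"` (factor scores) or `"trajectory"` (model-implied
#'   `Lambda %*% scores'`, the smoothed repeated measures).
#' @param method factor-score method, see [factor_scores()].
#' @param ... unused.
#' @return a matrix.
#' @export
predict.growth_sem <- function(object, newdata = NULL,
                               type = c("scores", "trajectory"),
                               method = c("regression", "bartlett"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata)) {
    object$data <- prepare_newdata(object, newdata)
  }
  sc <- factor_scores(object, method = match.arg(method))
  if (type == "scores") return(sc)
  fitted_y <- sc %*% t(object$spec$lambda)
  colnames(fitted_y) <- paste0("y", seq_len(object$waves))
  fitted_y
}

prepare_newdata <- function(object, newdata) {
  if (inherits(newdata, "cohort_sample")) newdata <- newdata$observed
  newdata <- as.matrix(newdata)
  if (ncol(newdata) < object$waves) {
    stop("`newdata` must provide at least ", object$waves, " waves")
  }
  nd <- newdata[, seq_len(object$waves), drop = FALSE]
  if (object$spec$has_w) {
    stop("supply covariate models with the original fitting data; ",
         "`newdata` scoring supports unconditional models")
  }
  nd
}

#' @export
fitted.growth_sem <- function(object, ...) {
  predict(object, type = "trajectory")
}

#' @export
residuals.growth_sem <- function(object, ...) {
  y <- object$data[, seq_len(object$waves), drop = FALSE]
  y - fitted(object)
}

#' Plot observed spaghetti and the model-implied mean trajectory
#'
#' @param x a `growth_sem` fit.
#' @param max_lines number of individual trajectories to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.growth_sem <- function(x, max_lines = 50, ...) {
  y <- x$data[, seq_len(x$waves), drop = FALSE]
  tt <- x$spec$time_codes
  idx <- seq_len(min(max_lines, nrow(y)))
  graphics::matplot(tt, t(y[idx, , drop = FALSE]), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.35),
                    xlab = "time", ylab = "observed score", ...)
  graphics::lines(tt, x$implied_mean[seq_len(x$waves)], lwd = 3,
                  col = "firebrick")
  invisible(x)
}

#' Simulate panels from the fitted (implied) distribution
#'
#' @param object a `growth_sem` fit.
#' @param nsim number of panels.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `n x p` matrices drawn from
#'   `N(mu(theta_hat), Sigma(theta_hat))`.
#' @export
simulate.growth_sem <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$implied_mean
  r <- chol(object$implied_cov)
  p <- length(mu)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    z <- matrix(stats::rnorm(object$n * p), object$n, p)
    sweep(z %*% r, 2, mu, `+`)
  }))
}

#' Serialize a fit summary to JSON
#'
#' @param fit a `growth_sem` fit.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(
    kind = fit$kind, degree = fit$degree, waves = fit$waves, n = fit$n,
    residual_structure = fit$spec$residuals,
    alpha = as.list(fit$alpha),
    psi = unname(apply(fit$psi, 1, as.list)),
    theta = as.list(fit$theta),
    w_block = fit$w_block,
    discrepancy = fit$discrepancy,
    logLik = fit$logLik,
    fiml = fit$fiml,
    convergence = fit$convergence
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Write factor scores to CSV keyed by replicant id
#'
#' @param scores a [factor_scores()] matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  d <- data.frame(id = seq_len(nrow(scores)), unclass(scores)[, , drop = FALSE])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
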