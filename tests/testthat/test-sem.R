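test_that("implied moments follow the growth-model structure", {
  pop <- lin_pop()
  s <- sample_cohort(pop, 50, seed = 1)
  fit <- growth_sem(s, waves = 3)
  spec <- fit$spec
  ## linear LCM, alpha = (3, 0.2), Theta = 0: mean is Lambda alpha
  mom <- implied_moments(spec, c(3, 0.2), pop$psi)
  expect_equal(mom$mean, c(3, 3.2, 3.4))
  expect_equal(mom$cov, loading_matrix(0:2, 1) %*% pop$psi %*%
                 t(loading_matrix(0:2, 1)))

  ## path-tracing the change score diagram: mu = (mu1, mu1 + alpha_change)
  fit2 <- growth_sem(s, waves = 2)
  mom2 <- implied_moments(fit2$spec, c(3, 0.2),
                          matrix(c(1, .15, .15, .25), 2))
  expect_equal(mom2$mean, c(3, 3.2))

  ## no latent structure: Sigma = Theta
  mom3 <- implied_moments(spec, c(0, 0), matrix(0, 2, 2), theta = rep(1, 3))
  expect_equal(mom3$cov, diag(3))
  expect_error(implied_moments(spec, c(0, 0, 0), diag(3)), "dimensions")
})

test_that("the ML discrepancy is zero at a saturated match and else positive", {
  s <- cov_pd <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  ybar <- c(1, 2)
  expect_equal(fml_discrepancy(ybar, s, ybar, s), 0)
  ## scalar evaluation: p = 1, S = 2, Sigma = 1 -> F = 1 - ln 2
  expect_equal(fml_discrepancy(0, matrix(1), 0, matrix(2)), 1 - log(2))
  ## F >= 0 whenever the mean is matched
  for (i in 1:20) {
    set.seed(i)
    a <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    b <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    m <- rnorm(3)
    expect_gte(fml_discrepancy(m, a, m, b), -1e-12)
  }
  expect_error(fml_discrepancy(0, matrix(1), 0, matrix(0)), "singular")
})

test_that("two-wave LCS reproduces the observed moments exactly", {
  s <- sample_cohort(lin_pop(), 200, seed = 13)
  fit <- growth_sem(s, waves = 2)
  d <- s$observed[, 2] - s$observed[, 1]
  expect_lt(abs(coef(fit)["change"] - mean(d)), 1e-6)
  ## ML (divisor n) variance of the differences
  expect_equal(unname(fit$psi["change", "change"]),
               mean((d - mean(d))^2), tolerance = 1e-6)
  expect_lt(fit$discrepancy, 1e-10)
  expect_true(fit$convergence$converged)
})

test_that("noise-free just-identified fits recover parameters exactly", {
  pop <- lin_pop()
  eta <- rmvn_exact(120, pop$alpha, pop$psi, seed = 17)
  y <- eta %*% t(loading_matrix(0:1, 1)) # two noise-free waves
  fit <- growth_sem(y, waves = 2, kind = "lcm", residuals = "zero")
  expect_lt(fit$discrepancy, 1e-10)
  expect_equal(unname(coef(fit)), pop$alpha, tolerance = 1e-8)
  ## change-score variance psi_dd = var(slope) in the LCS parameterization
  lcs <- growth_sem(y, waves = 2)
  expect_equal(unname(lcs$psi["change", "change"]),
               mean((eta[, 2] - mean(eta[, 2]))^2), tolerance = 1e-8)
})

test_that("saturated recovery: exactly model-implied moments fit perfectly", {
  ## build a 5-wave panel whose sample moments equal the implied moments
  ## exactly: draw (eta, eps) jointly with exact moments and a block-diagonal
  ## covariance, so S = Lambda Psi Lambda' + Theta and ybar = Lambda alpha
  psi <- matrix(c(1, .15, .15, .25), 2)
  theta <- c(1, 1.55, 2.6, 4.15, 6.2)
  lam <- loading_matrix(0:4, 1)
  ## scale by n/(n-1): the ML fit reproduces the divisor-n sample moments
  joint <- rmvn_exact(200, c(3, 0.2, rep(0, 5)),
                      rbind(cbind(psi, matrix(0, 2, 5)),
                            cbind(matrix(0, 5, 2), diag(theta))) * 200 / 199,
                      seed = 19)
  y <- joint[, 1:2] %*% t(lam) + joint[, 3:7]
  fit <- growth_sem(y, waves = 5, residuals = "free",
                    control = list(grad_tol = 1e-9))
  expect_lt(fit$discrepancy, 1e-10)
  expect_lt(max(abs(coef(fit) - c(3, 0.2))), 1e-4)
  expect_lt(max(abs(fit$psi - psi)), 1e-4)
  expect_lt(max(abs(fit$theta - theta)), 1e-4)
})

test_that("fits recover the generating values at large N with noise", {
  s <- sample_cohort(lin_pop(), 5000, seed = 23)
  fit <- growth_sem(s, waves = 5)
  expect_lt(max(abs(coef(fit) - c(3, 0.2))), 0.05)
  expect_lt(max(abs(fit$psi - matrix(c(1, .15, .15, .25), 2))), 0.06)
  expect_lt(max(abs(fit$theta - c(1, 1.55, 2.6, 4.15, 6.2))), 0.25)
})

test_that("scale equivariance: y -> c y maps alpha -> c alpha, psi -> c^2 psi", {
  s <- sample_cohort(lin_pop(), 150, seed = 29)
  f1 <- growth_sem(s$observed, waves = 4)
  f2 <- growth_sem(3 * s$observed, waves = 4)
  expect_equal(unname(coef(f2)), unname(3 * coef(f1)), tolerance = 1e-5)
  expect_equal(f2$psi, 9 * f1$psi, tolerance = 1e-5)
  expect_equal(f2$theta, 9 * f1$theta, tolerance = 1e-5)
  ## and the recovery correlations are unchanged
  r1 <- pearson_recovery(factor_scores(f1)[, 2], s$true_factors[, 2])
  r2 <- pearson_recovery(factor_scores(f2)[, 2], 3 * s$true_factors[, 2])
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("identification rules are enforced", {
  s <- sample_cohort(quad_pop(), 100, seed = 3)
  expect_error(growth_sem(s, waves = 3, kind = "lcm", degree = 2),
               "at least 4 waves")
  expect_error(growth_sem(s, waves = 3, kind = "lcs"), "exactly 2 waves")
  expect_error(growth_sem(s, waves = 2, kind = "lcs", residuals = "free"),
               "fixed to zero")
  expect_error(growth_sem(s, waves = 4, kind = "lcm", degree = 2,
                          residuals = "zero"),
               "just-identified")
  ## noise-free data with more waves than factors: singular sample covariance
  pop <- lin_pop()
  eta <- rmvn_exact(100, pop$alpha, pop$psi, seed = 31)
  y <- eta %*% t(loading_matrix(0:4, 1))
  expect_error(growth_sem(y, waves = 5), "singular")
})

test_that("analytic gradient matches central finite differences", {
  for (cfg in list(list(waves = 3, degree = 1, res = "free"),
                   list(waves = 5, degree = 2, res = "free"),
                   list(waves = 4, degree = 1, res = "equal"))) {
    pop <- if (cfg$degree == 2) quad_pop() else lin_pop()
    s <- sample_cohort(pop, 80, seed = 7 + cfg$waves)
    fit <- growth_sem(s, waves = cfg$waves, kind = "lcm",
                      degree = cfg$degree, residuals = cfg$res)
    spec <- fit$spec
    data <- growthrecovery:::prepare_complete(
      s$observed[, seq_len(cfg$waves)], spec)
    par <- fit$par + 0.07 # off the optimum, where the gradient is nonzero
    got <- growthrecovery:::objective_grad(spec, data, par)
    num <- vapply(seq_along(par), function(i) {
      h <- 1e-6
      up <- dn <- par
      up[i] <- up[i] + h
      dn[i] <- dn[i] - h
      (growthrecovery:::objective_grad(spec, data, up)$value -
         growthrecovery:::objective_grad(spec, data, dn)$value) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(got$grad - num)), 1e-6)
  }
})

test_that("FIML on complete data agrees with the moment-based fit", {
  s <- sample_cohort(lin_pop(), 250, seed = 37)
  fc <- growth_sem(s, waves = 4)
  expect_false(fc$fiml)
  ## mask 12% MCAR and check estimates stay near the complete-data fit
  sm <- impose_missingness(s, "mcar", 0.12, seed = 41)
  ## rows that lose every wave are dropped with a warning
  ff <- suppressWarnings(growth_sem(sm, waves = 4))
  expect_true(ff$fiml)
  expect_true(ff$convergence$converged)
  expect_lt(max(abs(coef(ff) - coef(fc))), 0.1)
  expect_lt(max(abs(ff$psi - fc$psi)), 0.2)
})

test_that("FIML reduces to the complete-data optimum when nothing is missing", {
  s <- sample_cohort(lin_pop(), 150, seed = 43)
  fc <- growth_sem(s, waves = 3)
  data_f <- growthrecovery:::prepare_fiml(s$observed[, 1:3])
  gg <- growthrecovery:::objective_grad(fc$spec, data_f, fc$par)
  ## at the complete-data optimum, the FIML gradient also vanishes
  expect_lt(max(abs(gg$grad)), 1e-5)
})

test_that("simulate() draws from the implied moments", {
  s <- sample_cohort(lin_pop(), 3000, seed = 47)
  fit <- growth_sem(s, waves = 3)
  sim <- simulate(fit, nsim = 1, seed = 5)[[1]]
  expect_equal(dim(sim), c(3000L, 3L))
  expect_lt(max(abs(colMeans(sim) - fit$implied_mean)), 0.12)
  expect_lt(max(abs(cov(sim) - fit$implied_cov)), 0.35)
})
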