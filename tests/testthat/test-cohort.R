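test_that("cohort samples carry exact latent moments and the 50% noise rule", {
  pop <- lin_pop()
  s <- sample_cohort(pop, 200, seed = 1)
  expect_lt(max(abs(colMeans(s$true_factors) - pop$alpha)), 1e-8)
  expect_lt(max(abs(cov(s$true_factors) - pop$psi)), 1e-8)
  ## noise variance equals true-score variance at R^2 = 0.50
  expect_equal(s$noise_variances, c(1, 1.55, 2.6, 4.15, 6.2))
  ## observed = Lambda eta' + noise, columnwise
  lam <- loading_matrix(pop$time_codes, 1)
  noise <- s$observed - s$true_factors %*% t(lam)
  expect_equal(dim(noise), c(200L, 5L))

  q <- quad_pop()
  sq <- sample_cohort(q, 200, seed = 2)
  expect_lt(max(abs(cov(sq$true_factors) - q$psi)), 1e-8)
  expect_lt(max(abs(colMeans(sq$true_factors) - q$alpha)), 1e-8)
})

test_that("identical (population, n, seed) inputs give identical samples", {
  a <- sample_cohort(lin_pop(), 60, seed = 5)
  b <- sample_cohort(lin_pop(), 60, seed = 5)
  expect_identical(a$observed, b$observed)
  expect_identical(a$true_factors, b$true_factors)
})

test_that("empirical per-wave R^2 matches the target at large N", {
  pop <- lin_pop()
  lam <- loading_matrix(pop$time_codes, 1)
  r2 <- rowMeans(vapply(1:4, function(i) {
    s <- sample_cohort(pop, 2000, seed = 20 + i)
    true_scores <- s$true_factors %*% t(lam)
    vapply(1:5, function(t) cor(s$observed[, t], true_scores[, t])^2,
           numeric(1))
  }, numeric(5)))
  expect_true(all(abs(r2 - 0.5) < 0.02))
})

test_that("noise columns are uncorrelated with the factors on average", {
  pop <- lin_pop()
  lam <- loading_matrix(pop$time_codes, 1)
  cors <- vapply(1:300, function(i) {
    s <- sample_cohort(pop, 200, seed = 7000 + i)
    noise <- s$observed - s$true_factors %*% t(lam)
    mean(cor(noise, s$true_factors))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.005)
})

test_that("r2 -> 1 gives noise-free observations; r2 variations rescale noise", {
  pop <- lin_pop()
  eta <- rmvn_exact(50, pop$alpha, pop$psi, seed = 4)
  out <- add_noise(eta, pop, seed = 9, r2 = 1)
  lam <- loading_matrix(pop$time_codes, 1)
  expect_equal(out$observed, eta %*% t(lam), ignore_attr = TRUE)
  expect_equal(out$noise_variances, rep(0, 5))
  low <- add_noise(eta, pop, seed = 9, r2 = 0.2)
  expect_equal(low$noise_variances, c(1, 1.55, 2.6, 4.15, 6.2) * 4)
  const <- add_noise(eta, pop, seed = 9, noise_rule = "constant_wave1")
  expect_equal(const$noise_variances, rep(1, 5))
})

test_that("difference-score correlation matches its closed form at N=2000", {
  ## population correlation between (y2 - y1) and the true slope:
  ## psi22 / sqrt(psi22 (psi22 + s0^2 + s1^2)) with noise variances 1, 1.55
  psi22 <- 0.25
  rho <- psi22 / sqrt(psi22 * (psi22 + 1 + 1.55))
  pop <- lin_pop()
  rs <- vapply(1:3, function(i) {
    s <- sample_cohort(pop, 2000, seed = 100 + i)
    cor(s$observed[, 2] - s$observed[, 1], s$true_factors[, 2])
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.02)
})

test_that("covariate W carries exact sample correlations with the factors", {
  pop <- lin_pop(covariate = list(r_intercept = 0.2, r_slope = -0.1))
  s <- sample_cohort(pop, 200, seed = 31)
  expect_equal(cor(s$w, s$true_factors[, 1]), 0.2, tolerance = 1e-10)
  expect_equal(cor(s$w, s$true_factors[, 2]), -0.1, tolerance = 1e-10)
  expect_equal(mean(s$w), 0, tolerance = 1e-10)
  expect_equal(var(s$w), 1, tolerance = 1e-10)

  ## standalone construction on existing factors
  eta <- rmvn_exact(100, pop$alpha, pop$psi, seed = 8)
  w0 <- sample_covariate(eta, list(r_intercept = 0, r_slope = 0), pop$psi,
                         seed = 2)
  expect_lt(abs(cor(w0, eta[, 1])), 1e-10)
  expect_lt(abs(cor(w0, eta[, 2])), 1e-10)
})

test_that("incompatible covariate correlations are rejected", {
  psi_std3 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_error(
    sample_covariate(rmvn_exact(50, c(0, 0), psi_std3, seed = 1),
                     list(r_intercept = 0.99, r_slope = 0.99), psi_std3),
    "eigenvalue"
  )
})

test_that("missingness mechanisms behave as specified", {
  s <- sample_cohort(lin_pop(), 2000, seed = 41)
  none <- impose_missingness(s, "none")
  expect_false(any(none$mask))
  expect_identical(none$observed, s$observed)

  mcar <- impose_missingness(s, "mcar", rate = 0.2, seed = 5)
  expect_lt(abs(mean(mcar$mask) - 0.2), 0.02)
  expect_true(all(is.na(mcar$observed[mcar$mask])))

  att_pop <- growth_population("linear", c(3, 0.2),
                               matrix(c(1, .15, .15, .25), 2), n_waves = 3)
  att <- impose_missingness(sample_cohort(att_pop, 4000, seed = 6),
                            "attrition", rate = 0.5, seed = 7)
  ## monotone: once missing, missing at all later waves
  expect_true(all(!att$mask[, 2] | att$mask[, 3]))
  ## expected fully-observed fraction (1 - rate)^(T-1) = 0.25
  expect_lt(abs(mean(rowSums(att$mask) == 0) - 0.25), 0.025)
  expect_error(impose_missingness(s, "mcar", rate = 1), "rate")
})

test_that("cohort exports to wide and long data frames", {
  pop <- lin_pop(covariate = list(r_intercept = 0.2, r_slope = -0.1))
  s <- sample_cohort(pop, 10, seed = 3)
  wide <- as.data.frame(s, format = "wide")
  expect_equal(names(wide), c("id", paste0("y", 1:5), "w"))
  expect_equal(nrow(wide), 10)
  long <- as.data.frame(s, format = "long")
  expect_equal(nrow(long), 50)
  expect_equal(long$y[long$id == 3], unname(s$observed[3, ]))
  expect_equal(unique(long$time), 0:4)
  f <- tempfile(fileext = ".csv")
  write_cohort(s, f, format = "long")
  expect_equal(nrow(utils::read.csv(f)), 50)
})
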