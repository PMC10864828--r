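test_that("built-in conditions encode the four study designs", {
  conds <- study_conditions()
  expect_setequal(names(conds),
                  c("linear_n200", "linear_n2000", "quadratic_n200",
                    "covariate_n200"))
  expect_equal(conds$linear_n200$population$alpha, c(3, 0.2))
  expect_equal(conds$linear_n200$n_replicants, 200)
  expect_equal(conds$linear_n200$n_replications, 1000)
  expect_equal(conds$linear_n200$population$r2_per_wave, 0.5)
  ## large-cohort condition differs only in N
  expect_equal(conds$linear_n2000$n_replicants, 2000)
  expect_equal(conds$linear_n2000$population, conds$linear_n200$population)
  expect_equal(conds$linear_n2000$waves, conds$linear_n200$waves)
  ## quadratic ladder misspecifies 2-3 waves as difference/linear models
  expect_equal(conds$quadratic_n200$waves, 2:6)
  cond <- conds$quadratic_n200
  expect_equal(growthrecovery:::ladder_degree(cond, 3), 1L)
  expect_equal(growthrecovery:::ladder_degree(cond, 4), 2L)
  expect_true(conds$covariate_n200$include_covariate)
  expect_equal(conds$covariate_n200$population$covariate$r_slope, -0.1)
})

test_that("run_study bookkeeping: rows, determinism, regenerable seeds", {
  st <- run_study("linear_n200", n_replications = 10, seed = 77)
  expect_equal(nrow(st$records), 40) # 10 replications x 4 ladder entries
  st2 <- run_study("linear_n200", n_replications = 10, seed = 77)
  expect_identical(st$records, st2$records)
  ## a replication regenerates in isolation from its recorded child seed
  row <- st$records[st$records$replication == 7 &
                      st$records$model == "lcm_3w", ]
  s <- sample_cohort(linear_population(), 200, seed = row$seed)
  fit <- growth_sem(s, waves = 3)
  expect_equal(unname(coef(fit)[2]), row$fixed_linear, tolerance = 1e-10)
})

test_that("median recovery improves with waves; fixed effects are unbiased", {
  st <- linear_study_200()
  tab <- figure_tables(st)$r_linear
  expect_equal(tab$waves, 2:5)
  ## non-decreasing within a small tolerance band at 200 replications
  expect_true(all(diff(tab$median) > -0.02))
  ## and the 2-wave model is clearly the worst
  expect_lt(tab$median[1] + 0.1, tab$median[4])

  fx <- figure_tables(st)$fixed_linear
  expect_true(all(abs(fx$median - 0.2) < 0.02))
  ## sample-to-sample variance of the fixed effect shrinks with waves
  expect_true(all(diff(fx$sd) < 0))
  ## agreement ICC never exceeds the Pearson recovery per model
  icc <- figure_tables(st)$icc_linear
  expect_true(all(icc$median <= tab$median + 0.2))
  expect_lt(icc$median[1], tab$median[1]) # 2-wave ICC drops below its r
})

test_that("sample size leaves medians unchanged but shrinks their spread", {
  small <- linear_study_small_n200()
  big <- linear_study_small_n2000()
  ts <- figure_tables(small)$r_linear
  tb <- figure_tables(big)$r_linear
  ## change-score recovery is N-invariant almost exactly; LCM entries shift
  ## slightly (~0.04) because noisier score weights at N = 200 attenuate
  ## per-sample recovery
  expect_lt(abs(tb$median[1] - ts$median[1]), 0.03)
  expect_true(all(abs(tb$median - ts$median) <= 0.06))
  iqr_s <- ts$q75 - ts$q25
  iqr_b <- tb$q75 - tb$q25
  expect_true(all(iqr_b < iqr_s))
})

test_that("quadratic condition scores curvature only where estimable", {
  sq <- run_study("quadratic_n200", n_replications = 8, seed = 88)
  rec <- sq$records
  expect_true(all(is.na(rec$r_curvature[rec$waves <= 3])))
  expect_true(all(!is.na(rec$r_curvature[rec$waves >= 4 & rec$converged])))
  ## every model is scored on the instantaneous linear slope
  expect_true(all(!is.na(rec$r_linear)))
  expect_true(all(rec$degree[rec$waves <= 3] == 1))
})

test_that("study results export and summarize", {
  st <- run_study("linear_n200", n_replications = 5, seed = 91, waves = c(2, 3))
  dir <- tempfile()
  write_study(st, dir, format = "json")
  expect_true(file.exists(file.path(dir, "records.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$master_seed, 91)
  expect_equal(prov$n_replications, 5)
  tabs <- figure_tables(st)
  expect_null(tabs$r_curvature)
  expect_s3_class(tabs$r_linear, "data.frame")
  expect_output(print(st), "Recovery study")
})

test_that("missing-data overlay runs end to end with FIML fits", {
  ## the rare all-missing row raises a warning from the FIML preparation
  st <- suppressWarnings(
    run_study("linear_n200", n_replications = 5, seed = 93,
              waves = c(3, 4), missing_mechanism = "mcar",
              missing_rate = 0.1)
  )
  expect_equal(sum(st$records$converged), nrow(st$records))
  expect_true(all(st$records$r_linear > 0.2))
})
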