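#' Built-in simulation study conditions
#'
#' Four Monte-Carlo conditions, each defaulting to 1000 replications with 50%
#' explained variance per wave:
#'
#' * `linear_n200` — linear population ([linear_population()]), N = 200,
#'   model ladder: 2-wave LCS, then linear LCMs on 3-5 waves.
#' * `linear_n2000` — identical except N = 2000 (large-cohort condition).
#' * `quadratic_n200` — quadratic population ([quadratic_population()]),
#'   N = 200, waves 2-6; the 2- and 3-wave models are deliberately
#'   misspecified as difference/linear models (too few waves to support the
#'   curvature factor), and quadratic LCMs are fit on 4-6 waves.
#' * `covariate_n200` — the linear condition with an external variable W
#'   correlated 0.2 with the intercept and -0.1 with the slope, estimated
#'   simultaneously with each growth model.
#'
#' @return a named list of `study_condition` objects.
#' @export
study_conditions <- function() {
  list(
    linear_n200 = study_condition(
      name = "linear_n200",
      population = linear_population(),
      n_replicants = 200,
      waves = 2:5
    ),
    linear_n2000 = study_condition(
      name = "linear_n2000",
      population = linear_population(),
      n_replicants = 2000,
      waves = 2:5
    ),
    quadratic_n200 = study_condition(
      name = "quadratic_n200",
      population = quadratic_population(),
      n_replicants = 200,
      waves = 2:6
    ),
    covariate_n200 = study_condition(
      name = "covariate_n200",
      population = linear_population(
        covariate = list(r_intercept = 0.2, r_slope = -0.1)
      ),
      n_replicants = 200,
      waves = 2:5,
      include_covariate = TRUE
    )
  )
}

#' Construct a study condition
#'
#' @param name condition label.
#' @param population the generating [growth_population()].
#' @param n_replicants individuals per sample.
#' @param waves integer vector: the model ladder. Each entry `T` fits on the
#'   first `T` waves — an LCS when `T == 2`, otherwise an LCM whose degree is
#'   the population's degree when `T >= degree + 2`, and 1 otherwise (the
#'   deliberately misspecified entries of a quadratic ladder).
#' @param n_replications Monte-Carlo replications (default 1000).
#' @param include_covariate estimate the W block in every ladder model.
#' @param master_seed default seed used when [run_study()] is not given one.
#' @return a `study_condition`.
#' @export
study_condition <- function(name, population, n_replicants, waves,
                            n_replications = 1000,
                            include_covariate = FALSE,
                            master_seed = 1L) {
  stopifnot(inherits(population, "growth_population"))
  waves <- sort(unique(as.integer(waves)))
  if (max(waves) > length(population$time_codes)) {
    stop("ladder requests more waves than the population defines")
  }
  if (min(waves) < 2) stop("ladder entries must use at least 2 waves")
  if (include_covariate && is.null(population$covariate)) {
    stop("`include_covariate` requires a population with a covariate spec")
  }
  structure(
    list(name = name, population = population,
         n_replicants = n_replicants, waves = waves,
         n_replications = n_replications,
         include_covariate = include_covariate,
         master_seed = master_seed),
    class = "study_condition"
  )
}

#' @export
print.study_condition <- function(x, ...) {
  cat(sprintf(
    "Study condition '%s': %s population, N = %d, %d replications\n",
    x$name, x$population$form, x$n_replicants, x$n_replications
  ))
  cat("Model ladder (waves):", paste(x$waves, collapse = ", "),
      if (x$include_covariate) "| covariate W estimated", "\n")
  invisible(x)
}

ladder_degree <- function(condition, waves_used) {
  deg <- condition$population$degree
  if (waves_used >= deg + 2) deg else 1L
}

#' Run a Monte-Carlo recovery study
#'
#' For each replication: one cohort sample is generated from the condition's
#' population (exact latent moments, stochastic per-wave noise, child seed
#' derived from the master seed so any replication is regenerable in
#' isolation); every ladder model is fit to the *same* sample using its first
#' `T` waves; factor scores are computed; and recovery of the growth
#' parameters of interest is recorded against the true generating values.
#'
#' For linear populations the factor of interest is the slope (the change
#' factor in the 2-wave model). For quadratic populations all models are
#' scored against the true instantaneous linear slope (the time-0 tangent),
#' and the curvature factor is additionally scored for ladder entries with
#' enough waves to estimate it.
#'
#' @param condition a [study_condition()] (or the name of a built-in one).
#' @param n_replications,n_replicants,seed,r2,waves optional overrides of the
#'   condition's settings.
#' @param noise_rule noise-scaling dialect, see [sample_cohort()].
#' @param missing_mechanism,missing_rate optional missing-data overlay
#'   applied to every sample before fitting (see [impose_missingness()]);
#'   fits then use full-information ML.
#' @param scores factor-score method (default `"regression"`).
#' @param residuals residual structure for the LCM fits (default `"free"`).
#' @param verbose print a progress line every 100 replications.
#' @return a `growth_study` object: `records` (one row per replication x
#'   ladder entry), `summary` (via [recovery_summary()]), and a `provenance`
#'   block (seeds, condition, convergence counts).
#' @export
run_study <- function(condition,
                      n_replications = NULL,
                      n_replicants = NULL,
                      seed = NULL,
                      r2 = NULL,
                      waves = NULL,
                      noise_rule = c("per_wave", "constant_wave1"),
                      missing_mechanism = c("none", "mcar", "attrition"),
                      missing_rate = 0,
                      scores = c("regression", "bartlett"),
                      residuals = c("free", "equal"),
                      verbose = FALSE) {
  if (is.character(condition)) {
    conds <- study_conditions()
    if (!condition %in% names(conds)) {
      stop("unknown condition '", condition, "'; see study_conditions()")
    }
    condition <- conds[[condition]]
  }
  stopifnot(inherits(condition, "study_condition"))
  noise_rule <- match.arg(noise_rule)
  missing_mechanism <- match.arg(missing_mechanism)
  scores <- match.arg(scores)
  residuals <- match.arg(residuals)

  pop <- condition$population
  if (!is.null(r2)) {
    pop <- growth_population(pop$form, pop$alpha, pop$psi, pop$time_codes,
                             r2_per_wave = r2, covariate = pop$covariate)
  }
  reps <- n_replications %||% condition$n_replications
  n <- n_replicants %||% condition$n_replicants
  master <- as.integer(seed %||% condition$master_seed)
  ladder <- waves %||% condition$waves

  rows <- vector("list", reps * length(ladder))
  failures <- list()
  k <- 0L
  for (j in seq_len(reps)) {
    rep_seed <- child_seed(master, j)
    smp <- sample_cohort(pop, n, seed = rep_seed, noise_rule = noise_rule)
    if (missing_mechanism != "none") {
      smp <- impose_missingness(smp, missing_mechanism, missing_rate,
                                seed = child_seed(rep_seed, 2L))
    }
    for (tt in ladder) {
      k <- k + 1L
      deg <- ladder_degree(condition, tt)
      row <- tryCatch(
        fit_one_entry(smp, condition, tt, deg, scores, residuals, j,
                      rep_seed),
        error = function(e) {
          structure(list(message = conditionMessage(e)), class = "fit_error")
        }
      )
      if (inherits(row, "fit_error")) {
        failures[[length(failures) + 1L]] <-
          list(replication = j, waves = tt, seed = rep_seed,
               message = row$message)
        next
      }
      rows[[k]] <- row
    }
    if (verbose && j %% 100 == 0) {
      message("replication ", j, "/", reps)
    }
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(failures)) {
    warning(length(failures), " model fits failed and were excluded; ",
            "see provenance$failures for replication indices and seeds")
  }
  summary_tab <- recovery_summary(records)
  structure(
    list(
      records = records,
      summary = summary_tab,
      provenance = list(
        condition = condition$name,
        master_seed = master,
        n_replications = reps,
        n_replicants = n,
        ladder = ladder,
        r2 = pop$r2_per_wave,
        noise_rule = noise_rule,
        missing = list(mechanism = missing_mechanism, rate = missing_rate),
        scores = scores,
        residuals = residuals,
        failures = failures,
        convergence_counts = table(records$model, records$converged),
        package_version = as.character(utils::packageVersion("growthrecovery"))
      )
    ),
    class = "growth_study"
  )
}

fit_one_entry <- function(smp, condition, tt, deg, scores, residuals, j,
                          rep_seed) {
  kind <- if (tt == 2) "lcs" else "lcm"
  fit <- growth_sem(
    smp, waves = tt, kind = kind, degree = deg,
    residuals = if (kind == "lcs") "zero" else residuals,
    include_covariate = condition$include_covariate
  )
  ## non-converged fits are still scored so the full record row exists, but
  ## they are excluded from every aggregate (converged flag below)
  sc <- withCallingHandlers(
    factor_scores(fit, method = scores),
    warning = function(w) invokeRestart("muffleWarning")
  )
  true <- smp$true_factors
  quadratic <- condition$population$degree == 2L

  ## the slope/change factor is always column 2 of the fitted scores
  est_lin <- sc[, 2]
  true_lin <- true[, 2]
  row <- data.frame(
    condition = condition$name,
    replication = j,
    model = model_label(kind, tt),
    waves = tt,
    kind = kind,
    degree = deg,
    seed = rep_seed,
    fixed_linear = unname(coef(fit)[2]),
    r_linear = pearson_recovery(est_lin, true_lin),
    icc_linear = icc2_agreement(est_lin, true_lin),
    fixed_curvature = NA_real_,
    r_curvature = NA_real_,
    icc_curvature = NA_real_,
    converged = fit$convergence$converged,
    stringsAsFactors = FALSE
  )
  if (quadratic && deg == 2L) {
    row$fixed_curvature <- unname(coef(fit)[3])
    row$r_curvature <- pearson_recovery(sc[, 3], true[, 3])
    row$icc_curvature <- icc2_agreement(sc[, 3], true[, 3])
  }
  if (condition$include_covariate) {
    row$wcor_intercept <- unname(fit$w_block$cor[1])
    row$wcor_slope <- unname(fit$w_block$cor[2])
  }
  row
}

model_label <- function(kind, waves) {
  if (kind == "lcs") sprintf("lcs_%dw", waves) else sprintf("lcm_%dw", waves)
}

#' @export
print.growth_study <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "Recovery study '%s': %d replications x N = %d (seed %d)\n",
    p$condition, p$n_replications, p$n_replicants, p$master_seed
  ))
  cols <- intersect(
    c("model", "n_converged", "median_fixed_linear", "sd_fixed_linear",
      "median_r_linear", "median_icc_linear", "median_r_curvature"),
    names(x$summary)
  )
  print(x$summary[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.growth_study <- function(object, ...) object$summary

#' Per-figure summary tables of a recovery study
#'
#' Splits a study result into the tables behind the standard displays:
#' distributions of the fixed effect(s), of the Pearson recovery of the
#' linear/change factor, of its agreement ICC, of curvature recovery
#' (quadratic conditions), and of covariate correlations (covariate
#' conditions). Each table carries per-model median, quartiles, and SD.
#'
#' @param study a [run_study()] result.
#' @return named list of data frames (elements are `NULL` when the condition
#'   does not produce them).
#' @export
figure_tables <- function(study) {
  stopifnot(inherits(study, "growth_study"))
  rec <- study$records[study$records$converged, , drop = FALSE]
  if (nrow(rec) == 0) stop("no converged replications in the study result")
  tab <- function(var) {
    if (!var %in% names(rec) || all(is.na(rec[[var]]))) return(NULL)
    out <- do.call(rbind, lapply(split(rec, rec$model), function(g) {
      v <- g[[var]]
      v <- v[!is.na(v)]
      if (!length(v)) return(NULL)
      data.frame(model = g$model[1], waves = g$waves[1], n = length(v),
                 median = stats::median(v),
                 q25 = unname(stats::quantile(v, .25)),
                 q75 = unname(stats::quantile(v, .75)),
                 sd = stats::sd(v))
    }))
    out[order(out$waves), , drop = FALSE]
  }
  list(
    fixed_linear = tab("fixed_linear"),
    fixed_curvature = tab("fixed_curvature"),
    r_linear = tab("r_linear"),
    icc_linear = tab("icc_linear"),
    r_curvature = tab("r_curvature"),
    icc_curvature = tab("icc_curvature"),
    wcor_intercept = tab("wcor_intercept"),
    wcor_slope = tab("wcor_slope")
  )
}

#' Boxplot of recovery distributions by ladder entry
#'
#' @param x a `growth_study`.
#' @param what records column to display (default `"r_linear"`).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.growth_study <- function(x, what = "r_linear", ...) {
  rec <- x$records[x$records$converged, , drop = FALSE]
  if (!what %in% names(rec)) stop("no column '", what, "' in records")
  graphics::boxplot(rec[[what]] ~ rec$waves, xlab = "waves used",
                    ylab = what, main = x$provenance$condition, ...)
  graphics::abline(h = stats::median(rec[[what]], na.rm = TRUE), lty = 3)
  invisible(x)
}

#' Export study results
#'
#' Writes the tidy per-replication record table and the per-model summary.
#'
#' @param study a `growth_study`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"json"` for the summary; records are always CSV.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  if (format == "csv") {
    utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                     row.names = FALSE)
  } else {
    jsonlite::write_json(study$summary, file.path(dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  prov <- study$provenance
  prov$convergence_counts <- as.data.frame(prov$convergence_counts)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
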