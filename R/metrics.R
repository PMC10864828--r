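#' Pearson recovery correlation
#'
#' Product-moment correlation between per-individual estimated and true
#' growth parameters. Insensitive to shifts or positive rescalings of either
#' argument, so a model that recovers rank order but misses the magnitude of
#' effects can still score 1; see [icc2_agreement()] for the penalized
#' alternative.
#'
#' @param estimated,true numeric vectors of equal length (at least 3),
#'   neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_recovery <- function(estimated, true) {
  check_pair(estimated, true, min_n = 3)
  if (stats::sd(estimated) == 0 || stats::sd(true) == 0) {
    stop("correlation undefined: constant input vector")
  }
  stats::cor(estimated, true)
}

#' Agreement intraclass correlation between estimated and true parameters
#'
#' Treats the `n` individuals as targets and `{estimated, true}` as the two
#' measurements of a two-way ANOVA, and returns an absolute-agreement
#' intraclass correlation, which penalizes mean (and scale) differences
#' between the recovered and generating values that a Pearson correlation
#' ignores. With `MSR` the between-target, `MSC` the between-measurement,
#' and `MSE` the residual mean square:
#'
#' * `type = "average"` (default): `(MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#'   the average-measures form — e.g. pairing `1..50` against `11..60` gives
#'   1.00 for the Pearson correlation but 0.895 here;
#' * `type = "single"`: `(MSR - MSE) / (MSR + (k - 1) MSE +
#'   k (MSC - MSE) / n)` with `k = 2`.
#'
#' @param estimated,true numeric vectors of equal length `n >= 3`.
#' @param type `"average"` or `"single"`.
#' @return intraclass correlation (at most 1; can be negative).
#' @examples
#' icc2_agreement(11:60, 1:50) # 0.895
#' @export
icc2_agreement <- function(estimated, true, type = c("average", "single")) {
  type <- match.arg(type)
  check_pair(estimated, true, min_n = 3)
  ms <- icc_mean_squares(cbind(estimated, true))
  n <- length(estimated)
  k <- 2
  if (type == "average") {
    (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  }
}

## Two-way ANOVA mean squares of an n x k table (targets x measurements).
icc_mean_squares <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

check_pair <- function(estimated, true, min_n = 3) {
  if (length(estimated) != length(true)) {
    stop("`estimated` and `true` must have equal length")
  }
  if (length(estimated) < min_n) {
    stop("need at least ", min_n, " pairs")
  }
  if (anyNA(estimated) || anyNA(true)) {
    stop("missing values in recovery inputs")
  }
  invisible(TRUE)
}

#' Aggregate per-replication recovery records
#'
#' Collapses a tidy table of per-replication recovery results (as produced by
#' [run_study()]) into one row per model label: median and standard deviation
#' (denominator `n - 1`) of the fixed-effect estimates, medians of the
#' Pearson and ICC recovery measures, medians of the covariate correlations
#' when present, and the count of converged replications. Non-converged
#' replications are excluded from all aggregates and reported in
#' `n_converged` / `n_total`.
#'
#' @param records data frame with columns `model`, `converged`, `fixed_*`,
#'   `r_*`, `icc_*` and optionally `wcor_*`.
#' @return a data frame, one row per model label.
#' @export
recovery_summary <- function(records) {
  stopifnot(is.data.frame(records))
  labels <- unique(records$model)
  rows <- lapply(labels, function(lab) {
    g <- records[records$model == lab, , drop = FALSE]
    conv <- g[g$converged, , drop = FALSE]
    if (nrow(conv) == 0) {
      warning("no converged replications for model '", lab, "': omitted")
      return(NULL)
    }
    if (nrow(conv) == 1) {
      warning("single converged replication for model '", lab,
              "': SD undefined")
    }
    out <- data.frame(model = lab, n_total = nrow(g),
                      n_converged = nrow(conv))
    for (v in intersect(c("fixed_linear", "fixed_curvature"), names(conv))) {
      vals <- conv[[v]]
      if (all(is.na(vals))) next
      out[[paste0("median_", v)]] <- stats::median(vals, na.rm = TRUE)
      out[[paste0("sd_", v)]] <- if (sum(!is.na(vals)) > 1) {
        stats::sd(vals, na.rm = TRUE)
      } else NA_real_
    }
    for (v in intersect(c("r_linear", "icc_linear", "r_curvature",
                          "icc_curvature", "wcor_intercept", "wcor_slope"),
                        names(conv))) {
      vals <- conv[[v]]
      if (all(is.na(vals))) next
      out[[paste0("median_", v)]] <- stats::median(vals, na.rm = TRUE)
      out[[paste0("q25_", v)]] <- unname(stats::quantile(vals, 0.25,
                                                         na.rm = TRUE))
      out[[paste0("q75_", v)]] <- unname(stats::quantile(vals, 0.75,
                                                         na.rm = TRUE))
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no converged replications in `records`")
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  do.call(rbind, rows)
}
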