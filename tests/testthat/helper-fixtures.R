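## Shared fixtures and a lazy cache so expensive Monte-Carlo runs are computed
## once per test session and reused across test files.

lin_pop <- function(...) linear_population(...)
quad_pop <- function(...) quadratic_population(...)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

## 200-replication linear study over the full 2-5 wave ladder (used by the
## monotonicity / unbiasedness / variance-ordering properties and the
## property-based acceptance block).
linear_study_200 <- function() {
  cached("linear_study_200", run_study("linear_n200", n_replications = 200,
                                       seed = 1234))
}

## paired N = 200 vs N = 2000 runs, shared ladder, for the N-invariance checks
linear_study_small_n200 <- function() {
  cached("lin_small_200",
         run_study("linear_n200", n_replications = 150, seed = 99,
                   waves = c(2, 3)))
}

linear_study_small_n2000 <- function() {
  cached("lin_small_2000",
         run_study("linear_n2000", n_replications = 150, seed = 99,
                   waves = c(2, 3)))
}
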