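# Shared desk-scale cohort: 3 subjects, 12-s trials, built once per run.
# Simulation and preparation are deterministic, so every test file sees
# the same data.
.cohort_cache <- new.env(parent = emptyenv())

shared_prep <- function() {
  if (is.null(.cohort_cache$prep)) {
    cohort <- make_cohort(3, seed = 42)
    .cohort_cache$cohort <- cohort
    .cohort_cache$sessions <- lapply(cohort, function(p) {
      simulate_session(p, session_plan(p$block_order, trial_duration_s = 12,
                                       seed = 420 + p$subject_id),
                       seed = 4200 + p$subject_id)
    })
    .cohort_cache$prep <- lapply(.cohort_cache$sessions, prepare_subject)
  }
  .cohort_cache$prep
}

shared_sessions <- function() {
  shared_prep()
  .cohort_cache$sessions
}

shared_cohort <- function() {
  shared_prep()
  .cohort_cache$cohort
}

# Small labeled Gaussian toy problem for classifier tests.
gaussian_toy <- function(n_per_class, p, delta = 2, seed = 1, sd = 1) {
  set.seed(seed)
  mu1 <- rep(0, p)
  mu2 <- c(rep(delta, min(3, p)), rep(0, p - min(3, p)))
  X <- rbind(matrix(stats::rnorm(n_per_class * p, sd = sd), n_per_class, p) +
               rep(mu1, each = n_per_class),
             matrix(stats::rnorm(n_per_class * p, sd = sd), n_per_class, p) +
               rep(mu2, each = n_per_class))
  list(X = X, y = rep(c("a", "b"), each = n_per_class),
       mu = rbind(mu1, mu2))
}
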