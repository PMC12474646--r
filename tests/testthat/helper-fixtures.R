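# Shared fixtures. Heavy objects (the trained network, the synthetic
# cohorts it is trained and validated on) are built once per test run and
# cached, so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 20-subject training cohort at the generator's default study conditions.
training_cohort <- function() {
  .cached("training_cohort", function() {
    suppressWarnings(generate_cohort(cohort_config(n_subjects = 20, seed = 101)))
  })
}

# 30-subject validation cohort, disjoint seed.
validation_cohort <- function() {
  .cached("validation_cohort", function() {
    suppressWarnings(generate_cohort(cohort_config(n_subjects = 30, seed = 202)))
  })
}

# 20-subject detection cohort for the repeatability check.
detection_cohort <- function() {
  .cached("detection_cohort", function() {
    suppressWarnings(generate_cohort(cohort_config(n_subjects = 20, seed = 42)))
  })
}

# The network trained with the default (tuned) hyperparameters on the
# training cohort; trained once and reused everywhere.
shared_model <- function() {
  .cached("shared_model", function() {
    train_segmenter(training_cohort(), model_config(seed = 101))
  })
}

# A deliberately tiny cohort for fast unit tests of the trainer itself.
tiny_cohort <- function(n_subjects = 2, seed = 7) {
  suppressWarnings(generate_cohort(cohort_config(
    n_subjects = n_subjects, measurements_per_subject = 2,
    baseline_gap = c(30, 40), seed = seed
  )))
}

# Random physiological parameter sets spanning the supported box.
random_params <- function(n, seed = 5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(
      v0 = runif(1, 1, 20), p50 = runif(1, 0.5, 10),
      p0 = runif(1, 30, 100), z = runif(1, 0, 0.3)
    )
  })
}

# Bisection root of dpdt on [0, p0]: independent oracle for the
# equilibrium tension.
bisect_equilibrium <- function(params, tol = 1e-10) {
  f <- function(p) dpdt(p, params)
  lo <- 0
  hi <- params$p0
  if (f(hi) >= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
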