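# Shared fixtures. Expensive objects (MCMC fits, cohorts) are memoized in
# a session-local cache so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The worked single-datum example: an isotropic unit-variance Gaussian at
# the origin versus a unit segment of Gaussian centers at height 1.
toy_pair <- function() {
  list(manifold_point(c(0, 0)),
       manifold_segment(c(-0.5, 1), c(0.5, 1)))
}
toy_noise <- function() noise_model(1, 1)
toy_datum <- function() matrix(c(0, 0.5), 1)

# Shipped calibrated task variants.
variants4 <- function() cached("variants4", default_variants())

# A generic test arc (radius 0.8, 2.4 rad span) and segment.
test_arc <- function() manifold_arc(c(0.3, -0.2), 0.8, 0.4, 2.4)
test_segment <- function() manifold_segment(c(-1, 0.25), c(1, 0.75))

# Reduced-scale planted logistic cohort with the human-like sensitivity
# vector, plus its hierarchical fit (used across sensitivity tests).
human_like_mu <- function() {
  stats::setNames(c(0, 1, 4.66, 1.12, 0.23, 2.21),
                  c("intercept", "L", "D", "B", "V", "R"))
}

planted_cohort <- function() cached("planted_cohort", {
  pol <- list(type = "logistic", mu = human_like_mu(),
              scale = stats::setNames(c(0.1, 0.15, 1.0, 0.25, 0.1, 0.5),
                                      names(human_like_mu())))
  spec <- cohort_spec(names(variants4()), n_participants = 10L,
                      n_trials = 100L, policy = pol, master_seed = 424242)
  generate_cohort(spec, variants4())
})

planted_design <- function() cached("planted_design", {
  coh <- planted_cohort()
  build_design(coh$trials, variants4(), choices = coh$choices)
})

planted_fit <- function() cached("planted_fit", {
  suppressWarnings(fit_hierarchical(planted_design(), chains = 3L,
                                    warmup = 800L, iter = 800L,
                                    seed = 99L, rhat_threshold = 1.05))
})

# Likelihood-only comparison fit on the same design.
planted_fit_lik <- function() cached("planted_fit_lik", {
  suppressWarnings(fit_hierarchical(planted_design(), terms = "L",
                                    chains = 3L, warmup = 800L,
                                    iter = 800L, seed = 98L,
                                    rhat_threshold = 1.05))
})

# Cohort of pure maximum-likelihood observers at the same reduced scale.
ml_cohort <- function() cached("ml_cohort", {
  spec <- cohort_spec(names(variants4()), n_participants = 10L,
                      n_trials = 100L,
                      policy = list(type = "observer",
                                    strategy = "max_likelihood"),
                      master_seed = 31337)
  generate_cohort(spec, variants4())
})

ml_fit <- function() cached("ml_fit", {
  coh <- ml_cohort()
  des <- build_design(coh$trials, variants4(), choices = coh$choices)
  suppressWarnings(fit_hierarchical(des, chains = 3L, warmup = 800L,
                                    iter = 800L, seed = 77L,
                                    rhat_threshold = 1.05))
})
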