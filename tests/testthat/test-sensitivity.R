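# Design construction and hierarchical sensitivity estimation.

test_that("design rows: symmetry zeroes, label-swap antisymmetry, likelihood closed form", {
  # congruent mirrored segments: a centroid on the symmetry line zeroes
  # every predictor
  v <- task_variant("mirror",
                    manifold_segment(c(-1, 0.5), c(1, 0.5)),
                    manifold_segment(c(-1, -0.5), c(1, -0.5)),
                    noise_model(0.8, 10))
  tdf <- data.frame(trial_id = 1L, variant = "mirror", swap = 0L,
                    centroid_x = 0.37, centroid_y = 0)
  des <- build_design(tdf, list(mirror = v))
  expect_equal(unlist(des[paste0("delta_", c("L", "D", "B", "V", "R"))]),
               rep(0, 5), ignore_attr = TRUE, tolerance = 1e-12)

  # relabeling the models (mirror the centroid and the orientation)
  # negates every delta
  v2 <- variants4()$boundary
  tdf2 <- data.frame(trial_id = 1:50, variant = "boundary", swap = 0L,
                     centroid_x = runif(50, -2, 2),
                     centroid_y = runif(50, -1, 1))
  tdf2_swapped <- transform(tdf2, swap = 1L, centroid_y = -centroid_y)
  d1 <- build_design(tdf2, list(boundary = v2))
  d2 <- build_design(tdf2_swapped, list(boundary = v2))
  for (k in paste0("delta_", c("L", "D", "B", "V", "R")))
    expect_equal(d1[[k]], -d2[[k]], tolerance = 1e-10)

  # delta_L equals the clamped-projection closed form
  vd <- variants4()$dimensionality
  cc <- c(1.4, 0.2)
  tdf3 <- data.frame(trial_id = 1L, variant = "dimensionality",
                     swap = 0L, centroid_x = cc[1], centroid_y = cc[2])
  d3 <- build_design(tdf3, list(dimensionality = vd))
  pair <- occamfia:::variant_pair(vd, 0L)
  d_up <- ml_project(pair$up, cc)$distance
  d_dn <- ml_project(pair$down, cc)$distance
  sg <- vd$noise$sigma
  expect_equal(d3$delta_L, -(10 / (2 * sg^2)) * (d_up^2 - d_dn^2),
               tolerance = 1e-12)
})

test_that("choices join correctly and degenerate trials are dropped with a count", {
  coh <- planted_cohort()
  des <- planted_design()
  expect_true(all(des$choice_up %in% 0:1))
  expect_gte(attr(des, "n_dropped"), 0)
  expect_equal(nrow(des) + attr(des, "n_dropped"), nrow(coh$trials))
  # missing choices error
  expect_error(
    build_design(coh$trials, variants4(),
                 choices = coh$choices[-1, ]), "cover")
})

test_that("the hierarchical fit recovers planted human-like sensitivities", {
  fit <- planted_fit()
  expect_s3_class(fit, "hier_fit")
  # reduced-scale fits tolerate slightly looser mixing than the shipped
  # full-scale sampler settings
  expect_lt(max(fit$diagnostics$rhat), 1.1)
  mu <- fit$draws$mu
  planted <- human_like_mu()
  for (k in c("L", "D", "B", "V", "R")) {
    est <- mean(mu[, k]); psd <- sd(mu[, k])
    expect_lt(abs(est - planted[[k]]) / psd, 3)
  }
  rs <- relative_sensitivity(fit)
  rel_planted <- planted[c("D", "B", "V", "R")] / planted[["L"]]
  for (i in 1:4) {
    expect_lt(abs(rs$population$mean[i] - rel_planted[i]) /
                rs$population$sd[i], 3)
  }
})

test_that("relative sensitivity is a per-draw ratio, scale-invariant, and guarded", {
  fit <- planted_fit()
  rs <- relative_sensitivity(fit)
  # scaling every coefficient leaves the ratios untouched
  fit2 <- fit
  fit2$draws$mu <- fit$draws$mu * 3.7
  fit2$draws$beta <- fit$draws$beta * 3.7
  rs2 <- relative_sensitivity(fit2)
  expect_equal(rs$population$mean, rs2$population$mean, tolerance = 1e-12)
  expect_equal(rs$participant$mean, rs2$participant$mean,
               tolerance = 1e-12)
  # a fit whose FIA coefficients are all zero has zero ratios
  fit3 <- fit
  fit3$draws$mu[, c("D", "B", "V", "R")] <- 0
  fit3$draws$beta[, , c("D", "B", "V", "R")] <- 0
  rs3 <- relative_sensitivity(fit3)
  expect_equal(rs3$population$mean, rep(0, 4), ignore_attr = TRUE)
  # guard: shrink the likelihood coefficient below threshold on some
  # draws and expect them excluded (with a warning past 1%)
  fit4 <- fit
  fit4$draws$mu[1:100, "L"] <- 1e-6
  expect_warning(rs4 <- relative_sensitivity(fit4), "excluded")
  expect_equal(unique(rs4$population$n_guarded), 100)
})

test_that("WAIC comparison favors the full model for FIA-sensitive cohorts only", {
  wt <- compare_waic(planted_fit(), planted_fit_lik())
  expect_lt(attr(wt, "diff"), -2 * attr(wt, "se_diff"))

  # for pure maximum-likelihood observers the likelihood-only model is
  # not meaningfully worse
  coh <- ml_cohort()
  des <- build_design(coh$trials, variants4(), choices = coh$choices)
  fit_l <- suppressWarnings(
    fit_hierarchical(des, terms = "L", chains = 3, warmup = 800,
                     iter = 800, seed = 41, rhat_threshold = 1.05))
  wt2 <- compare_waic(ml_fit(), fit_l)
  expect_gt(attr(wt2, "diff"), -2 * attr(wt2, "se_diff"))
  # mismatched data are rejected
  expect_error(compare_waic(planted_fit(), fit_l), "identical data")
})

test_that("an ML-observer cohort shows no sensitivity to any FIA term", {
  rs <- relative_sensitivity(ml_fit())
  for (i in 1:4) {
    expect_lt(rs$population$q025[i], 0)
    expect_gt(rs$population$q975[i], 0)
  }
})

test_that("the lapse-extended model recovers a planted lapse rate", {
  pol <- list(type = "logistic", mu = human_like_mu(),
              scale = stats::setNames(rep(0.05, 6),
                                      names(human_like_mu())),
              lapse = 0.1)
  spec <- cohort_spec(c("dimensionality", "volume"),
                      n_participants = 8L, n_trials = 120L,
                      policy = pol, master_seed = 606)
  coh <- generate_cohort(spec, variants4())
  des <- build_design(coh$trials, variants4(), choices = coh$choices)
  fit <- suppressWarnings(fit_lapse(des, chains = 2, warmup = 800,
                                    iter = 800, seed = 8,
                                    rhat_threshold = 1.1))
  lam <- fit$draws$lambda_population
  expect_lt(abs(mean(lam) - 0.1) / sd(lam), 3)
  # misspecification direction: ignoring lapses shrinks the fitted
  # likelihood coefficient, modeling them does not
  fit_nolapse <- suppressWarnings(
    fit_hierarchical(des, chains = 2, warmup = 800, iter = 800,
                     seed = 9, rhat_threshold = 1.1))
  expect_lt(mean(fit_nolapse$draws$mu[, "L"]),
            mean(fit$draws$mu[, "L"]))
})

test_that("accuracy-sensitivity correlations behave at the limits", {
  # a posterior with no uncertainty about participant sensitivities:
  # accuracy strictly decreasing in |relative sensitivity - 1| must give
  # Spearman's rho of exactly -1
  J <- 12L; M <- 40L
  relD <- seq(0.2, 3, length.out = J)
  beta <- array(1, c(M, J, 3L),
                dimnames = list(NULL, sprintf("p%02d", 1:J),
                                c("intercept", "L", "D")))
  beta[, , "D"] <- matrix(relD, M, J, byrow = TRUE)
  fake <- structure(list(draws = list(beta = beta),
                         participants = sprintf("p%02d", 1:J),
                         terms = c("L", "D")), class = "hier_fit")
  acc <- data.frame(participant_id = sprintf("p%02d", 1:J),
                    accuracy = 1 - 0.3 * abs(relD - 1))
  out <- accuracy_sensitivity_corr(fake, acc, n_draws = 10)
  expect_equal(out$rho_mean[out$term == "dimensionality"], -1)
  expect_equal(out$rho_sd[out$term == "dimensionality"], 0)
  # permuted accuracies: correlation centered on zero
  set.seed(14)
  null_rho <- replicate(50, {
    acc_p <- acc; acc_p$accuracy <- sample(acc_p$accuracy)
    accuracy_sensitivity_corr(fake, acc_p, n_draws = 5)$rho_mean[1]
  })
  expect_lt(abs(mean(null_rho)), 0.15)
  expect_error(accuracy_sensitivity_corr(fake, acc[1:3, ]), "at least 5")
})
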