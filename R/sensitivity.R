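# Sensitivity estimation: how strongly choices weigh the likelihood and
# each geometric complexity term.
#
# The choice model is a hierarchical logistic regression
#   P(choose up) = logistic(b0 + bL*dL + bD*dD + bB*dB + bV*dV + bR*dR)
# with participant-level coefficients partially pooled under
# Normal(population mean, population scale) and weakly informative priors
# (Normal(0, 5) means, half-Normal(2.5) scales on the standardized
# predictor scale). Predictors are the up-minus-down differences, in nats,
# of the maximum log-likelihood and of the four FIA penalty terms, so a
# likelihood coefficient of 1 with all relative sensitivities equal to 1
# is exactly the FIA-posterior observer. Predictors are scaled internally
# for sampling and the draws are mapped back to the nat scale.

FIA_TERM_NAMES <- c("D" = "dimensionality", "B" = "boundary",
                    "V" = "volume", "R" = "robustness")

#' Build a regression design from trials and choices
#'
#' One row per trial with the up-minus-down differences (model 2 - model
#' 1, in nats) of the maximum log-likelihood (`delta_L`) and of the four
#' FIA penalty terms (`delta_D`, `delta_B`, `delta_V`, `delta_R`), plus
#' the indicator `choice_up` when choices are supplied. Trials whose FIA
#' breakdown is degenerate (non-positive observed information on an arc)
#' are dropped; their count is kept in the `"n_dropped"` attribute.
#'
#' @param trials either a [sample_trials()] `"trial_set"` or a data.frame
#'   with columns `trial_id`, `variant`, `swap`, `centroid_x`,
#'   `centroid_y` and optionally `participant_id`.
#' @param variants named list of [task_variant()] objects covering every
#'   variant name present (ignored when `trials` is a trial_set, which
#'   carries its own).
#' @param choices optional data.frame with `trial_id`, `choice` (1/2) and
#'   optionally `participant_id`, matched by (participant, trial).
#' @return A `data.frame` of design rows.
#' @export
build_design <- function(trials, variants = NULL, choices = NULL) {
  if (inherits(trials, "trial_set")) {
    variants <- stats::setNames(list(trials$variant),
                                trials$variant$name)
    tdf <- trials$trials
    tdf$centroid_x <- trials$centroids[, 1]
    tdf$centroid_y <- trials$centroids[, 2]
  } else {
    tdf <- as.data.frame(trials)
  }
  if (is.null(tdf$participant_id)) tdf$participant_id <- 1L
  need <- c("trial_id", "variant", "swap", "centroid_x", "centroid_y")
  if (!all(need %in% names(tdf)))
    stop("trials must provide columns ", paste(need, collapse = ", "),
         call. = FALSE)
  des <- design_rows(tdf, variants)
  if (!is.null(choices)) {
    if (is.null(choices$participant_id)) choices$participant_id <- 1L
    key_d <- paste(des$participant_id, des$trial_id)
    key_c <- paste(choices$participant_id, choices$trial_id)
    pos <- match(key_d, key_c)
    if (anyNA(pos))
      stop("choices do not cover every trial in the design", call. = FALSE)
    des$choice_up <- as.integer(choices$choice[pos] == 2L)
  }
  n_dropped <- sum(des$degenerate)
  des <- des[!des$degenerate, , drop = FALSE]
  des$degenerate <- NULL
  rownames(des) <- NULL
  attr(des, "n_dropped") <- n_dropped
  des
}

# All design rows (degenerate ones flagged, not dropped); internal.
#' @noRd
design_rows <- function(tdf, variants) {
  missing_v <- setdiff(unique(tdf$variant), names(variants))
  if (length(missing_v))
    stop("no task_variant supplied for: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  out <- vector("list", 0L)
  for (vn in unique(tdf$variant)) {
    variant <- variants[[vn]]
    for (o in 0:1) {
      idx <- which(tdf$variant == vn & tdf$swap == o)
      if (!length(idx)) next
      pair <- variant_pair(variant, o)
      C <- cbind(tdf$centroid_x[idx], tdf$centroid_y[idx])
      up <- fia_components(pair$up, C, variant$noise)
      dn <- fia_components(pair$down, C, variant$noise)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = tdf$participant_id[idx],
        trial_id = tdf$trial_id[idx],
        variant = vn, swap = o,
        delta_L = up$rel_log_max_lik - dn$rel_log_max_lik,
        delta_D = up$term_dimensionality - dn$term_dimensionality,
        delta_B = up$term_boundary - dn$term_boundary,
        delta_V = up$term_volume - dn$term_volume,
        delta_R = up$term_robustness - dn$term_robustness,
        degenerate = up$degenerate | dn$degenerate)
    }
  }
  des <- do.call(rbind, out)
  des <- des[order(des$participant_id, des$trial_id), ]
  rownames(des) <- NULL
  des
}

# ---- JAGS machinery ------------------------------------------------------

#' @noRd
jags_model_string <- function(K, lapse = FALSE) {
  eta <- paste(sprintf("X[i,%d] * beta[pid[i],%d]", 1:K, 1:K),
               collapse = " + ")
  lik <- if (lapse) {
    paste0(
      "    y[i] ~ dbern(p[i])\n",
      "    p[i] <- lam[pid[i]] / 2 + (1 - lam[pid[i]]) * ilogit(", eta, ")\n")
  } else {
    paste0("    y[i] ~ dbern(p[i])\n",
           "    logit(p[i]) <- ", eta, "\n")
  }
  lapse_block <- if (lapse) paste0(
    "  for (j in 1:J) {\n",
    "    lam[j] <- 0.5 * ilogit(laml[j])\n",
    "    laml[j] ~ dnorm(mu_l, tau_l)\n",
    "  }\n",
    "  mu_l ~ dnorm(-2.2, 0.25)\n",
    "  sigma_l ~ dnorm(0, 1) T(0,)\n",
    "  tau_l <- pow(sigma_l, -2)\n") else ""
  # non-centered parameterization of the participant level: mixes far
  # better than beta[j,k] ~ dnorm(mu[k], tau[k]) for logistic hierarchies
  paste0(
    "model {\n",
    "  for (i in 1:n) {\n", lik, "  }\n",
    "  for (j in 1:J) {\n",
    "    for (k in 1:K) {\n",
    "      z[j,k] ~ dnorm(0, 1)\n",
    "      beta[j,k] <- mu[k] + sigma[k] * z[j,k]\n",
    "    }\n",
    "  }\n",
    "  for (k in 1:K) {\n",
    "    mu[k] ~ dnorm(0, 0.04)\n",
    "    sigma[k] ~ dnorm(0, 0.16) T(0,)\n",
    "  }\n", lapse_block, "}\n")
}

#' Fit the hierarchical sensitivity model
#'
#' MCMC fit (JAGS) of the hierarchical logistic regression described
#' above. The returned draws are on the natural (nat) predictor scale, so
#' the likelihood coefficient of an exact FIA-posterior observer is 1.
#'
#' @param design a [build_design()] data.frame with a `choice_up` column.
#' @param terms which predictors to include besides the intercept, a
#'   subset of `c("L", "D", "B", "V", "R")`; the default full model uses
#'   all five, the likelihood-only comparison model uses `"L"`.
#' @param lapse if TRUE, fit the lapse-extended model in which the choice
#'   probability is mixed with a uniform component,
#'   `lambda/2 + (1 - lambda) * logistic(eta)`, with participant-level
#'   lambda in `[0, 0.5)` partially pooled on the logit scale.
#' @param chains,warmup,iter,thin sampler settings (defaults 4 chains,
#'   1000 warmup, 1000 kept draws).
#' @param seed integer; chain RNGs are derived from it.
#' @param rhat_threshold split-R̂ above which the fit is flagged
#'   non-converged (default 1.01).
#' @param quiet suppress JAGS progress output.
#' @return An object of class `"hier_fit"`; see
#'   [relative_sensitivity()], [compare_waic()], [fit_waic()].
#' @export
fit_hierarchical <- function(design, terms = c("L", "D", "B", "V", "R"),
                             lapse = FALSE, chains = 4L, warmup = 1000L,
                             iter = 1000L, thin = 1L, seed = 1L,
                             rhat_threshold = 1.01, quiet = TRUE) {
  stopifnot(is.data.frame(design))
  if (is.null(design$choice_up))
    stop("design has no choice_up column; supply choices to build_design()",
         call. = FALSE)
  terms <- match.arg(terms, c("L", "D", "B", "V", "R"),
                     several.ok = TRUE)
  cols <- paste0("delta_", terms)
  if (!all(cols %in% names(design)))
    stop("design lacks columns ", paste(setdiff(cols, names(design)),
                                        collapse = ", "), call. = FALSE)
  pid_f <- factor(design$participant_id)
  J <- nlevels(pid_f)
  if (J < 2L) stop("need at least 2 participants", call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(design[cols]))
  scales <- c(1, vapply(seq_along(cols) + 1L, function(k) {
    s <- stats::sd(X[, k])
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1)))
  Xs <- sweep(X, 2L, scales, "/")
  K <- ncol(Xs)

  data_list <- list(y = as.integer(design$choice_up), X = unname(Xs),
                    pid = as.integer(pid_f), n = nrow(Xs), J = J, K = K)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, "jags-chain", ch))
  })
  monitor <- c("mu", "sigma", "beta")
  if (lapse) monitor <- c(monitor, "lam", "mu_l", "sigma_l")

  run <- function() {
    jm <- rjags::jags.model(
      textConnection(jags_model_string(K, lapse = lapse)),
      data = data_list, inits = inits, n.chains = chains,
      n.adapt = min(500L, warmup), quiet = quiet)
    extra <- warmup - min(500L, warmup)
    if (extra > 0L) stats::update(jm, n.iter = extra,
                                  progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitor, n.iter = iter,
                        thin = thin, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  vn <- colnames(samp[[1]])
  pick <- function(pat) {
    as.matrix(do.call(rbind, lapply(samp, function(s)
      s[, grep(pat, vn), drop = FALSE])))
  }
  mu_std <- pick("^mu\\[")
  sigma_std <- pick("^sigma\\[")
  beta_std_flat <- pick("^beta\\[")
  M <- nrow(mu_std)
  term_names <- c("intercept", terms)
  colnames(mu_std) <- colnames(sigma_std) <- term_names
  # beta[j,k] columns come ordered j fastest; rebuild as draws x J x K
  beta <- array(NA_real_, c(M, J, K),
                dimnames = list(NULL, levels(pid_f), term_names))
  for (k in seq_len(K)) for (j in seq_len(J)) {
    beta[, j, k] <- beta_std_flat[, sprintf("beta[%d,%d]", j, k)]
  }
  # convergence diagnostics on the population-level parameters
  hyper <- grep("^(mu|sigma|mu_l|sigma_l)", vn, value = TRUE)
  hy <- lapply(samp, function(s) s[, hyper, drop = FALSE])
  rhat <- tryCatch({
    gd <- coda::gelman.diag(coda::as.mcmc.list(hy), autoburnin = FALSE,
                            multivariate = FALSE)
    stats::setNames(gd$psrf[, 1], rownames(gd$psrf))
  }, error = function(e) stats::setNames(rep(NA_real_, length(hyper)),
                                         hyper))
  ess <- coda::effectiveSize(coda::as.mcmc.list(hy))
  converged <- all(is.finite(rhat)) && max(rhat) < rhat_threshold
  if (!converged)
    warning(sprintf(
      "fit flagged non-converged (max split-Rhat = %.3f >= %.3f)",
      suppressWarnings(max(rhat)), rhat_threshold), call. = FALSE)

  # back-transform to the nat scale
  mu <- sweep(mu_std, 2L, scales, "/")
  sigma <- sweep(sigma_std, 2L, scales, "/")
  beta_nat <- beta
  for (k in seq_len(K)) beta_nat[, , k] <- beta[, , k] / scales[k]

  lam_draws <- mu_l <- NULL
  if (lapse) {
    lam_flat <- pick("^lam\\[")
    lam_draws <- lam_flat[, sprintf("lam[%d]", seq_len(J)), drop = FALSE]
    colnames(lam_draws) <- levels(pid_f)
    mu_l <- as.numeric(pick("^mu_l"))
  }

  fit <- structure(list(
    draws = list(mu = mu, sigma = sigma, beta = beta_nat,
                 lambda = lam_draws, lambda_population =
                   if (lapse) 0.5 * stats::plogis(mu_l) else NULL),
    std = list(mu = mu_std, beta = beta, scales = scales, X = Xs,
               y = data_list$y, pid = data_list$pid),
    terms = terms, lapse = lapse, participants = levels(pid_f),
    design = design,
    diagnostics = list(rhat = rhat, ess = ess,
                       threshold = rhat_threshold),
    converged = converged,
    sampler = list(chains = chains, warmup = warmup, iter = iter,
                   thin = thin, seed = seed)),
    class = "hier_fit")
  fit$waic <- fit_waic(fit)
  fit
}

#' Lapse-extended hierarchical fit
#'
#' Convenience wrapper for [fit_hierarchical()] with `lapse = TRUE`.
#' @inheritParams fit_hierarchical
#' @param ... passed on to [fit_hierarchical()].
#' @export
fit_lapse <- function(design, ...) {
  fit_hierarchical(design, lapse = TRUE, ...)
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf(
    "<hierarchical sensitivity fit> %d participants, %d trials, %s model%s\n",
    length(x$participants), nrow(x$design),
    paste(x$terms, collapse = "+"),
    if (x$lapse) " (lapse-extended)" else ""))
  cat(sprintf("  converged: %s (max Rhat %.3f); WAIC %.1f\n",
              x$converged, suppressWarnings(max(x$diagnostics$rhat)),
              x$waic$waic))
  mu <- x$draws$mu
  for (k in colnames(mu))
    cat(sprintf("  beta[%s] = %.3f +/- %.3f\n", k, mean(mu[, k]),
                stats::sd(mu[, k])))
  invisible(x)
}

# Pointwise WAIC from the stored standardized draws; exported because the
# comparison helper and the tests recompute it on demand.

#' WAIC of a hierarchical fit
#'
#' Widely applicable information criterion computed from the pointwise
#' posterior predictive density over the kept draws:
#' `waic = -2 * sum(lppd_i - p_waic_i)` with `p_waic_i` the pointwise
#' posterior variance of the log predictive density.
#'
#' @param fit a `"hier_fit"`.
#' @param chunk draws processed per block (memory control).
#' @return List with `waic`, `se`, `elpd`, `p_waic` and the pointwise
#'   `elpd_i` vector.
#' @export
fit_waic <- function(fit, chunk = 200L) {
  Xs <- fit$std$X; y <- fit$std$y; pid <- fit$std$pid
  beta <- fit$std$beta            # draws x J x K, standardized scale
  M <- dim(beta)[1]; n <- length(y)
  lp_sum <- numeric(n); lp_sq <- numeric(n); lse <- rep(-Inf, n)
  for (i0 in seq(1L, M, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, M)
    for (m in ii) {
      B <- beta[m, , , drop = TRUE]
      if (is.null(dim(B))) B <- matrix(B, ncol = dim(beta)[3])
      eta <- rowSums(Xs * B[pid, , drop = FALSE])
      p <- stats::plogis(eta)
      if (fit$lapse) {
        lam <- fit$draws$lambda[m, pid]
        p <- lam / 2 + (1 - lam) * p
      }
      lp <- ifelse(y == 1L, log(p), log1p(-p))
      lp_sum <- lp_sum + lp
      lp_sq <- lp_sq + lp^2
      lse <- pmax(lse, lp) + log1p(exp(pmin(lse, lp) - pmax(lse, lp)))
    }
  }
  lppd_i <- lse - log(M)
  p_waic_i <- (lp_sq - lp_sum^2 / M) / (M - 1)
  elpd_i <- lppd_i - p_waic_i
  list(waic = -2 * sum(elpd_i), se = 2 * sqrt(n * stats::var(elpd_i)),
       elpd = sum(elpd_i), p_waic = sum(p_waic_i), elpd_i = elpd_i)
}

#' Relative sensitivities to the FIA terms
#'
#' Ratio of each FIA-term coefficient to the likelihood coefficient,
#' computed per posterior draw (never as a ratio of means), at the
#' population level (from the population-mean draws) and per participant.
#' Zero is maximum-likelihood behavior; one is Bayes-optimal weighting.
#' Draws with `|beta_L|` below `guard` are excluded and counted; a
#' warning is attached if more than 1% of draws are guarded.
#'
#' @param fit a converged `"hier_fit"` including the likelihood term.
#' @param guard threshold on `|beta_L|` (nat scale).
#' @return An object of class `"relative_sensitivity"`: list with
#'   `population` (data.frame term, mean, sd, q025, q975, n_guarded),
#'   `participant` (data.frame participant_id, term, mean, sd), and
#'   `draws` (population-ratio draws).
#' @export
relative_sensitivity <- function(fit, guard = 0.05) {
  stopifnot(inherits(fit, "hier_fit"))
  if (!"L" %in% fit$terms)
    stop("fit does not include the likelihood term", call. = FALSE)
  fterms <- intersect(c("D", "B", "V", "R"), fit$terms)
  mu <- fit$draws$mu
  keep <- abs(mu[, "L"]) >= guard
  n_guard <- sum(!keep)
  if (n_guard > 0.01 * nrow(mu))
    warning(sprintf(
      "%d of %d draws have |beta_L| < %g and were excluded from ratios",
      n_guard, nrow(mu), guard), call. = FALSE)
  ratios <- mu[keep, fterms, drop = FALSE] / mu[keep, "L"]
  pop <- data.frame(
    term = unname(FIA_TERM_NAMES[fterms]),
    mean = colMeans(ratios),
    sd = apply(ratios, 2L, stats::sd),
    q025 = apply(ratios, 2L, stats::quantile, 0.025),
    q975 = apply(ratios, 2L, stats::quantile, 0.975),
    n_guarded = n_guard, row.names = NULL)
  beta <- fit$draws$beta
  part <- do.call(rbind, lapply(seq_along(fit$participants), function(j) {
    bl <- beta[, j, "L"]
    kj <- abs(bl) >= guard
    rj <- beta[kj, j, fterms, drop = FALSE] / bl[kj]
    data.frame(participant_id = fit$participants[j],
               term = unname(FIA_TERM_NAMES[fterms]),
               mean = apply(rj, 3L, mean),
               sd = apply(rj, 3L, stats::sd), row.names = NULL)
  }))
  structure(list(population = pop, participant = part, draws = ratios,
                 guard = guard),
            class = "relative_sensitivity")
}

#' @export
print.relative_sensitivity <- function(x, ...) {
  cat("<relative sensitivities> (0 = maximum-likelihood, 1 = Bayes-optimal)\n")
  for (i in seq_len(nrow(x$population)))
    cat(sprintf("  %-15s %6.3f +/- %.3f\n", x$population$term[i],
                x$population$mean[i], x$population$sd[i]))
  invisible(x)
}

#' Compare two hierarchical fits by WAIC
#'
#' @param fit_full,fit_reduced two `"hier_fit"` objects estimated on the
#'   identical design rows (checked).
#' @return Data.frame with one row per model (WAIC, se, p_waic) plus
#'   attributes `diff` (full minus reduced; negative favors the full
#'   model) and `se_diff`.
#' @export
compare_waic <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "hier_fit"),
            inherits(fit_reduced, "hier_fit"))
  if (!identical(fit_full$std$y, fit_reduced$std$y) ||
      !identical(fit_full$std$pid, fit_reduced$std$pid))
    stop("fits were not estimated on identical data", call. = FALSE)
  w1 <- fit_full$waic; w2 <- fit_reduced$waic
  d_i <- w1$elpd_i - w2$elpd_i
  out <- data.frame(
    model = c(paste(fit_full$terms, collapse = "+"),
              paste(fit_reduced$terms, collapse = "+")),
    waic = c(w1$waic, w2$waic), se = c(w1$se, w2$se),
    p_waic = c(w1$p_waic, w2$p_waic))
  attr(out, "diff") <- w1$waic - w2$waic
  attr(out, "se_diff") <- 2 * sqrt(length(d_i) * stats::var(d_i))
  out
}

#' Rank correlation between accuracy and sensitivity mistuning
#'
#' For each FIA term and each posterior draw, the Spearman correlation
#' across participants between task accuracy and `|relative sensitivity -
#' 1|` (distance from the Bayes-optimal weighting), summarized as
#' posterior mean and sd.
#'
#' @param fit a `"hier_fit"`.
#' @param accuracies data.frame with `participant_id` and `accuracy`.
#' @param n_draws posterior draws used (subsampled deterministically).
#' @param guard `|beta_L|` guard as in [relative_sensitivity()].
#' @return Data.frame: term, rho_mean, rho_sd.
#' @export
accuracy_sensitivity_corr <- function(fit, accuracies, n_draws = 400L,
                                      guard = 0.05) {
  stopifnot(inherits(fit, "hier_fit"))
  if (nrow(accuracies) < 5L)
    stop("need at least 5 participants for a rank correlation",
         call. = FALSE)
  pos <- match(fit$participants, as.character(accuracies$participant_id))
  if (anyNA(pos))
    stop("accuracies must cover every participant in the fit",
         call. = FALSE)
  acc <- accuracies$accuracy[pos]
  fterms <- intersect(c("D", "B", "V", "R"), fit$terms)
  beta <- fit$draws$beta
  M <- dim(beta)[1]
  use <- unique(round(seq(1L, M, length.out = min(n_draws, M))))
  out <- lapply(fterms, function(k) {
    rho <- vapply(use, function(m) {
      bl <- beta[m, , "L"]
      bl[abs(bl) < guard] <- sign(bl[abs(bl) < guard]) * guard +
        (bl[abs(bl) < guard] == 0) * guard
      rel <- beta[m, , k] / bl
      suppressWarnings(stats::cor(acc, abs(rel - 1), method = "spearman"))
    }, numeric(1))
    data.frame(term = unname(FIA_TERM_NAMES[k]),
               rho_mean = mean(rho, na.rm = TRUE),
               rho_sd = stats::sd(rho, na.rm = TRUE))
  })
  do.call(rbind, out)
}
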