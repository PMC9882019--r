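# Synthetic cohorts: participants with planted decision policies, their
# trials and their choices, emulating the structure of the deposited
# behavioral dataset so the whole estimation pipeline is testable without
# any download. Two planting policies are supported:
#  * "logistic": participant-level regression coefficients drawn from a
#    planted population distribution, choices drawn from the logistic
#    model on the trial design rows (exact parameter-recovery ground
#    truth);
#  * "observer": participant-level observer configurations (strategy +
#    noise/integration parameters), choices produced by the simulated
#    observers (exercises the full nonlinear decision path).

#' Cohort specification
#'
#' @param variants character vector of task-variant names (each
#'   participant performs exactly one variant, as in the behavioral
#'   study).
#' @param n_participants participants per variant (default 50).
#' @param n_trials trials per participant (default 500).
#' @param policy a list describing the planted decision policy. Either
#'   `list(type = "logistic", mu = <named length-6>, scale = <named
#'   length-6>, lapse = 0)` with names `intercept, L, D, B, V, R` (mu on
#'   the nat scale: `L = 1` with all FIA coefficients 1 is the
#'   FIA-posterior observer), or `list(type = "observer", strategy =,
#'   rho =, integration =, temperature =, lapse =)` where each observer
#'   parameter is a scalar (fixed across participants) or a length-2
#'   `c(mean, sd)` population distribution (truncated to its valid
#'   range).
#' @param master_seed integer; every other seed is derived from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(variants = c("dimensionality", "boundary",
                                     "volume", "robustness"),
                        n_participants = 50L, n_trials = 500L,
                        policy = list(type = "observer",
                                      strategy = "posterior_sample"),
                        master_seed = 1L) {
  stopifnot(length(variants) >= 1L, n_participants >= 2L, n_trials >= 1L)
  if (!policy$type %in% c("logistic", "observer"))
    stop("policy$type must be 'logistic' or 'observer'", call. = FALSE)
  if (policy$type == "logistic") {
    nm <- c("intercept", "L", "D", "B", "V", "R")
    policy$mu <- policy$mu %||%
      stats::setNames(c(0, 1, 1, 1, 1, 1), nm)
    policy$scale <- policy$scale %||%
      stats::setNames(pmax(0.05, 0.25 * abs(policy$mu)), nm)
    policy$lapse <- policy$lapse %||% 0
    stopifnot(all(nm %in% names(policy$mu)),
              all(nm %in% names(policy$scale)))
  } else {
    policy$strategy <- policy$strategy %||% "posterior_sample"
    policy$rho <- policy$rho %||% 0
    policy$integration <- policy$integration %||% 1
    policy$temperature <- policy$temperature %||% 0
    policy$lapse <- policy$lapse %||% 0
  }
  structure(list(variants = variants,
                 n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), policy = policy,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# scalar -> fixed; c(mean, sd) -> truncated-normal population draw
#' @noRd
draw_param <- function(spec, n, lo = 0, hi = Inf) {
  if (length(spec) == 1L) return(rep(spec, n))
  x <- stats::rnorm(n, spec[1], spec[2])
  pmin(pmax(x, lo), hi)
}

#' Generate a complete synthetic cohort
#'
#' Produces trials, choices and a ground-truth table for every participant
#' of a [cohort_spec()], deterministically from the master seed. Trials
#' come from [sample_trials()]; choices come from the planted policy.
#' Logistic-policy choices on trials with a degenerate FIA breakdown
#' (excluded from designs downstream) are drawn as fair coins.
#'
#' @param spec a [cohort_spec()].
#' @param variants named list of [task_variant()] objects (default: the
#'   shipped calibrated variants).
#' @return A list of class `"cohort"` with data.frames `participants`
#'   (ground truth), `trials` (trial-level, with centroids), `points`
#'   (long format), `choices`, and a `manifest` list (seeds, geometry
#'   hash, sizes). The `choices` table is the package's canonical
#'   interchange schema for observed choice data.
#' @export
generate_cohort <- function(spec, variants = default_variants()) {
  stopifnot(inherits(spec, "cohort_spec"))
  missing_v <- setdiff(spec$variants, names(variants))
  if (length(missing_v))
    stop("variants list lacks: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  pol <- spec$policy
  participants <- trials <- points <- choices <- list()
  pix <- 0L
  for (vn in spec$variants) {
    variant <- variants[[vn]]
    # participant-level planted parameters for this variant group
    gt <- with_seed(derive_seed(spec$master_seed, paste0("policy-", vn)), {
      n <- spec$n_participants
      if (pol$type == "logistic") {
        nm <- c("intercept", "L", "D", "B", "V", "R")
        B <- sapply(nm, function(k)
          stats::rnorm(n, pol$mu[[k]], pol$scale[[k]]))
        colnames(B) <- paste0("beta_", nm)
        data.frame(B, lapse = rep(pol$lapse, n))
      } else {
        data.frame(strategy = rep(pol$strategy, n),
                   rho = draw_param(pol$rho, n),
                   integration = draw_param(pol$integration, n, 0, 1),
                   temperature = draw_param(pol$temperature, n),
                   lapse = draw_param(pol$lapse, n, 0, 0.45))
      }
    })
    for (i in seq_len(spec$n_participants)) {
      pix <- pix + 1L
      pid <- sprintf("%s-%02d", vn, i)
      seed_i <- derive_seed(spec$master_seed, paste0("trials-", pid))
      ts <- sample_trials(variant, spec$n_trials, seed = seed_i)
      tdf <- ts$trials
      tdf$participant_id <- pid
      tdf$centroid_x <- ts$centroids[, 1]
      tdf$centroid_y <- ts$centroids[, 2]
      pdf <- ts$points
      pdf$participant_id <- pid

      seed_c <- derive_seed(spec$master_seed, paste0("choices-", pid))
      if (pol$type == "logistic") {
        des <- design_rows(tdf, stats::setNames(list(variant), vn))
        beta <- unlist(gt[i, paste0("beta_",
                                    c("intercept", "L", "D", "B", "V",
                                      "R"))])
        eta <- beta[1] + as.matrix(des[paste0("delta_",
                                              c("L", "D", "B", "V",
                                                "R"))]) %*% beta[-1]
        p2 <- stats::plogis(as.numeric(eta))
        p2[des$degenerate] <- 0.5
        p2 <- gt$lapse[i] / 2 + (1 - gt$lapse[i]) * p2
        ch <- with_seed(seed_c,
                        ifelse(stats::runif(nrow(des)) < p2, 2L, 1L))
        ord <- match(tdf$trial_id, des$trial_id)
        choice <- ch[ord]
        # maximum-likelihood solution for dual scoring
        ml <- ml_solutions(variant, tdf,
                           derive_seed(spec$master_seed,
                                       paste0("mlsol-", pid)))
      } else {
        obs <- observer_config(
          strategy = gt$strategy[i], sensory_noise_rho = gt$rho[i],
          integration_strength = gt$integration[i],
          choice_temperature = gt$temperature[i],
          lapse_rate = gt$lapse[i])
        ses <- session_choices(obs, ts, seed = seed_c)
        choice <- ses$choice
        ml <- ses$ml_solution
      }
      trials[[pix]] <- tdf
      points[[pix]] <- pdf
      choices[[pix]] <- data.frame(
        participant_id = pid, trial_id = tdf$trial_id, variant = vn,
        choice = choice, ml_solution = ml,
        correct_generative = as.integer(choice == tdf$true_model),
        correct_ml = as.integer(choice == ml), seed = seed_c)
      participants[[pix]] <- cbind(
        data.frame(participant_id = pid, variant = vn,
                   policy = pol$type), gt[i, , drop = FALSE])
    }
  }
  trials <- do.call(rbind, trials); rownames(trials) <- NULL
  cols <- c("participant_id", "trial_id", "variant", "swap", "true_model",
            "true_s", "centroid_x", "centroid_y")
  trials <- trials[cols]
  points <- do.call(rbind, points); rownames(points) <- NULL
  points <- points[c("participant_id", "trial_id", "point_index", "x",
                     "y")]
  choices <- do.call(rbind, choices); rownames(choices) <- NULL
  participants <- do.call(rbind, participants)
  rownames(participants) <- NULL
  structure(list(
    participants = participants, trials = trials, points = points,
    choices = choices,
    manifest = list(master_seed = spec$master_seed,
                    n_participants = spec$n_participants,
                    n_trials = spec$n_trials, variants = spec$variants,
                    policy_type = pol$type,
                    geometry_hash = geometry_hash(variants),
                    package_version =
                      as.character(utils::packageVersion("occamfia")))),
    class = "cohort")
}

# deterministic ML solutions for a trial table; internal
#' @noRd
ml_solutions <- function(variant, tdf, seed) {
  with_seed(seed, {
    coin <- stats::runif(nrow(tdf))
    ml <- integer(nrow(tdf))
    for (o in 0:1) {
      idx <- which(tdf$swap == o)
      if (!length(idx)) next
      pair <- variant_pair(variant, o)
      d <- evidence_delta(list(pair$down, pair$up),
                          cbind(tdf$centroid_x[idx], tdf$centroid_y[idx]),
                          variant$noise, "ml_only")
      ml[idx] <- ifelse(d > 0, 2L, ifelse(d < 0, 1L,
                                          ifelse(coin[idx] < 0.5, 1L,
                                                 2L)))
    }
    ml
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic cohort> %d participants x %d trials (%s policy), variants: %s\n",
    x$manifest$n_participants * length(x$manifest$variants),
    x$manifest$n_trials, x$manifest$policy_type,
    paste(x$manifest$variants, collapse = ", ")))
  invisible(x)
}

#' @noRd
geometry_hash <- function(variants) {
  desc <- vapply(variants, function(v) {
    paste(v$name, v$noise$sigma, v$noise$n_obs,
          paste(deparse(manifold_to_list(v$shape_a)), collapse = ""),
          paste(deparse(manifold_to_list(v$shape_b)), collapse = ""))
  }, character(1))
  fnv1a_hex(paste(desc, collapse = "|"))
}

#' Reference sensitivity bands from simulated ideal-type observers
#'
#' Simulates `n_observers` single-variant sessions of a reference
#' strategy (by default the observer that samples from the exact Bayesian
#' posterior), fits the hierarchical sensitivity model to their choices,
#' and returns the posterior of the population-level relative
#' sensitivities as a reference band (mean, +/- 1 and 2 sd) for each FIA
#' term.
#'
#' @param variants named list of [task_variant()] objects to span (one
#'   group of observers per variant).
#' @param n_observers observers per variant.
#' @param strategy reference strategy (an [observer_config()] strategy
#'   name).
#' @param n_trials trials per observer.
#' @param seed master seed.
#' @param ... sampler settings forwarded to [fit_hierarchical()].
#' @return List with `bands` (data.frame term, mean, sd, lo1, hi1, lo2,
#'   hi2), the `fit`, and the `sensitivity` object.
#' @export
reference_bands <- function(variants, n_observers = 50L,
                            strategy = "posterior_sample",
                            n_trials = 500L, seed = 1L, ...) {
  spec <- cohort_spec(variants = names(variants),
                      n_participants = n_observers, n_trials = n_trials,
                      policy = list(type = "observer",
                                    strategy = strategy),
                      master_seed = seed)
  coh <- generate_cohort(spec, variants)
  des <- build_design(coh$trials, variants, choices = coh$choices)
  fit <- fit_hierarchical(des, seed = derive_seed(seed, "reffit"), ...)
  rs <- relative_sensitivity(fit)
  b <- rs$population
  bands <- data.frame(term = b$term, mean = b$mean, sd = b$sd,
                      lo1 = b$mean - b$sd, hi1 = b$mean + b$sd,
                      lo2 = b$mean - 2 * b$sd, hi2 = b$mean + 2 * b$sd)
  list(bands = bands, fit = fit, sensitivity = rs, cohort = coh)
}
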