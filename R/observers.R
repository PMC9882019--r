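# Simulated decision-makers.
#
# All strategies are functions of the (possibly sensory-corrupted) data
# centroid, because every per-model score used here differs from a full
# data-set score only by a model-independent constant. The
# noise-integration-noise (NIN) observer composes three mechanisms:
#  1. sensory noise: each observed point is corrupted by an isotropic
#     Gaussian with sd rho (equivalently the centroid by rho/sqrt(N));
#  2. integration over latent causes: the per-model score interpolates
#     between the maximum log-likelihood (integration_strength 0) and the
#     full Jeffreys-prior log marginal (integration_strength 1);
#  3. choice noise: softmax readout of the score difference with a
#     temperature, plus a uniform lapse mixture.

#' Observer configuration
#'
#' @param strategy one of `"max_likelihood"`, `"fia"`, `"exact_bayes"`,
#'   `"posterior_sample"`, `"nin"`.
#' @param sensory_noise_rho sd of the Gaussian corruption applied to each
#'   observed point before deciding (>= 0; NIN mechanism 1, but honored by
#'   every strategy).
#' @param integration_strength scalar in `[0, 1]` interpolating the
#'   per-model score from maximum log-likelihood (0) to the full log
#'   marginal (1). Used by the `"nin"` strategy.
#' @param choice_temperature softmax temperature on the score difference;
#'   0 gives a deterministic argmax.
#' @param lapse_rate probability of an information-independent uniform
#'   choice, in `[0, 0.5)`.
#' @param seed optional default seed used by [decide()] and
#'   [simulate_session()] when none is passed.
#' @return An object of class `"observer_config"`.
#' @export
observer_config <- function(strategy = c("max_likelihood", "fia",
                                         "exact_bayes", "posterior_sample",
                                         "nin"),
                            sensory_noise_rho = 0,
                            integration_strength = 1,
                            choice_temperature = 0,
                            lapse_rate = 0, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(sensory_noise_rho >= 0, choice_temperature >= 0,
            integration_strength >= 0, integration_strength <= 1)
  if (lapse_rate < 0 || lapse_rate >= 0.5)
    stop("lapse_rate must lie in [0, 0.5)", call. = FALSE)
  structure(list(strategy = strategy,
                 sensory_noise_rho = sensory_noise_rho,
                 integration_strength = integration_strength,
                 choice_temperature = choice_temperature,
                 lapse_rate = lapse_rate, seed = seed),
            class = "observer_config")
}

#' @export
print.observer_config <- function(x, ...) {
  cat(sprintf(
    "<observer '%s'> rho = %.3g, integration = %.3g, temperature = %.3g, lapse = %.3g\n",
    x$strategy, x$sensory_noise_rho, x$integration_strength,
    x$choice_temperature, x$lapse_rate))
  invisible(x)
}

# P(choose model 2) for a matrix of (already corrupted) centroids.
#' @noRd
choice_prob_centroids <- function(observer, pair, C, noise) {
  delta <- switch(observer$strategy,
    max_likelihood = evidence_delta(pair, C, noise, "ml_only"),
    fia = {
      d <- evidence_delta(pair, C, noise, "fia")
      # degenerate breakdowns (h <= 0 on an arc) fall back to the exact
      # marginal the FIA approximates
      if (anyNA(d)) {
        bad <- is.na(d)
        d[bad] <- evidence_delta(pair, C[bad, , drop = FALSE], noise,
                                 "exact")
      }
      d
    },
    exact_bayes = evidence_delta(pair, C, noise, "exact"),
    posterior_sample = evidence_delta(pair, C, noise, "exact"),
    nin = {
      g <- observer$integration_strength
      (1 - g) * evidence_delta(pair, C, noise, "ml_only") +
        g * evidence_delta(pair, C, noise, "exact")
    })
  p <- switch(observer$strategy,
    posterior_sample = stats::plogis(delta),  # probability matching
    {
      tau <- observer$choice_temperature
      if (tau > 0) stats::plogis(delta / tau)
      else ifelse(delta > 0, 1, ifelse(delta < 0, 0, 0.5))
    })
  lam <- observer$lapse_rate
  lam / 2 + (1 - lam) * p
}

# Vectorized choices for one orientation group; returns integer 1/2.
#' @noRd
draw_choices <- function(observer, pair, C, noise) {
  p2 <- choice_prob_centroids(observer, pair, C, noise)
  ifelse(stats::runif(nrow(C)) < p2, 2L, 1L)
}

#' Decide one trial
#'
#' Applies the observer's strategy to a single stimulus: corrupts the
#' observed points with the sensory noise, scores the two models, and
#' draws the (possibly stochastic) choice.
#'
#' @param observer an [observer_config()].
#' @param pair list of two manifolds: model 1 ("down") and model 2 ("up").
#' @param X N x 2 matrix of observed points.
#' @param noise the generative [noise_model()] (supplies sigma used in the
#'   observer's internal likelihoods).
#' @param seed optional seed (falls back to the observer's own).
#' @return Integer choice, 1 or 2.
#' @export
decide <- function(observer, pair, X, noise, seed = NULL) {
  stopifnot(inherits(observer, "observer_config"))
  X <- as_point_matrix(X)
  noise <- noise_model(noise$sigma, nrow(X))
  with_seed(seed %||% observer$seed, {
    rho <- observer$sensory_noise_rho
    Xc <- if (rho > 0) X + rho * matrix(stats::rnorm(length(X)),
                                        nrow(X), 2L) else X
    C <- matrix(colMeans(Xc), 1L)
    draw_choices(observer, pair, C, noise)[1]
  })
}

#' Simulate a full session of an observer on a task variant
#'
#' Generates `n_trials` stimuli and the observer's choices, and scores
#' accuracy two ways: against the generating model (`generative`) and
#' against the per-trial maximum-likelihood solution (`ml`, the model
#' whose manifold is nearer the uncorrupted data centroid).
#'
#' @inheritParams decide
#' @param variant a [task_variant()].
#' @param n_trials number of trials (default 500).
#' @return An object of class `"session"`: list with `records` (one row
#'   per trial: trial_id, variant, swap, true_model, choice, ml_solution,
#'   correct_generative, correct_ml), `accuracy` (named numeric:
#'   generative, ml), plus the observer, variant and seed.
#' @export
simulate_session <- function(observer, variant, n_trials = 500L,
                             seed = NULL) {
  stopifnot(inherits(observer, "observer_config"),
            inherits(variant, "task_variant"))
  seed <- seed %||% observer$seed %||%
    stop("simulate_session needs a seed for reproducibility", call. = FALSE)
  ts <- sample_trials(variant, n_trials, seed = derive_seed(seed, "trials"))
  ch <- session_choices(observer, ts, seed = derive_seed(seed, "choices"))
  records <- cbind(ts$trials, ch)
  acc <- c(generative = mean(records$correct_generative),
           ml = mean(records$correct_ml))
  structure(list(records = records, accuracy = acc, observer = observer,
                 variant = variant, seed = seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf(
    "<session> %d trials of '%s' for a '%s' observer\n  accuracy: %.1f%% generative, %.1f%% vs maximum-likelihood solution\n",
    nrow(x$records), x$variant$name, x$observer$strategy,
    100 * x$accuracy[["generative"]], 100 * x$accuracy[["ml"]]))
  invisible(x)
}

# Choices + scoring for a whole trial_set; internal vectorized path.
# Sensory noise is applied at centroid scale (rho/sqrt(N)), which is
# distributionally identical to corrupting each point.
#' @noRd
session_choices <- function(observer, trial_set, seed = NULL) {
  variant <- trial_set$variant
  noise <- variant$noise
  n <- nrow(trial_set$trials)
  with_seed(seed, {
    rho_c <- observer$sensory_noise_rho / sqrt(noise$n_obs)
    C_obs <- trial_set$centroids +
      if (rho_c > 0) rho_c * matrix(stats::rnorm(2L * n), n, 2L) else 0
    choice <- integer(n)
    ml_sol <- integer(n)
    coin <- stats::runif(n)
    for (o in 0:1) {
      idx <- which(trial_set$trials$swap == o)
      if (!length(idx)) next
      pair <- variant_pair(variant, o)
      pl <- list(pair$down, pair$up)
      choice[idx] <- draw_choices(observer, pl,
                                  C_obs[idx, , drop = FALSE], noise)
      dml <- evidence_delta(pl, trial_set$centroids[idx, , drop = FALSE],
                            noise, "ml_only")
      ml_sol[idx] <- ifelse(dml > 0, 2L,
                            ifelse(dml < 0, 1L,
                                   ifelse(coin[idx] < 0.5, 1L, 2L)))
    }
    data.frame(choice = choice, ml_solution = ml_sol,
               correct_generative = choice == trial_set$trials$true_model,
               correct_ml = choice == ml_sol)
  })
}

#' Map an observer's choice probabilities over the data plane
#'
#' Places a single stimulus at each node of a rectangular grid, simulates
#' the observer `reps` times per node, and records the Monte-Carlo
#' estimate of P(choose model 2). Along vertical transects the 0.5-level
#' crossing of a logistic fit gives the observer's decision boundary.
#'
#' @inheritParams decide
#' @param grid list with `xlim`, `ylim` (length-2) and `nx`, `ny` node
#'   counts.
#' @param reps Monte-Carlo repetitions per node.
#' @param transect_x x-locations of the vertical transects used for the
#'   boundary estimate (default: five interior columns).
#' @param noise [noise_model()] for the stimulus; `n_obs = 1` reproduces
#'   the single-datum maps.
#' @return An object of class `"boundary_map"`: `x`, `y` node vectors,
#'   `P` (ny x nx matrix of P(choose model 2)), and `transects`
#'   (data.frame x, y50).
#' @export
boundary_map <- function(observer, pair, noise, grid, reps = 20L,
                         transect_x = NULL, seed = 1L) {
  stopifnot(inherits(observer, "observer_config"), length(pair) == 2L)
  xs <- seq(grid$xlim[1], grid$xlim[2], length.out = grid$nx)
  ys <- seq(grid$ylim[1], grid$ylim[2], length.out = grid$ny)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  n <- nrow(nodes)
  noise <- noise_model(noise$sigma, noise$n_obs)
  P <- with_seed(seed, {
    rho_c <- observer$sensory_noise_rho / sqrt(noise$n_obs)
    k <- integer(n)
    for (r in seq_len(reps)) {
      C <- nodes + if (rho_c > 0)
        rho_c * matrix(stats::rnorm(2L * n), n, 2L) else 0
      k <- k + (draw_choices(observer, pair, C, noise) == 2L)
    }
    k / reps
  })
  Pm <- matrix(P, grid$ny, grid$nx, byrow = TRUE)
  if (is.null(transect_x))
    transect_x <- stats::quantile(xs, c(0.2, 0.35, 0.5, 0.65, 0.8),
                                  names = FALSE)
  tr <- data.frame(x = transect_x,
                   y50 = vapply(transect_x, function(x0) {
                     j <- which.min(abs(xs - x0))
                     fit_crossing(ys, Pm[, j], reps)
                   }, numeric(1)))
  structure(list(x = xs, y = ys, P = Pm, transects = tr,
                 observer = observer, reps = reps),
            class = "boundary_map")
}

# 0.5 crossing of P(y) via a binomial logistic fit, falling back to linear
# interpolation when the fit is degenerate (e.g. a deterministic step).
#' @noRd
fit_crossing <- function(y, p, reps) {
  k <- round(p * reps)
  fit <- tryCatch(
    suppressWarnings(stats::glm(cbind(k, reps - k) ~ y,
                                family = stats::binomial())),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (all(is.finite(cf)) && abs(cf[2]) > 1e-8) {
      y50 <- -cf[1] / cf[2]
      if (y50 >= min(y) && y50 <= max(y)) return(unname(y50))
    }
  }
  # interpolate the first upward 0.5 crossing
  above <- p >= 0.5
  i <- which(!above[-length(p)] & above[-1])
  if (!length(i)) return(NA_real_)
  i <- i[1]
  y[i] + (0.5 - p[i]) * (y[i + 1] - y[i]) / (p[i + 1] - p[i])
}

#' k-nearest-neighbor interpolation of recorded choices
#'
#' Spatial summary of choice records: at each grid node, the mean of the
#' choices (coded as P(model 2)) of the `k` records with the nearest data
#' centroids.
#'
#' @param records data.frame with columns `centroid_x`, `centroid_y`,
#'   `choice` (1/2).
#' @param k number of neighbors (>= 1, at most the number of records).
#' @param grid list with `xlim`, `ylim`, `nx`, `ny`.
#' @return A `"knn_map"` object: `x`, `y`, and `P` (ny x nx matrix of the
#'   k-NN mean of `choice == 2`).
#' @export
knn_choice_map <- function(records, k, grid) {
  need <- c("centroid_x", "centroid_y", "choice")
  if (!all(need %in% names(records)))
    stop("records must have columns centroid_x, centroid_y, choice",
         call. = FALSE)
  if (nrow(records) < k)
    stop("fewer records than neighbors k", call. = FALSE)
  xs <- seq(grid$xlim[1], grid$xlim[2], length.out = grid$nx)
  ys <- seq(grid$ylim[1], grid$ylim[2], length.out = grid$ny)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  up <- as.numeric(records$choice == 2L)
  cx <- records$centroid_x; cy <- records$centroid_y
  P <- numeric(nrow(nodes))
  chunk <- 2048L
  for (i0 in seq(1L, nrow(nodes), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(nodes))
    d2 <- outer(nodes[idx, 1], cx, "-")^2 + outer(nodes[idx, 2], cy, "-")^2
    P[idx] <- apply(d2, 1L, function(row) {
      mean(up[order(row)[seq_len(k)]])
    })
  }
  structure(list(x = xs, y = ys,
                 P = matrix(P, grid$ny, grid$nx, byrow = TRUE), k = k),
            class = "knn_map")
}
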