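# Psychophysical task variants and trial generation.
#
# Each variant opposes two shapes (canonically shape A on top, shape B at
# the bottom, mirrored about the x-axis). Per trial the generating shape is
# a fair coin, the latent center is a Jeffreys-prior draw on that shape,
# and N points are sampled from an isotropic Gaussian around it. Mirror
# randomization flips which shape is on top per trial, which is also what
# makes the trial-constant dimensionality and volume penalty differences
# identifiable in the sensitivity regression (they flip sign with the
# orientation while the up/down choice bias does not).
#
# Package-wide sign convention: model 1 is the "down" shape and model 2
# the "up" shape of a trial, after mirror randomization.

#' Construct a task variant
#'
#' @param name one of `"dimensionality"`, `"boundary"`, `"volume"`,
#'   `"robustness"` (or any label for custom pairs).
#' @param shape_a,shape_b the two manifolds in canonical placement:
#'   `shape_a` on top (y > 0), `shape_b` at the bottom. They must not
#'   intersect.
#' @param noise a [noise_model()]; defaults to N = 10 observations.
#' @param mirror_randomization randomly swap which shape is on top, per
#'   trial (default TRUE).
#' @param block_size feedback block length recorded as metadata only (no
#'   learning is simulated).
#' @return An object of class `"task_variant"` with precomputed up/down
#'   manifold pairs for both orientations.
#' @export
task_variant <- function(name, shape_a, shape_b, noise,
                         mirror_randomization = TRUE, block_size = 100L) {
  stopifnot(inherits(shape_a, "manifold"), inherits(shape_b, "manifold"),
            inherits(noise, "noise_model"))
  if (manifolds_overlap(shape_a, shape_b))
    stop("the two shapes of a task variant must be disjoint", call. = FALSE)
  orientations <- list(
    # orientation 0: A on top ("up" = model 2), B at the bottom
    list(down = shape_b, up = shape_a),
    # orientation 1: mirrored placement
    list(down = reflect_y(shape_a), up = reflect_y(shape_b)))
  structure(
    list(name = name, shape_a = shape_a, shape_b = shape_b, noise = noise,
         mirror_randomization = isTRUE(mirror_randomization),
         block_size = as.integer(block_size),
         orientations = orientations),
    class = "task_variant")
}

#' @export
print.task_variant <- function(x, ...) {
  cat(sprintf("<task variant '%s'> sigma = %.4g, N = %d, mirror = %s\n",
              x$name, x$noise$sigma, x$noise$n_obs,
              x$mirror_randomization))
  cat("  shape A (top): "); print(x$shape_a)
  cat("  shape B (bottom): "); print(x$shape_b)
  invisible(x)
}

# Coarse disjointness check: minimum distance between a dense sampling of
# one shape and the other shape, against the sampling resolution.
#' @noRd
manifolds_overlap <- function(m1, m2, n = 1000L) {
  s1 <- if (m1$d == 0L) 0 else seq(0, m1$length, length.out = n)
  p1 <- embed_manifold(m1, s1)
  pr <- ml_project_many(m2, p1)
  min(pr$distance) < 2 * m1$length / n + 1e-9
}

# Manifold pair (list(down, up)) for a vector of swap flags; internal.
#' @noRd
variant_pair <- function(variant, swap = 0L) {
  variant$orientations[[swap + 1L]]
}

#' The four default task variants
#'
#' Builds the dimensionality (point vs segment), boundary (two offset
#' segments whose near endpoints face each other), volume (short vs long
#' segment) and robustness (segment vs equal-length arc) pairs from the
#' packaged geometry config, with the shipped per-variant noise level
#' calibrated so that an ideal Bayesian observer outperforms a
#' maximum-likelihood observer by about one percentage point.
#'
#' @param config a pipeline/geometry config list (see
#'   [read_pipeline_config()]); defaults to the packaged
#'   `default_config.yaml`.
#' @param sigma optional named (or single) numeric overriding the shipped
#'   noise sd per variant.
#' @param n_obs observations per trial (default from config).
#' @return Named list of four [task_variant()] objects.
#' @export
default_variants <- function(config = NULL, sigma = NULL, n_obs = NULL) {
  if (is.null(config)) config <- read_pipeline_config()
  geoms <- config$variants
  out <- list()
  for (nm in names(geoms)) {
    gv <- geoms[[nm]]
    sg <- if (!is.null(sigma)) {
      if (!is.null(names(sigma))) unname(sigma[[nm]]) else sigma
    } else gv$sigma
    nobs <- n_obs %||% config$noise$n_obs %||% 10L
    out[[nm]] <- task_variant(
      name = nm,
      shape_a = manifold_from_list(gv$shape_a),
      shape_b = manifold_from_list(gv$shape_b),
      noise = noise_model(sg, nobs),
      mirror_randomization = config$mirror_randomization %||% TRUE,
      block_size = config$block_size %||% 100L)
  }
  out
}

#' Sample a set of trials from a task variant
#'
#' Vectorized generative process: fair-coin source shape, Jeffreys-prior
#' latent center, `N` iid Gaussian observations per trial. Fully
#' deterministic given `seed`.
#'
#' @param variant a [task_variant()].
#' @param n number of trials.
#' @param seed integer seed (the whole trial set is reproducible bitwise).
#' @return An object of class `"trial_set"`: list with
#'   `trials` (data.frame: trial_id, variant, swap, true_model, true_s),
#'   `points` (long data.frame: trial_id, point_index, x, y),
#'   `centroids` (n x 2 matrix), and the generating `variant`.
#' @export
sample_trials <- function(variant, n, seed = NULL) {
  stopifnot(inherits(variant, "task_variant"), n >= 1)
  n <- as.integer(n)
  N <- variant$noise$n_obs
  sg <- variant$noise$sigma
  with_seed(seed, {
    swap <- if (variant$mirror_randomization) {
      stats::rbinom(n, 1L, 0.5)
    } else rep(0L, n)
    true_model <- stats::rbinom(n, 1L, 0.5) + 1L  # 1 = down, 2 = up
    u <- stats::runif(n)
    Z <- array(stats::rnorm(n * N * 2L), dim = c(n, N, 2L))
    mu <- matrix(NA_real_, n, 2L)
    true_s <- numeric(n)
    for (o in 0:1) {
      pair <- variant_pair(variant, o)
      for (tm in 1:2) {
        idx <- which(swap == o & true_model == tm)
        if (!length(idx)) next
        m <- if (tm == 2L) pair$up else pair$down
        true_s[idx] <- u[idx] * m$length
        mu[idx, ] <- embed_manifold(m, true_s[idx])
      }
    }
    px <- mu[, 1] + sg * Z[, , 1L, drop = TRUE]
    py <- mu[, 2] + sg * Z[, , 2L, drop = TRUE]
    if (N == 1L) { px <- matrix(px, n, 1L); py <- matrix(py, n, 1L) }
    centroids <- cbind(rowMeans(px), rowMeans(py))
    points <- data.frame(
      trial_id = rep(seq_len(n), times = N),
      point_index = rep(seq_len(N), each = n),
      x = as.vector(px), y = as.vector(py))
    points <- points[order(points$trial_id, points$point_index), ]
    rownames(points) <- NULL
    structure(list(
      trials = data.frame(trial_id = seq_len(n), variant = variant$name,
                          swap = swap, true_model = true_model,
                          true_s = true_s),
      points = points, centroids = centroids, variant = variant,
      seed = seed), class = "trial_set")
  })
}

#' Sample a single trial
#'
#' Convenience wrapper around [sample_trials()] returning one fully
#' materialized trial.
#'
#' @inheritParams sample_trials
#' @param trial_id identifier stored on the trial.
#' @return A list of class `"trial"`: variant name, `true_model` (1 =
#'   down, 2 = up), `true_s`, `swap`, `X` (N x 2 matrix), `centroid`,
#'   `trial_id`, `seed`.
#' @export
sample_trial <- function(variant, seed = NULL, trial_id = 1L) {
  ts <- sample_trials(variant, 1L, seed = seed)
  X <- cbind(ts$points$x, ts$points$y)
  structure(list(
    variant = variant$name, true_model = ts$trials$true_model[1],
    true_s = ts$trials$true_s[1], swap = ts$trials$swap[1],
    X = X, centroid = ts$centroids[1, ], trial_id = trial_id,
    seed = seed), class = "trial")
}

#' Calibrate task difficulty to a target ideal-vs-ML accuracy gap
#'
#' Tunes the observation noise sigma (the monotone difficulty knob: larger
#' sigma lowers every observer's accuracy) until the generative-scored
#' accuracy advantage of a deterministic exact-Bayes observer over a
#' maximum-likelihood observer matches `target_gap`. The Monte-Carlo
#' estimate reuses one fixed set of latent draws across all sigma values
#' (common random numbers), so the gap is a smooth function of sigma and
#' can be bisected; the smallest sigma attaining the target (the rising,
#' easier branch) is returned.
#'
#' @param variant a [task_variant()].
#' @param target_gap accuracy gap to hit, as a fraction (default 0.01).
#' @param budget Monte-Carlo trials per gap evaluation.
#' @param sigma_range search interval for sigma.
#' @param tol acceptable |gap - target| at the solution.
#' @param grid_n coarse-grid size used to bracket the crossing.
#' @param seed seed for the common random numbers.
#' @return The variant with calibrated noise; attribute `"calibration"`
#'   holds the trace (grid and bisection evaluations), the achieved gap,
#'   target and seed.
#' @export
calibrate_difficulty <- function(variant, target_gap = 0.01,
                                 budget = 40000L,
                                 sigma_range = c(0.15, 3), tol = 0.0015,
                                 grid_n = 10L, seed = 1L) {
  stopifnot(inherits(variant, "task_variant"), target_gap >= 0)
  N <- variant$noise$n_obs
  n <- as.integer(budget)
  draws <- with_seed(derive_seed(seed, "calibrate"), list(
    swap = if (variant$mirror_randomization)
      stats::rbinom(n, 1L, 0.5) else rep(0L, n),
    true_model = stats::rbinom(n, 1L, 0.5) + 1L,
    u = stats::runif(n),
    W = matrix(stats::rnorm(2L * n), n, 2L),   # scaled centroid noise
    coin = stats::runif(n)))                   # ML tie-breaks

  gap_at <- function(sg) {
    nm <- noise_model(sg, N)
    acc_b <- acc_m <- logical(n)
    for (o in 0:1) {
      pair <- variant_pair(variant, o)
      for (tm in 1:2) {
        idx <- which(draws$swap == o & draws$true_model == tm)
        if (!length(idx)) next
        m <- if (tm == 2L) pair$up else pair$down
        mu <- embed_manifold(m, draws$u[idx] * m$length)
        C <- mu + (sg / sqrt(N)) * draws$W[idx, , drop = FALSE]
        d_ex <- evidence_delta(list(pair$down, pair$up), C, nm, "exact")
        ch_b <- ifelse(d_ex > 0, 2L, 1L)
        d_ml <- evidence_delta(list(pair$down, pair$up), C, nm, "ml_only")
        ch_m <- ifelse(d_ml > 0, 2L,
                       ifelse(d_ml < 0, 1L,
                              ifelse(draws$coin[idx] < 0.5, 1L, 2L)))
        acc_b[idx] <- ch_b == tm
        acc_m[idx] <- ch_m == tm
      }
    }
    mean(acc_b) - mean(acc_m)
  }

  sig_grid <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                      length.out = grid_n))
  trace <- data.frame(sigma = sig_grid,
                      gap = vapply(sig_grid, gap_at, numeric(1)),
                      phase = "grid")
  cross <- which(trace$gap >= target_gap)
  if (!length(cross))
    stop(sprintf(
      "difficulty target unreachable: max gap %.4f < target %.4f in sigma range [%.3g, %.3g]",
      max(trace$gap), target_gap, sigma_range[1], sigma_range[2]),
      call. = FALSE)
  i_hi <- min(cross)
  if (i_hi == 1L) {
    # already at or past the target at the easiest setting (e.g. a zero
    # target): return the easy end of the knob
    out <- variant
    out$noise <- noise_model(sig_grid[1], N)
    attr(out, "calibration") <- list(target = target_gap,
                                     achieved = trace$gap[1],
                                     sigma = sig_grid[1], tol = tol,
                                     seed = seed, budget = n,
                                     trace = trace)
    return(out)
  }
  lo <- sig_grid[i_hi - 1L]; hi <- sig_grid[i_hi]
  g_best <- trace$gap[i_hi]; s_best <- hi
  for (it in seq_len(14L)) {
    mid <- sqrt(lo * hi)
    g <- gap_at(mid)
    trace <- rbind(trace, data.frame(sigma = mid, gap = g,
                                     phase = "bisect"))
    if (abs(g - target_gap) < abs(g_best - target_gap)) {
      g_best <- g; s_best <- mid
    }
    if (abs(g - target_gap) < tol / 2) break
    if (g < target_gap) lo <- mid else hi <- mid
  }
  out <- variant
  out$noise <- noise_model(s_best, N)
  # rebuild nothing else: geometry is unchanged, only sigma moved
  attr(out, "calibration") <- list(target = target_gap,
                                   achieved = g_best, sigma = s_best,
                                   tol = tol, seed = seed, budget = n,
                                   trace = trace)
  out
}
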