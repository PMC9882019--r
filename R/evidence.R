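# Bayesian evidence for (manifold, data) pairs: exact Jeffreys-prior
# quadrature and the Fisher Information Approximation (FIA) split into
# dimensionality, boundary, volume and robustness penalties.
#
# Conventions (shared package-wide):
#  * natural logarithms everywhere;
#  * g and h are per-datum Fisher informations; the number of observations
#    N enters the penalty terms explicitly;
#  * penalties carry the sign with which they ADD to the log evidence, so
#    a complexity cost is negative.
#
# With L(s) the total log-likelihood, s_hat its clamped maximizer,
# a = N * h(s_hat) and b = L'(s_hat), the expansion used here is
#
#   log p(X|M) ~ L(s_hat)
#     - (d/2) log(N / 2pi)                                [dimensionality]
#     + b^2/(2a) + log[ Phi(sqrt(a)(Lambda - s_hat) - b/sqrt(a))
#                      - Phi(-sqrt(a) s_hat - b/sqrt(a)) ]      [boundary]
#     - log( integral of sqrt(g) ds )                          [volume]
#     - (1/2) log( h(s_hat) / g )                           [robustness]
#
# The boundary factor is the Gaussian mass of the local quadratic expansion
# actually contained in the parameter domain. At an interior optimum
# (b = 0, s_hat far from both ends) it vanishes; at a boundary optimum it
# equals 0.5*|l|^2_{h^-1} + log Phi(-|l|_{h^-1}) with |l|_{h^-1} the
# gradient length in the inverse observed-information metric, and it is
# continuous as the projection crosses an endpoint. For straight segments
# the expansion is exact.

# ---- internal vectorized core -------------------------------------------

# FIA components for many centroids at once. C is n x 2. Returns a list of
# numeric vectors. "rel" quantities omit the data-dependent constant
# -N log(2 pi sigma^2) - SS/(2 sigma^2), which is common to all models and
# cancels in every model comparison.
#' @noRd
fia_components <- function(m, C, noise) {
  n <- nrow(C)
  N <- noise$n_obs
  sig2 <- noise$sigma^2
  pr <- ml_project_many(m, C)
  rel_lml <- -N * pr$distance^2 / (2 * sig2)

  if (m$d == 0L) {
    z <- numeric(n)
    return(list(
      s_hat = z, on_boundary = rep(FALSE, n), s_star = z,
      distance = pr$distance, grad_norm = z,
      g = rep(1, n), h = rep(1, n),
      rel_log_max_lik = rel_lml,
      term_dimensionality = z, term_boundary = z, term_volume = z,
      term_robustness = z, rel_fia = rel_lml, degenerate = rep(FALSE, n)))
  }

  g <- 1 / sig2
  h <- observed_fisher_centroid(m, C, pr$s_hat, noise)
  mu <- embed_manifold(m, pr$s_hat)
  tang <- manifold_tangent(m, pr$s_hat)
  # gradient of the total log-likelihood at s_hat (0 at interior optima)
  b <- (N / sig2) *
    ((C[, 1] - mu[, 1]) * tang[, 1] + (C[, 2] - mu[, 2]) * tang[, 2])

  degenerate <- h <= 0
  a <- N * h
  sqa <- sqrt(pmax(a, 0))
  term_dim <- rep(-(m$d / 2) * log(N / (2 * pi)), n)
  term_vol <- rep(-log(m$length * sqrt(g)), n)
  term_rob <- rep(NA_real_, n)
  term_bnd <- rep(NA_real_, n)
  ok <- !degenerate
  if (any(ok)) {
    term_rob[ok] <- -0.5 * log(h[ok] / g)
    hi <- sqa[ok] * (m$length - pr$s_hat[ok]) - b[ok] / sqa[ok]
    lo <- -sqa[ok] * pr$s_hat[ok] - b[ok] / sqa[ok]
    term_bnd[ok] <- b[ok]^2 / (2 * a[ok]) + log_pnorm_diff(hi, lo)
  }
  rel_fia <- rel_lml + term_dim + term_bnd + term_vol + term_rob
  list(s_hat = pr$s_hat, on_boundary = pr$on_boundary, s_star = pr$s_star,
       distance = pr$distance,
       grad_norm = abs(b) / ifelse(sqa > 0, sqa, NA_real_),
       g = rep(g, n), h = h,
       rel_log_max_lik = rel_lml,
       term_dimensionality = term_dim, term_boundary = term_bnd,
       term_volume = term_vol, term_robustness = term_rob,
       rel_fia = rel_fia, degenerate = degenerate)
}

# Exact relative log marginal (same "rel" convention) for many centroids.
# Closed form for points and segments; fixed-order Gauss-Legendre for arcs
# (order chosen so that typical task geometries are converged well past
# choice-probability accuracy; the adaptive scalar path is the reference).
#' @noRd
exact_rel_marginal <- function(m, C, noise, n_nodes = 257L,
                               chunk = 8192L) {
  n <- nrow(C)
  N <- noise$n_obs
  sig2 <- noise$sigma^2
  if (m$kind == "point") {
    d2 <- (C[, 1] - m$location[1])^2 + (C[, 2] - m$location[2])^2
    return(-N * d2 / (2 * sig2))
  }
  if (m$kind == "segment") {
    t_star <- (C[, 1] - m$from[1]) * m$unit[1] +
              (C[, 2] - m$from[2]) * m$unit[2]
    dx <- C[, 1] - m$from[1] - t_star * m$unit[1]
    dy <- C[, 2] - m$from[2] - t_star * m$unit[2]
    dperp2 <- dx^2 + dy^2
    S <- sqrt(N) / noise$sigma
    -N * dperp2 / (2 * sig2) + 0.5 * log(2 * pi * sig2 / N) -
      log(m$length) + log_pnorm_diff(S * (m$length - t_star), S * (-t_star))
  } else {
    gl <- pracma::gaussLegendre(n_nodes, 0, m$length)
    th <- m$theta0 + m$orientation * gl$x / m$radius
    mux <- m$center[1] + m$radius * cos(th)
    muy <- m$center[2] + m$radius * sin(th)
    logw <- log(gl$w) - log(m$length)
    out <- numeric(n)
    for (i0 in seq(1L, n, by = chunk)) {
      idx <- i0:min(i0 + chunk - 1L, n)
      # ll[i, k] = -N |c_i - mu_k|^2 / (2 sig2)
      d2 <- outer(C[idx, 1], mux, "-")^2 + outer(C[idx, 2], muy, "-")^2
      ll <- -N * d2 / (2 * sig2)
      mrow <- apply(ll, 1L, max)
      out[idx] <- mrow +
        log(rowSums(exp(ll - mrow) *
                    matrix(exp(logw), length(idx), n_nodes, byrow = TRUE)))
    }
    out
  }
}

# ---- user-facing scalar API ---------------------------------------------

#' Log-likelihood of a data set at a manifold coordinate
#'
#' Sum over the rows of `X` of the log density of an isotropic 2D Gaussian
#' with standard deviation `noise$sigma` centered at `embed_manifold(m, s)`.
#'
#' @param m a manifold.
#' @param s arc-length coordinate (scalar or vector; vectorized over s).
#' @param X n x 2 matrix of observations.
#' @param noise a [noise_model()] (sigma is used; the actual row count of
#'   `X` is the N that enters the likelihood).
#' @return Log-likelihood in nats (vector along `s`).
#' @export
log_likelihood <- function(m, s, X, noise) {
  stopifnot(inherits(m, "manifold"), inherits(noise, "noise_model"))
  X <- as_point_matrix(X)
  n <- nrow(X)
  mu <- embed_manifold(m, s)
  sig2 <- noise$sigma^2
  cbar <- colMeans(X)
  ss <- sum((X[, 1] - cbar[1])^2 + (X[, 2] - cbar[2])^2)
  d2 <- (cbar[1] - mu[, 1])^2 + (cbar[2] - mu[, 2])^2
  -n * log(2 * pi * sig2) - (ss + n * d2) / (2 * sig2)
}

#' Exact log marginal likelihood under the Jeffreys prior
#'
#' Computes `log integral w(s) p(X | m, s) ds` over the arc-length domain,
#' with `w` the normalized Jeffreys prior (uniform for these manifolds).
#' Uses Gauss-Legendre quadrature in log space, doubling the node count
#' until two successive estimates agree to `tol`; point manifolds reduce to
#' the plain log-likelihood.
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance on the log marginal (nats).
#' @param max_nodes node-count ceiling before a convergence error.
#' @return Log marginal likelihood in nats, with attributes `nodes` (final
#'   rule size) and `delta` (last successive change).
#' @export
exact_log_marginal <- function(m, X, noise, tol = 1e-8, max_nodes = 4096L) {
  stopifnot(inherits(m, "manifold"), inherits(noise, "noise_model"))
  X <- as_point_matrix(X)
  if (m$d == 0L) {
    v <- log_likelihood(m, 0, X, noise)
    attr(v, "nodes") <- 1L; attr(v, "delta") <- 0
    return(v)
  }
  n_nodes <- 16L
  prev <- NA_real_
  repeat {
    gl <- pracma::gaussLegendre(n_nodes, 0, m$length)
    ll <- log_likelihood(m, gl$x, X, noise)
    est <- logsumexp(log(gl$w) + ll) - log(m$length)
    if (!is.na(prev) && abs(est - prev) < tol) {
      attr(est, "nodes") <- n_nodes
      attr(est, "delta") <- abs(est - prev)
      return(est)
    }
    if (n_nodes >= max_nodes)
      stop(sprintf(
        "quadrature did not converge: last delta %.3g at %d nodes (tol %.3g)",
        abs(est - prev), n_nodes, tol), call. = FALSE)
    prev <- est
    n_nodes <- n_nodes * 2L
  }
}

#' FIA breakdown of the log evidence
#'
#' Evaluates the four-term Fisher Information Approximation of the log
#' marginal likelihood at the maximum-likelihood projection, together with
#' the quantities entering it. For point manifolds all four penalty terms
#' are exactly zero and the approximation is exact.
#'
#' If the observed information at the projection is not positive (for arcs,
#' when the data centroid sits at or beyond the center of curvature) the
#' expansion is invalid: the breakdown is returned with `degenerate = TRUE`
#' and non-finite robustness/boundary terms, and such trials are excluded
#' from regression designs.
#'
#' @inheritParams log_likelihood
#' @param with_exact also run the exact quadrature and store it.
#' @return An object of class `"evidence_breakdown"`: a list with fields
#'   `log_max_likelihood`, `term_dimensionality`, `term_boundary`,
#'   `term_volume`, `term_robustness`, `fia_log_evidence`,
#'   `exact_log_evidence` (NA unless `with_exact`), `s_hat`, `on_boundary`,
#'   `grad_norm`, `g_at_shat`, `h_at_shat`, `degenerate`.
#' @export
fia_breakdown <- function(m, X, noise, with_exact = FALSE) {
  stopifnot(inherits(m, "manifold"), inherits(noise, "noise_model"))
  X <- as_point_matrix(X)
  N <- nrow(X)
  if (N != noise$n_obs) noise <- noise_model(noise$sigma, N)
  cbar <- colMeans(X)
  ss <- sum((X[, 1] - cbar[1])^2 + (X[, 2] - cbar[2])^2)
  const <- -N * log(2 * pi * noise$sigma^2) - ss / (2 * noise$sigma^2)
  fc <- fia_components(m, matrix(cbar, 1L), noise)
  exact <- if (with_exact) {
    as.numeric(exact_log_marginal(m, X, noise))
  } else NA_real_
  structure(list(
    log_max_likelihood = const + fc$rel_log_max_lik[1],
    term_dimensionality = fc$term_dimensionality[1],
    term_boundary = fc$term_boundary[1],
    term_volume = fc$term_volume[1],
    term_robustness = fc$term_robustness[1],
    fia_log_evidence = const + fc$rel_fia[1],
    exact_log_evidence = exact,
    s_hat = fc$s_hat[1], on_boundary = fc$on_boundary[1],
    grad_norm = fc$grad_norm[1],
    g_at_shat = fc$g[1], h_at_shat = fc$h[1],
    degenerate = fc$degenerate[1]),
    class = "evidence_breakdown")
}

#' @export
print.evidence_breakdown <- function(x, ...) {
  cat("<evidence breakdown>\n")
  cat(sprintf("  log max likelihood : %10.4f\n", x$log_max_likelihood))
  cat(sprintf("  dimensionality     : %10.4f\n", x$term_dimensionality))
  cat(sprintf("  boundary           : %10.4f\n", x$term_boundary))
  cat(sprintf("  volume             : %10.4f\n", x$term_volume))
  cat(sprintf("  robustness         : %10.4f\n", x$term_robustness))
  cat(sprintf("  FIA log evidence   : %10.4f\n", x$fia_log_evidence))
  if (!is.na(x$exact_log_evidence))
    cat(sprintf("  exact log evidence : %10.4f\n", x$exact_log_evidence))
  cat(sprintf("  s_hat = %.4f%s%s\n", x$s_hat,
              if (x$on_boundary) " (boundary)" else "",
              if (x$degenerate) " [degenerate h <= 0]" else ""))
  invisible(x)
}

#' Posterior probability of choosing the second model
#'
#' Probability that model 2 of a pair is the source, under equal model
#' priors, from the difference of log evidences computed by the requested
#' method: exact quadrature, the FIA, or maximum likelihood only.
#'
#' @param pair list of two manifolds (model 1, model 2).
#' @param X n x 2 matrix of observations.
#' @param noise a [noise_model()].
#' @param method one of `"exact"`, `"fia"`, `"ml_only"`.
#' @return `P(model 2 | X)` in `[0, 1]` (NA if a FIA breakdown is
#'   degenerate).
#' @export
posterior_choice_prob <- function(pair, X, noise,
                                  method = c("exact", "fia", "ml_only")) {
  method <- match.arg(method)
  stopifnot(length(pair) == 2L, inherits(pair[[1]], "manifold"),
            inherits(pair[[2]], "manifold"))
  X <- as_point_matrix(X)
  noise <- noise_model(noise$sigma, nrow(X))
  C <- matrix(colMeans(X), 1L)
  delta <- evidence_delta(pair, C, noise, method)
  stats::plogis(delta)
}

#' Per-trial evidence table
#'
#' Evaluates the FIA breakdown (and optionally the exact marginal) of both
#' models of a trial set, one row per (trial, model), in a flat
#' delimited-text-friendly layout. Values are relative to the trial's
#' model-independent likelihood constant, which cancels in every
#' between-model comparison.
#'
#' @param trial_set a [sample_trials()] result.
#' @param with_exact also compute the exact log marginal per row.
#' @return A data.frame with columns trial_id, model (1 = down, 2 = up),
#'   the five evidence components, fia_log_evidence, exact_log_evidence
#'   (if requested), s_hat, on_boundary, grad_norm, g_at_shat, h_at_shat,
#'   degenerate.
#' @export
evidence_table <- function(trial_set, with_exact = FALSE) {
  stopifnot(inherits(trial_set, "trial_set"))
  variant <- trial_set$variant
  out <- list()
  for (o in 0:1) {
    idx <- which(trial_set$trials$swap == o)
    if (!length(idx)) next
    pair <- variant_pair(variant, o)
    C <- trial_set$centroids[idx, , drop = FALSE]
    for (mi in 1:2) {
      m <- if (mi == 2L) pair$up else pair$down
      fc <- fia_components(m, C, variant$noise)
      row <- data.frame(
        trial_id = trial_set$trials$trial_id[idx], model = mi,
        log_max_likelihood = fc$rel_log_max_lik,
        term_dimensionality = fc$term_dimensionality,
        term_boundary = fc$term_boundary,
        term_volume = fc$term_volume,
        term_robustness = fc$term_robustness,
        fia_log_evidence = fc$rel_fia,
        s_hat = fc$s_hat, on_boundary = fc$on_boundary,
        grad_norm = fc$grad_norm, g_at_shat = fc$g,
        h_at_shat = fc$h, degenerate = fc$degenerate)
      if (with_exact)
        row$exact_log_evidence <- exact_rel_marginal(m, C, variant$noise)
      out[[length(out) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$trial_id, tab$model), ]
  rownames(tab) <- NULL
  tab
}

# delta = (log evidence of model 2) - (log evidence of model 1), vectorized
# over centroids; the data-dependent constant cancels.
#' @noRd
evidence_delta <- function(pair, C, noise, method) {
  score <- function(m) {
    switch(method,
      exact = exact_rel_marginal(m, C, noise),
      fia = fia_components(m, C, noise)$rel_fia,
      ml_only = {
        pr <- ml_project_many(m, C)
        -noise$n_obs * pr$distance^2 / (2 * noise$sigma^2)
      })
  }
  score(pair[[2]]) - score(pair[[1]])
}
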