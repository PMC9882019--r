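# Model manifolds: 0- and 1-parameter families of 2D Gaussian centers.
#
# Every 1D manifold is parameterized by arc length s on [0, Lambda], so the
# embedding is unit speed, the expected Fisher information per datum is the
# constant 1/sigma^2, and the Jeffreys prior over s is uniform.

#' Point manifold (zero-dimensional model)
#'
#' A candidate explanation consisting of a single possible 2D Gaussian
#' center. It has no free parameters (`d = 0`), so its evidence carries no
#' complexity penalty.
#'
#' @param location numeric length-2, the center's coordinates in the data
#'   plane (y increases upward).
#' @param label optional role tag, e.g. `"up"` or `"down"`.
#' @return An object of class `c("point_manifold", "manifold")`.
#' @examples
#' m <- manifold_point(c(0, 0.5))
#' embed_manifold(m, 0)
#' @export
manifold_point <- function(location, label = NULL) {
  location <- as.numeric(location)
  stopifnot(length(location) == 2L, all(is.finite(location)))
  structure(
    list(kind = "point", location = location, d = 0L, length = 0,
         label = label),
    class = c("point_manifold", "manifold"))
}

#' Segment manifold (one-dimensional, straight)
#'
#' Gaussian centers anywhere on the straight segment between two endpoints,
#' arc-length parameterized from `from` (s = 0) to `to` (s = Lambda).
#'
#' @param from,to numeric length-2 endpoints; must be distinct.
#' @inheritParams manifold_point
#' @return An object of class `c("segment_manifold", "manifold")`.
#' @export
manifold_segment <- function(from, to, label = NULL) {
  from <- as.numeric(from); to <- as.numeric(to)
  stopifnot(length(from) == 2L, length(to) == 2L,
            all(is.finite(c(from, to))))
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("segment endpoints must be distinct", call. = FALSE)
  structure(
    list(kind = "segment", from = from, to = to,
         unit = (to - from) / len, d = 1L, length = len, label = label),
    class = c("segment_manifold", "manifold"))
}

#' Arc manifold (one-dimensional, constant curvature)
#'
#' Gaussian centers on a circular arc. The arc starts at polar angle
#' `theta0` on the circle of radius `radius` around `center` and spans
#' `span` radians; `orientation = +1` traverses it counter-clockwise as the
#' arc-length coordinate s grows, `-1` clockwise. The parameterization is
#' unit speed, so `Lambda = radius * span`.
#'
#' @param center numeric length-2, center of curvature.
#' @param radius positive radius (data-plane units).
#' @param theta0 start angle in radians.
#' @param span angular span in radians, in (0, 2*pi].
#' @param orientation +1 (counter-clockwise) or -1 (clockwise).
#' @inheritParams manifold_point
#' @return An object of class `c("arc_manifold", "manifold")`.
#' @export
manifold_arc <- function(center, radius, theta0, span, orientation = 1,
                         label = NULL) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2L, all(is.finite(center)),
            is.finite(radius), is.finite(theta0), is.finite(span))
  if (radius <= 0) stop("arc radius must be positive", call. = FALSE)
  if (span <= 0 || span > 2 * pi)
    stop("arc span must lie in (0, 2*pi]", call. = FALSE)
  if (!orientation %in% c(-1, 1))
    stop("orientation must be +1 or -1", call. = FALSE)
  structure(
    list(kind = "arc", center = center, radius = radius, theta0 = theta0,
         span = span, orientation = orientation, d = 1L,
         length = radius * span, label = label),
    class = c("arc_manifold", "manifold"))
}

#' @export
print.manifold <- function(x, ...) {
  geom <- switch(x$kind,
    point = sprintf("at (%.3g, %.3g)", x$location[1], x$location[2]),
    segment = sprintf("(%.3g, %.3g) -- (%.3g, %.3g)",
                      x$from[1], x$from[2], x$to[1], x$to[2]),
    arc = sprintf("center (%.3g, %.3g), r = %.3g, span = %.3g rad",
                  x$center[1], x$center[2], x$radius, x$span))
  cat(sprintf("<%s manifold> %s  [d = %d, Lambda = %.4g%s]\n",
              x$kind, geom, x$d, x$length,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Manifold length (Jeffreys parameter domain)
#'
#' Returns Lambda, the upper end of the arc-length domain `[0, Lambda]`
#' (0 for point manifolds).
#' @param m a manifold.
#' @export
manifold_length <- function(m) {
  stopifnot(inherits(m, "manifold"))
  m$length
}

#' Embed an arc-length coordinate into the data plane
#'
#' Maps the intrinsic coordinate s to the Gaussian-center location mu(s).
#' The parameterization is unit speed: |d mu / ds| = 1 for d = 1 manifolds.
#'
#' @param m a manifold.
#' @param s numeric vector of arc-length coordinates in `[0, Lambda]`
#'   (must be 0 for point manifolds).
#' @return An `length(s) x 2` matrix of 2D locations.
#' @export
embed_manifold <- function(m, s) {
  stopifnot(inherits(m, "manifold"))
  s <- as.numeric(s)
  tol <- 1e-9 * max(1, m$length)
  if (any(s < -tol | s > m$length + tol))
    stop("arc-length coordinate outside [0, Lambda]", call. = FALSE)
  s <- pmin(pmax(s, 0), m$length)
  switch(m$kind,
    point = matrix(m$location, nrow = length(s), ncol = 2, byrow = TRUE),
    segment = cbind(m$from[1] + s * m$unit[1], m$from[2] + s * m$unit[2]),
    arc = {
      th <- m$theta0 + m$orientation * s / m$radius
      cbind(m$center[1] + m$radius * cos(th),
            m$center[2] + m$radius * sin(th))
    })
}

# Tangent mu'(s) (unit vector) at s; internal.
#' @noRd
manifold_tangent <- function(m, s) {
  switch(m$kind,
    point = matrix(0, length(s), 2),
    segment = matrix(m$unit, length(s), 2, byrow = TRUE),
    arc = {
      th <- m$theta0 + m$orientation * s / m$radius
      cbind(-m$orientation * sin(th), m$orientation * cos(th))
    })
}

# Second derivative mu''(s) = kappa * n(s); internal.
#' @noRd
manifold_second_deriv <- function(m, s) {
  switch(m$kind,
    point = matrix(0, length(s), 2),
    segment = matrix(0, length(s), 2),
    arc = {
      th <- m$theta0 + m$orientation * s / m$radius
      cbind(-cos(th), -sin(th)) / m$radius
    })
}

#' Signed curvature of the embedding
#'
#' 0 for segments; `orientation / radius` for arcs (positive when the
#' center of curvature lies to the left of the direction of travel, the
#' standard Frenet convention for counter-clockwise arcs). Errors for
#' point manifolds, which have no curve.
#'
#' @param m a manifold with `d = 1`.
#' @param s arc-length coordinate(s); curvature is constant so `s` only
#'   needs to be in-domain.
#' @export
manifold_curvature <- function(m, s = 0) {
  stopifnot(inherits(m, "manifold"))
  if (m$d == 0L)
    stop("curvature is undefined for 0-dimensional manifolds", call. = FALSE)
  s <- as.numeric(s)
  if (any(s < 0 | s > m$length))
    stop("arc-length coordinate outside [0, Lambda]", call. = FALSE)
  k <- switch(m$kind, segment = 0, arc = m$orientation / m$radius)
  rep(k, length(s))
}

#' Maximum-likelihood projection onto a manifold
#'
#' For isotropic Gaussian noise the maximum-likelihood parameter is the
#' arc-length coordinate whose embedding is closest to the data centroid,
#' clamped to `[0, Lambda]`. Arcs are projected in closed form through the
#' polar angle of the centroid around the center of curvature; when the
#' angle falls outside the arc's span the nearer endpoint (by circular
#' angular distance) is chosen, with exact ties broken toward s = 0.
#'
#' @param m a manifold.
#' @param centroid numeric length-2, the data centroid.
#' @return A list with elements
#'   \describe{
#'     \item{s_hat}{clamped maximizer in `[0, Lambda]`;}
#'     \item{on_boundary}{TRUE iff `s_hat` is 0 or Lambda for d = 1
#'       manifolds (always FALSE for points);}
#'     \item{s_star}{the unconstrained stationary coordinate on the curve's
#'       natural extension (outside `[0, Lambda]` when clamped), used by the
#'       boundary term of the evidence expansion;}
#'     \item{distance}{Euclidean distance from the centroid to
#'       `embed_manifold(m, s_hat)`.}
#'   }
#' @export
ml_project <- function(m, centroid) {
  stopifnot(inherits(m, "manifold"))
  centroid <- as.numeric(centroid)
  stopifnot(length(centroid) == 2L, all(is.finite(centroid)))
  p <- ml_project_many(m, matrix(centroid, 1L))
  list(s_hat = p$s_hat[1], on_boundary = p$on_boundary[1],
       s_star = p$s_star[1], distance = p$distance[1])
}

# Vectorized projection over an n x 2 centroid matrix; internal fast path.
#' @noRd
ml_project_many <- function(m, C) {
  n <- nrow(C)
  if (m$kind == "point") {
    d <- sqrt((C[, 1] - m$location[1])^2 + (C[, 2] - m$location[2])^2)
    return(list(s_hat = numeric(n), on_boundary = rep(FALSE, n),
                s_star = numeric(n), distance = d))
  }
  if (m$kind == "segment") {
    t_star <- (C[, 1] - m$from[1]) * m$unit[1] +
              (C[, 2] - m$from[2]) * m$unit[2]
    s_hat <- pmin(pmax(t_star, 0), m$length)
    mu <- cbind(m$from[1] + s_hat * m$unit[1], m$from[2] + s_hat * m$unit[2])
    d <- sqrt(rowSums((C - mu)^2))
    return(list(s_hat = s_hat,
                on_boundary = s_hat <= 0 | s_hat >= m$length,
                s_star = t_star, distance = d))
  }
  # arc: polar angle of the centroid around the center of curvature
  vx <- C[, 1] - m$center[1]; vy <- C[, 2] - m$center[2]
  R <- sqrt(vx^2 + vy^2)
  phi <- atan2(vy, vx)
  # angular offset from the start of the arc, measured along s
  delta <- (m$orientation * (phi - m$theta0)) %% (2 * pi)
  s_raw <- m$radius * delta
  inside <- s_raw <= m$length
  # outside the span: nearer endpoint by circular angular distance,
  # exact ties toward s = 0
  past_end <- delta - m$span          # > 0 when outside
  to_start <- 2 * pi - delta
  clamp_hi <- !inside & (past_end < to_start)
  s_hat <- ifelse(inside, s_raw, ifelse(clamp_hi, m$length, 0))
  # unconstrained coordinate on the full circle, unwrapped toward the domain
  s_star <- ifelse(inside, s_raw,
                   ifelse(clamp_hi, s_raw, s_raw - 2 * pi * m$radius))
  # degenerate centroid at the center of curvature: all s equivalent
  degen <- R < 1e-12
  s_hat[degen] <- 0; s_star[degen] <- 0
  th <- m$theta0 + m$orientation * s_hat / m$radius
  mu <- cbind(m$center[1] + m$radius * cos(th),
              m$center[2] + m$radius * sin(th))
  d <- sqrt(rowSums((C - mu)^2))
  list(s_hat = s_hat,
       on_boundary = s_hat <= 0 | s_hat >= m$length,
       s_star = s_star, distance = d)
}

#' Noise model for a trial
#'
#' The generative observation process: `n_obs` iid draws from an isotropic
#' 2D Gaussian with standard deviation `sigma` centered on a point of one
#' of the manifolds.
#'
#' @param sigma positive standard deviation (data-plane units).
#' @param n_obs number of observations per trial (N; default 10).
#' @export
noise_model <- function(sigma, n_obs = 10L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  n_obs <- as.integer(n_obs)
  if (is.na(n_obs) || n_obs < 1L) stop("n_obs must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, n_obs = n_obs), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise model> sigma = %.4g, N = %d per trial\n",
              x$sigma, x$n_obs))
  invisible(x)
}

#' Expected Fisher information (metric g)
#'
#' For a unit-speed curve of Gaussian centers the expected per-datum Fisher
#' information is the constant `1 / sigma^2`, independent of both the
#' coordinate and the curvature. Point manifolds return 1, the determinant
#' convention for a 0-dimensional metric.
#'
#' @param m a manifold.
#' @param s arc-length coordinate(s) (unused beyond a domain check; g is
#'   constant under the arc-length parameterization).
#' @param noise a [noise_model()].
#' @export
expected_fisher <- function(m, s = 0, noise) {
  stopifnot(inherits(m, "manifold"), inherits(noise, "noise_model"))
  s <- as.numeric(s)
  if (any(s < 0 | s > m$length))
    stop("arc-length coordinate outside [0, Lambda]", call. = FALSE)
  if (m$d == 0L) return(rep(1, length(s)))
  rep(1 / noise$sigma^2, length(s))
}

#' Observed Fisher information (metric h)
#'
#' Negative second derivative of the per-datum log-likelihood in the
#' arc-length coordinate: `h(s) = (1 - (cbar - mu(s)) . mu''(s)) / sigma^2`,
#' where `cbar` is the data centroid. For straight segments `h = g`
#' exactly; for arcs h depends on where the centroid sits relative to the
#' center of curvature (`h = R / (r * sigma^2)` at an aligned interior
#' optimum, with R the centroid's distance from the center) and can reach 0
#' or go negative, signalling a locally flat or concave likelihood.
#'
#' @param m a manifold with `d = 1`.
#' @param X n x 2 matrix of observations (only the centroid matters).
#' @param s arc-length coordinate(s) at which to evaluate.
#' @param noise a [noise_model()] (supplies sigma; the per-datum convention
#'   means `X`'s row count does not rescale h).
#' @export
observed_fisher <- function(m, X, s, noise) {
  stopifnot(inherits(m, "manifold"), inherits(noise, "noise_model"))
  if (m$d == 0L)
    stop("observed information is undefined for point manifolds",
         call. = FALSE)
  X <- as_point_matrix(X)
  cbar <- colMeans(X)
  observed_fisher_centroid(m, matrix(cbar, 1L), s, noise)
}

# Vectorized over centroids (n x 2) with one s per row (recycled).
#' @noRd
observed_fisher_centroid <- function(m, C, s, noise) {
  s <- rep_len(as.numeric(s), nrow(C))
  if (any(s < 0 | s > m$length))
    stop("arc-length coordinate outside [0, Lambda]", call. = FALSE)
  mu <- embed_manifold(m, s)
  mpp <- manifold_second_deriv(m, s)
  resid_dot <- (C[, 1] - mu[, 1]) * mpp[, 1] + (C[, 2] - mu[, 2]) * mpp[, 2]
  (1 - resid_dot) / noise$sigma^2
}

#' Jeffreys prior density over the arc-length coordinate
#'
#' The reparameterization-invariant prior is proportional to `sqrt(g)`;
#' under arc-length parameterization it is the uniform density
#' `1 / Lambda` on `[0, Lambda]` (0 outside). For point manifolds the
#' prior is a unit point mass at s = 0, returned as a `"point_mass"`
#' object.
#'
#' @param m a manifold.
#' @param s coordinate(s) at which to evaluate the density.
#' @export
jeffreys_density <- function(m, s = NULL) {
  stopifnot(inherits(m, "manifold"))
  if (m$d == 0L)
    return(structure(list(at = 0, mass = 1), class = "point_mass"))
  if (is.null(s)) s <- m$length / 2
  s <- as.numeric(s)
  ifelse(s >= 0 & s <= m$length, 1 / m$length, 0)
}

#' Sample from the Jeffreys prior of a manifold
#'
#' Uniform over arc length for d = 1; the fixed point s = 0 for d = 0.
#' @param m a manifold.
#' @param n number of draws.
#' @export
jeffreys_sample <- function(m, n) {
  stopifnot(inherits(m, "manifold"))
  if (m$d == 0L) return(numeric(n))
  stats::runif(n, 0, m$length)
}

# Reflect a manifold across the x-axis (y -> -y); used to mirror the
# up/down placement of the two shapes of a task pair.
#' @noRd
reflect_y <- function(m) {
  switch(m$kind,
    point = manifold_point(c(m$location[1], -m$location[2]), label = m$label),
    segment = manifold_segment(c(m$from[1], -m$from[2]),
                               c(m$to[1], -m$to[2]), label = m$label),
    arc = manifold_arc(c(m$center[1], -m$center[2]), m$radius,
                       -m$theta0, m$span, orientation = -m$orientation,
                       label = m$label))
}

# Serializable geometry description (used by configs and manifests).
#' @noRd
manifold_to_list <- function(m) {
  switch(m$kind,
    point = list(kind = "point", location = m$location, label = m$label),
    segment = list(kind = "segment", from = m$from, to = m$to,
                   label = m$label),
    arc = list(kind = "arc", center = m$center, radius = m$radius,
               theta0 = m$theta0, span = m$span,
               orientation = m$orientation, label = m$label))
}

#' @noRd
manifold_from_list <- function(x) {
  switch(x$kind,
    point = manifold_point(unlist(x$location), label = x$label),
    segment = manifold_segment(unlist(x$from), unlist(x$to),
                               label = x$label),
    arc = manifold_arc(unlist(x$center), x$radius, x$theta0, x$span,
                       orientation = x$orientation %||% 1, label = x$label),
    stop("unknown manifold kind: ", x$kind, call. = FALSE))
}
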