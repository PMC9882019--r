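# Geometry of the model manifolds: embedding, projection, metrics, prior.

test_that("embedding hits the stated landmarks", {
  seg <- manifold_segment(c(-0.5, 1), c(0.5, 1))
  expect_equal(drop(embed_manifold(seg, 0)), c(-0.5, 1))
  expect_equal(drop(embed_manifold(seg, seg$length)), c(0.5, 1))
  pt <- manifold_point(c(0, 0))
  expect_equal(drop(embed_manifold(pt, 0)), c(0, 0))
  arc <- manifold_arc(c(0, 0), 1, 0, 2)
  expect_equal(drop(embed_manifold(arc, pi / 2)), c(0, 1),
               tolerance = 1e-12)
  expect_error(embed_manifold(seg, -0.1), "outside")
  expect_error(embed_manifold(seg, seg$length + 0.1), "outside")
})

test_that("all d = 1 embeddings are unit speed (finite differences)", {
  set.seed(1)
  for (m in list(test_segment(), test_arc(),
                 manifold_arc(c(2, 1), 0.3, -1, 2 * pi))) {
    eps <- 1e-6 * max(1, m$length)
    s <- runif(100, eps, m$length - eps)
    speed <- sqrt(rowSums((embed_manifold(m, s + eps) -
                           embed_manifold(m, s - eps))^2)) / (2 * eps)
    expect_equal(speed, rep(1, 100), tolerance = 1e-7)
  }
})

test_that("ml_project clamps and matches a brute-force grid oracle", {
  seg <- manifold_segment(c(-0.5, 1), c(0.5, 1))
  p <- ml_project(seg, c(2, 1))
  expect_equal(p$s_hat, seg$length)
  expect_true(p$on_boundary)
  expect_equal(ml_project(manifold_point(c(0, 0)), c(3, -2))$s_hat, 0)
  expect_false(ml_project(manifold_point(c(0, 0)), c(3, -2))$on_boundary)

  set.seed(42)
  s_grid <- seq(0, 1, length.out = 1e5)
  for (m in list(test_arc(), test_segment(),
                 manifold_arc(c(0, 0), 0.5, -3.5707963, 4))) {
    grid_pts <- embed_manifold(m, s_grid * m$length)
    for (i in 1:20) {
      cc <- runif(2, -2, 2)
      p <- ml_project(m, cc)
      d_grid <- min(sqrt((grid_pts[, 1] - cc[1])^2 +
                         (grid_pts[, 2] - cc[2])^2))
      expect_lte(p$distance, d_grid + m$length / 1e5)
    }
  }
})

test_that("expected Fisher information is 1/sigma^2, flat, and curvature-free", {
  seg <- test_segment()
  expect_equal(expected_fisher(seg, 0.5, noise_model(1)), 1)
  expect_equal(expected_fisher(seg, 0.5, noise_model(0.5)),
               4 * expected_fisher(seg, 0.5, noise_model(1)))
  arc <- test_arc()
  s <- seq(0.1, arc$length - 0.1, length.out = 7)
  expect_equal(expected_fisher(arc, s, noise_model(0.7)),
               rep(1 / 0.49, 7))
  # Monte-Carlo: the observed information averaged over data sampled at a
  # fixed s converges to g, also on curved manifolds
  set.seed(7)
  nm <- noise_model(0.5, 10)
  s0 <- 1.1
  mu <- drop(embed_manifold(arc, s0))
  h_bar <- mean(replicate(4000, {
    X <- cbind(rnorm(10, mu[1], 0.5), rnorm(10, mu[2], 0.5))
    observed_fisher(arc, X, s0, nm)
  }))
  g <- expected_fisher(arc, s0, nm)
  expect_equal(h_bar, g, tolerance = 0.03)
})

test_that("observed Fisher information: h = g on segments, 0 at the arc's focus, matches finite differences", {
  nm <- noise_model(0.8, 10)
  seg <- test_segment()
  set.seed(11)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(observed_fisher(seg, X, 0.7, nm),
               expected_fisher(seg, 0.7, nm))
  arc <- test_arc()
  Xc <- matrix(rep(arc$center, 5), ncol = 2, byrow = TRUE)
  expect_equal(observed_fisher(arc, Xc, 1, nm), 0, tolerance = 1e-12)

  for (i in 1:100) {
    m <- if (i %% 2) test_arc() else
      manifold_arc(runif(2, -1, 1), runif(1, 0.3, 2), runif(1, -3, 3),
                   runif(1, 0.5, 2 * pi))
    s0 <- runif(1, 0.1, m$length - 0.1)
    X <- matrix(runif(8, -2, 2), 4, 2)
    h_an <- observed_fisher(m, X, s0, nm)
    # 5-point central stencil: O(eps^4) truncation with benign rounding
    eps <- min(1e-3 * max(1, m$length), (m$length - s0) / 2, s0 / 2)
    ll <- function(s) log_likelihood(m, s, X, nm)
    h_fd <- -(-ll(s0 - 2 * eps) + 16 * ll(s0 - eps) - 30 * ll(s0) +
                16 * ll(s0 + eps) - ll(s0 + 2 * eps)) / (12 * eps^2) / 4
    expect_lt(abs(h_an - h_fd), 1e-6 * max(1, abs(h_an)))
  }
})

test_that("Jeffreys prior is uniform 1/Lambda, normalized, invariant in form", {
  expect_equal(jeffreys_density(manifold_segment(c(0, 0), c(1, 0)), 0.3),
               1)
  expect_equal(jeffreys_density(manifold_arc(c(0, 0), 2, 0, pi), 1),
               1 / (2 * pi))
  set.seed(3)
  for (i in 1:20) {
    m <- if (i %% 2) {
      manifold_segment(runif(2, -2, 2), runif(2, -2, 2) + c(3, 0))
    } else {
      manifold_arc(runif(2, -1, 1), runif(1, 0.2, 3), runif(1, -3, 3),
                   runif(1, 0.3, 2 * pi))
    }
    s <- seq(0, m$length, length.out = 2001)
    integral <- sum(jeffreys_density(m, s)) * m$length / 2001
    expect_equal(integral, 1, tolerance = 1e-2)
    expect_true(all(jeffreys_density(m, s) >= 0))
    gl <- pracma::gaussLegendre(64, 0, m$length)
    expect_equal(sum(gl$w * jeffreys_density(m, gl$x)), 1,
                 tolerance = 1e-8)
  }
  expect_s3_class(jeffreys_density(manifold_point(c(1, 1))),
                  "point_mass")
})

test_that("curvature is 0 for segments, 1/radius for arcs, and matches the embedding", {
  expect_equal(manifold_curvature(test_segment(), 0.4), 0)
  expect_equal(abs(manifold_curvature(manifold_arc(c(0, 0), 2, 0, pi), 1)),
               0.5)
  expect_error(manifold_curvature(manifold_point(c(0, 0))), "undefined")
  set.seed(5)
  for (i in 1:50) {
    r <- runif(1, 0.2, 3)
    m <- manifold_arc(runif(2, -1, 1), r, runif(1, -3, 3),
                      runif(1, 0.5, 2 * pi),
                      orientation = sample(c(-1, 1), 1))
    s0 <- runif(1, 0.1, m$length - 0.1)
    eps <- 1e-5 * max(1, m$length)
    # |mu''| from central differences equals |kappa| for unit-speed curves
    mpp <- (embed_manifold(m, s0 + eps) - 2 * embed_manifold(m, s0) +
            embed_manifold(m, s0 - eps)) / eps^2
    expect_equal(sqrt(sum(mpp^2)), abs(manifold_curvature(m, s0)),
                 tolerance = 1e-3)
  }
})

test_that("manifold constructors reject invalid geometry", {
  expect_error(manifold_segment(c(1, 1), c(1, 1)), "distinct")
  expect_error(manifold_arc(c(0, 0), -1, 0, 1), "positive")
  expect_error(manifold_arc(c(0, 0), 1, 0, 7), "span")
  expect_error(noise_model(0), "positive")
  expect_error(noise_model(1, 0), "n_obs")
})

test_that("serialization round-trips geometry", {
  for (m in list(manifold_point(c(1, -1)), test_segment(), test_arc())) {
    m2 <- occamfia:::manifold_from_list(occamfia:::manifold_to_list(m))
    expect_equal(embed_manifold(m2, m2$length / 2),
                 embed_manifold(m, m$length / 2))
  }
})
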