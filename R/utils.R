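# Internal helpers: seeded sub-streams, stable log-sums, small numerics.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(pnorm(hi) - pnorm(lo)) for hi > lo, stable in both tails
#' @noRd
log_pnorm_diff <- function(hi, lo) {
  # work on the side where mass is small: P(lo < Z < hi) = P(-hi < Z < -lo)
  flip <- (hi + lo) > 0
  h <- ifelse(flip, -lo, hi)
  l <- ifelse(flip, -hi, lo)
  lh <- stats::pnorm(h, log.p = TRUE)
  ll <- stats::pnorm(l, log.p = TRUE)
  lh + log1p(-exp(pmin(ll - lh, 0)))
}

# Deterministic 31-bit sub-seed derived from a master seed and a string tag.
# FNV-1a style mix; keeps every derived seed in [1, 2^31 - 2].
#' @noRd
derive_seed <- function(master, tag, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- (as.numeric(master) %% 2147483647) + 1
  bytes <- c(utf8ToInt(as.character(tag)), as.numeric(index) %% 65536)
  for (b in bytes) {
    h <- (h * 31 + b + 17) %% 2147483629
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr with a locally-set RNG state, restoring the caller's state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Tiny FNV-1a hash of a character scalar, hex string; used for manifests.
#' @noRd
fnv1a_hex <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_point_matrix <- function(X) {
  if (is.null(dim(X))) {
    if (length(X) != 2L) stop("data points must be 2D", call. = FALSE)
    X <- matrix(X, nrow = 1L)
  }
  X <- as.matrix(X)
  if (ncol(X) != 2L) stop("data must be an n x 2 matrix of 2D points", call. = FALSE)
  if (nrow(X) < 1L) stop("data set is empty", call. = FALSE)
  storage.mode(X) <- "double"
  X
}
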