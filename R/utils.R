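# Internal utilities: seeded RNG scoping, seed derivation, small numerics.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic operations
# route through this so that results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.finite(seed)) stop("seed must be a finite integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Counter-based scheme (multiplicative congruential step modulo 2^31 - 1) so
#' that each pipeline stage gets a reproducible seed that does not depend on
#' the execution order of other stages.
#'
#' @param seed Global integer seed.
#' @param index Stage counter (1, 2, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(index)) {
    s <- (s * 48271 + 11213) %% m
  }
  as.integer(max(1, s))
}

# Round half up to nearest integer (the projection convention; R's round()
# uses banker's rounding which would not reproduce the printed funnel counts).
round_half_up <- function(x) floor(x + 0.5)

# Multivariate normal draw via Cholesky (n draws, mean mu, covariance Sigma).
rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  sweep(z, 2, mu, "+")
}

# Inverse-Wishart draw: X ~ IW(df, S) <=> X^{-1} ~ Wishart(df, S^{-1}).
riwish <- function(df, S) {
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

# Cheap stable content digest for manifests (no external digest package):
# chunked polynomial rolling hash over the serialized object bytes, reported
# as hex. Vectorised; all arithmetic stays below 2^53 so doubles are exact.
content_digest <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  v <- as.numeric(bytes)
  p <- 2147483647           # 2^31 - 1
  w <- numeric(256); w[1] <- 1
  for (i in 2:256) w[i] <- (w[i - 1] * 48271) %% p
  h <- 0
  n <- length(v)
  idx <- seq(1, n, by = 256)
  for (s in idx) {
    chunk <- v[s:min(n, s + 255)]
    ch <- sum((chunk * w[seq_along(chunk)]) %% p) %% p
    h <- (h * 69621 + ch) %% p
  }
  sprintf("%08x", as.integer(h))
}

assert_prob <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(if (allow_one) x > 1 else x >= 1)) {
    stop(sprintf("`%s` must be in [0,%s]", name, if (allow_one) "1" else "1)"),
         call. = FALSE)
  }
  invisible(x)
}
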