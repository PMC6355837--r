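# Shared numeric helpers and validation utilities.

#' Logit and inverse-logit transforms
#'
#' Methylation beta values live on \[0,1\]; latent effects in the synthetic
#' model act on the logit scale. `inv_logit` is the standard expit.
#'
#' @param p probabilities in (0,1)
#' @param x real values
#' @return transformed numeric vector
#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clip beta values away from the boundary
#'
#' Degenerate logits at exactly 0 or 1 are avoided by clipping to
#' \[eps, 1 - eps\].
#'
#' @param b numeric beta values
#' @param eps boundary margin (default 1e-6)
#' @return clipped values
#' @keywords internal
clip_beta <- function(b, eps = 1e-6) pmin(pmax(b, eps), 1 - eps)

# Deterministic substream seed derivation. Mixes a root seed with integer
# stream keys using a small-multiplier LCG so products stay exactly
# representable in doubles; result always in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  keys <- c(...)
  m <- 2147483629
  s <- as.double(seed %% m)
  for (k in keys) {
    s <- (s * 7919 + as.double(k) + 104729) %% m
  }
  as.integer(s + 1)
}

# stopifnot-style validation with a named-field error message.
assert_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

# Draw one Dirichlet vector per row of n draws given a concentration vector.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # all-zero rows can occur for very small concentrations; fall back to the
  # largest-concentration vertex
  rs <- rowSums(g)
  bad <- rs == 0
  if (any(bad)) {
    g[bad, which.max(alpha)] <- 1
    rs <- rowSums(g)
  }
  g / rs
}
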