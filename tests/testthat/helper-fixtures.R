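# Shared fixtures and small oracles used across test files.

# fast, battery-grade options for tests that fit models
quick_opts <- function(...) fit_options(tol_loglik = 1e-4, ...)

# independently coded generalized partial credit model:
# P(k | theta) prop. exp(sum_{v<=k} a (theta - b_v)), k = 0..K-1 (empty sum
# for k = 0). Written from the standard GPCM formula, not via the package.
gpcm_prob <- function(theta, a, b) {
  K <- length(b) + 1L
  eta <- c(0, cumsum(a * (theta - b)))
  p <- exp(eta - max(eta))
  p / sum(p)
}

# brute-force marginal log-likelihood for a unidimensional model by
# trapezoid-rule integration over theta
trapezoid_loglik <- function(Y, items, scoring, from = -8, to = 8, n = 2001) {
  theta <- seq(from, to, length.out = n)
  h <- theta[2] - theta[1]
  w <- dnorm(theta) * h * c(0.5, rep(1, n - 2L), 0.5)
  total <- 0
  for (i in seq_len(nrow(Y))) {
    lik <- rep(1, n)
    for (j in seq_len(ncol(Y))) {
      y <- Y[i, j]
      if (is.na(y)) next
      pj <- vapply(theta, function(th)
        category_probabilities(th, items[[j]], scoring)[y + 1L], numeric(1))
      lik <- lik * pj
    }
    total <- total + log(sum(w * lik))
  }
  total
}

# a small deterministic ers_mrs item for probability tests
example_item <- function(slopes = c(1, 1), intercepts = c(-2, -1, 0, -1, -2)) {
  item_parameters(slopes, intercepts)
}
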