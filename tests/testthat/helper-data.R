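# Shared fixture builders (all data generated in code, fixed seeds).

# Well-conditioned linear map: y = X beta + N(0, noise_sd)
linear_map_data <- function(n = 100, p = 7, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- runif(p, -1, 1)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = noise_sd)
  list(X = X, y = y, beta = beta, noise_sd = noise_sd)
}

# Exactly two informative latent directions feeding the response through
# two distinct-variance components (so classical PLS is Krylov-exact at
# k = 2); the small sensor noise keeps X full rank.
two_latent_data <- function(n = 80, seed = 1, ynoise = 0.5, xnoise = 0.1) {
  set.seed(seed)
  L <- qr.Q(qr(matrix(rnorm(49), 7)))[, 1:2]
  T2 <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 2))
  X <- T2 %*% t(L) * 3 + matrix(rnorm(n * 7, sd = xnoise), n)
  y <- T2[, 1] + 0.8 * T2[, 2] + rnorm(n, sd = ynoise)
  etongue_dataset(X, y)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
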