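# small fixtures built in code

# two-condition Gaussian matrix with a known number of shifted genes
toy_two_class <- function(G = 100, n1 = 5, n2 = 5, n_de = 10, effect = 2,
                          sigma2 = 0.3, seed = 101) {
  set.seed(seed)
  mu <- matrix(runif(G, 3, 5), G, 2)
  if (n_de > 0) mu[seq_len(n_de), 2] <- mu[seq_len(n_de), 1] + effect
  labels <- rep(c("a", "b"), c(n1, n2))
  x <- mu[, rep(1:2, c(n1, n2))] +
    matrix(rnorm(G * (n1 + n2), 0, sqrt(sigma2)), G, n1 + n2)
  list(es = expression_set(x, labels), de = seq_len(G) <= n_de, mu = mu)
}

# minimal theta carrier for the score-formula tests
theta_fixture <- function(mean, variance) {
  list(mean = as.matrix(mean), variance = as.matrix(variance))
}

# independent brute-force two-class SAM scores (plain group stats), used as
# the oracle against the package's scoring path
oracle_two_class_d <- function(x, idx1, idx2, s0) {
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- apply(x[, idx1, drop = FALSE], 1, var)
  v2 <- apply(x[, idx2, drop = FALSE], 1, var)
  n1 <- length(idx1); n2 <- length(idx2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  s <- sqrt(a * ((n1 - 1) * v1 + (n2 - 1) * v2))
  (m1 - m2) / (s + s0)
}
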