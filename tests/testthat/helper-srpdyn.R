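# Shared fixtures and independent oracles for the test suite.

# Brute-force O(n^2) oracle for the filtered spike train: entry (l, j) is
# the explicit double sum over prior spikes, independent of the recursive
# event-driven implementation.
brute_force_filter <- function(bases, train) {
  tj <- train$times
  n <- length(tj)
  X <- matrix(0, nrow = length(bases) + 1L, ncol = n)
  X[1L, ] <- 1
  for (l in seq_along(bases)) {
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) {
        if (i < j) s <- s + evaluate_basis(bases[[l]], tj[j] - tj[i])
      }
      X[l + 1L, j] <- s
    }
  }
  X
}

# Independent gamma log-density oracle via stats::dgamma under the
# (shape = mu^2/sigma^2, scale = sigma^2/mu) parameterization.
gamma_nll_oracle <- function(y, mu, sigma) {
  -sum(stats::dgamma(y, shape = mu^2 / sigma^2, scale = sigma^2 / mu, log = TRUE))
}

# A small random kernel/parameter configuration for property tests.
random_srp_config <- function() {
  n_bases <- sample(1:3, 1)
  taus <- stats::runif(n_bases, 0.01, 1)
  amps <- stats::runif(n_bases, -0.3, 0.3)
  b_mu <- stats::runif(1, -4, 4)
  b_sig <- stats::runif(1, -4, 4)
  srp_parameters(
    mu_kernel = kernel(lapply(taus, exp_basis), amps, baseline = b_mu),
    sigma_kernel = kernel(lapply(taus, exp_basis), abs(amps), baseline = b_sig),
    sigma_scale = stats::runif(1, 0.1, 2))
}

random_train <- function(max_spikes = 12) {
  n <- sample(1:max_spikes, 1)
  spike_train(sort(stats::runif(n, 0, 2)))
}
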