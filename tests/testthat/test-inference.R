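test_that("gamma_nll matches the independent gamma log-density oracle", {
  expect_equal(gamma_nll(1, 1, 1), 1)
  set.seed(4)
  y <- runif(1e4, 0.05, 5)
  mu <- runif(1e4, 0.1, 3)
  sg <- runif(1e4, 0.05, 2)
  expect_lt(abs(gamma_nll(y, mu, sg) - gamma_nll_oracle(y, mu, sg)) /
              abs(gamma_nll_oracle(y, mu, sg)), 1e-12)
  for (i in 1:20) {
    j <- sample(1e4, 1)
    expect_equal(gamma_nll(y[j], mu[j], sg[j]),
                 gamma_nll_oracle(y[j], mu[j], sg[j]), tolerance = 1e-10)
  }
  # missing observations contribute zero
  expect_equal(gamma_nll(c(y[1], NA), mu[1:2], sg[1:2]),
               gamma_nll(y[1], mu[1], sg[1]))
  expect_error(gamma_nll(-1, 1, 1), "positive")
  expect_error(gamma_nll(1, -1, 1), "positive")
  expect_error(gamma_nll(1, 1, 0), "positive")
})

test_that("the NLL is minimized near the sample mean in a 1-D scan", {
  set.seed(8)
  y <- rgamma(5000, shape = 16, scale = 0.125)  # mean 2, cv 0.25
  mus <- seq(1.5, 2.5, by = 0.01)
  nll <- vapply(mus, function(m) gamma_nll(y, m, 0.25 * m), numeric(1))
  expect_lt(abs(mus[which.min(nll)] - mean(y)), 0.03)
})

test_that("srp_nll is lowest at the generating parameters on large surrogates", {
  p <- surrogate_srp_parameters()
  dat <- simulate_surrogate(p, n_spikes = 1500, seed = 21)
  nll0 <- srp_nll(p, dat)
  set.seed(22)
  worse <- 0L
  for (i in 1:100) {
    pert <- srp_parameters(
      kernel(p$mu_kernel$bases, p$mu_kernel$amplitudes * runif(1, 0.8, 1.2),
             baseline = p$mu_kernel$baseline * runif(1, 0.8, 1.2)),
      kernel(p$sigma_kernel$bases, p$sigma_kernel$amplitudes * runif(1, 0.8, 1.2),
             baseline = p$sigma_kernel$baseline * runif(1, 0.8, 1.2)),
      sigma_scale = p$sigma_scale * runif(1, 0.8, 1.2))
    if (srp_nll(pert, dat) > nll0) worse <- worse + 1L
  }
  expect_gte(worse, 97)  # likelihood concentrates at the truth
})

test_that("zero sigma-kernel amplitudes reduce srp_nll to the constant-sigma case", {
  kmu <- kernel(list(exp_basis(0.1)), 0.1, baseline = -1)
  ksig0 <- kernel(list(exp_basis(0.1)), 0, baseline = -0.8)
  p <- srp_parameters(kmu, ksig0, sigma_scale = 0.9)
  dat <- simulate_surrogate(p, n_spikes = 100, n_trials = 3, seed = 2)
  # hand-built: sigma = sigma_0 * f(b_sigma) for every pulse
  tr <- dat$protocols[[1]]$train
  y <- dat$protocols[[1]]$amplitudes
  mu <- mean_efficacies(p, tr)
  hand <- gamma_nll(as.vector(y), rep(mu, each = nrow(y)),
                    0.9 * plogis(-0.8))
  expect_equal(srp_nll(p, dat), hand, tolerance = 1e-12)
})

test_that("likelihood slices around the optimum have a single interior minimum", {
  p <- surrogate_srp_parameters()
  dat <- simulate_surrogate(p, n_spikes = 600, seed = 31)
  slice_minima <- function(f, x0, y0) {
    xs <- seq(0.5 * x0, 1.5 * x0, length.out = 11)
    ys <- seq(0.5 * y0, 1.5 * y0, length.out = 11)
    z <- outer(seq_along(xs), seq_along(ys),
               Vectorize(function(i, j) f(xs[i], ys[j])))
    n_min <- 0
    for (i in 2:10) for (j in 2:10) {
      nb <- z[cbind(c(i-1,i+1,i,i,i-1,i-1,i+1,i+1), c(j,j,j-1,j+1,j-1,j+1,j-1,j+1))]
      if (all(z[i, j] < nb)) n_min <- n_min + 1
    }
    n_min
  }
  mk <- function(a_mu, a_sig) {
    srp_parameters(kernel(p$mu_kernel$bases, a_mu, baseline = -1.0),
                   kernel(p$sigma_kernel$bases, a_sig, baseline = -1.5),
                   sigma_scale = 1.0)
  }
  n1 <- slice_minima(function(a, c) srp_nll(mk(a, c), dat), 0.08, 0.10)
  expect_equal(n1, 1)
  mk2 <- function(b_sig, s0) {
    srp_parameters(p$mu_kernel, kernel(p$sigma_kernel$bases, 0.10, baseline = b_sig),
                   sigma_scale = s0)
  }
  n2 <- slice_minima(function(b, s) srp_nll(mk2(b, s), dat), -1.5, 1.0)
  expect_equal(n2, 1)
})

test_that("fit_srp recovers generating parameters and is deterministic", {
  p <- surrogate_srp_parameters()
  dat <- simulate_surrogate(p, n_spikes = 2000, seed = 41)
  fit <- fit_srp(dat, p$mu_kernel$bases, p$sigma_kernel$bases,
                 n_starts = 8, seed = 42)
  expect_true(fit$converged)
  expect_true(is.finite(fit$objective))
  th <- c(fit$parameters$mu_kernel$baseline, fit$parameters$mu_kernel$amplitudes,
          fit$parameters$sigma_kernel$baseline, fit$parameters$sigma_kernel$amplitudes,
          fit$parameters$sigma_scale)
  tt <- c(-1.0, 0.08, -1.5, 0.10, 1.0)
  expect_lt(max(abs(th - tt) / abs(tt)), 0.35)
  expect_true(all(th >= fit$bounds$lower & th <= fit$bounds$upper))
  # determinism under identical seed and data
  fit2 <- fit_srp(dat, p$mu_kernel$bases, p$sigma_kernel$bases,
                  n_starts = 8, seed = 42)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$objective, fit2$objective)
  # refitting data generated from the fitted model recovers it (round trip)
  dat2 <- simulate_surrogate(fit$parameters, n_spikes = 2000, seed = 43)
  fit3 <- fit_srp(dat2, p$mu_kernel$bases, p$sigma_kernel$bases,
                  n_starts = 8, seed = 44)
  th3 <- srpdyn:::srp_theta(fit3$parameters)
  expect_lt(max(abs(th3 - srpdyn:::srp_theta(fit$parameters)) /
                  abs(srpdyn:::srp_theta(fit$parameters))), 0.35)
})

test_that("fit_srp drops non-positive amplitudes and supports fixed sigma_0", {
  p <- surrogate_srp_parameters()
  dat <- simulate_surrogate(p, n_spikes = 300, seed = 51)
  dat$protocols[[1]]$amplitudes[1, 3] <- -0.5
  expect_message(
    fit <- fit_srp(dat, p$mu_kernel$bases, n_starts = 4, seed = 52,
                   sigma_scale = 1),
    "non-positive")
  expect_equal(fit$parameters$sigma_scale, 1)
  expect_true(isTRUE(fit$sigma_scale_fixed))
  expect_length(fit$theta, 4)  # b_mu, a1, b_sigma, c1
})

test_that("fit_tm recovers on-grid truth exactly and near-grid truth closely", {
  grid <- tm_grid(n_U = 7, n_f = 7, n_tau_u = 7, n_tau_R = 7,
                  U_range = c(0.1, 0.7), f_range = c(0.1, 0.7),
                  tau_range = c(0.02, 2))
  truth <- tm_parameters(grid$U[100], grid$f[100], grid$tau_u[100], grid$tau_R[100])
  trains <- validation_protocols(include_poisson = FALSE)
  protos <- lapply(trains, function(tr) {
    mu <- tm_efficacies(truth, tr)$mu
    list(train = tr, amplitudes = matrix(mu / mu[1], nrow = 1))
  })
  dat <- amplitude_data(protos)
  fit <- fit_tm(dat, grid, variant = "classic")
  expect_equal(fit$parameters$U, truth$U)
  expect_equal(fit$parameters$f, truth$f)
  expect_equal(fit$parameters$tau_u, truth$tau_u)
  expect_equal(fit$parameters$tau_R, truth$tau_R)
  expect_equal(fit$objective, 0, tolerance = 1e-20)
  # off-grid generator: MSE at the returned argmin beats MSE at the snapped truth
  off <- tm_parameters(truth$U * 1.04, truth$f * 0.97,
                       truth$tau_u * 1.1, truth$tau_R * 0.93)
  protos2 <- lapply(trains, function(tr) {
    mu <- tm_efficacies(off, tr)$mu
    list(train = tr, amplitudes = matrix(mu / mu[1], nrow = 1))
  })
  fit2 <- fit_tm(amplitude_data(protos2), grid, variant = "classic")
  expect_lt(abs(fit2$parameters$U - off$U), diff(range(grid$U)) / 6)
  expect_lt(abs(fit2$parameters$f - off$f), diff(range(grid$f)) / 6)
  expect_true(is.finite(fit2$objective))
  expect_error(fit_tm(dat, grid[0, ]), "non-empty")
})

test_that("predictions reproduce training-protocol efficacies in a common layout", {
  p <- surrogate_srp_parameters()
  dat <- simulate_surrogate(p, n_spikes = 200, n_trials = 2, seed = 61)
  fit <- fit_srp(dat, p$mu_kernel$bases, n_starts = 4, seed = 62)
  tr <- dat$protocols[[1]]$train
  pred <- predict_heldout(fit, tr)
  expect_named(pred, c("time", "pulse", "mu", "sigma"))
  expect_equal(pred$mu, mean_efficacies(fit$parameters, tr))
  expect_equal(pred$sigma, sd_efficacies(fit$parameters, tr))
  tm_fit <- fit_tm(dat, tm_grid(n_U = 3, n_f = 3, n_tau_u = 3, n_tau_R = 3))
  pred_tm <- predict_heldout(tm_fit, tr)
  expect_named(pred_tm, names(pred))
  expect_true(all(is.na(pred_tm$sigma)))
})

test_that("free-parameter counts follow the basis configuration", {
  bases3 <- lapply(c(0.015, 0.1, 0.65), exp_basis)
  p3 <- srp_parameters(kernel(bases3, rep(0.1, 3), baseline = -1),
                       kernel(bases3, rep(0.1, 3), baseline = -1),
                       sigma_scale = 1)
  expect_equal(n_free_parameters(p3, sigma_scale_fixed = TRUE), 8L)
  expect_equal(n_free_parameters(p3, sigma_scale_fixed = FALSE), 9L)
  expect_equal(n_free_parameters(tm_parameters(0.2, 0.1, 0.1, 0.5)), 4L)
})
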