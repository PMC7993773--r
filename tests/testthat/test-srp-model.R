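test_that("mean efficacies are first-pulse-normalized and match closed form", {
  # closed form: single exponential basis, two spikes one tau apart
  k <- kernel(list(exp_basis(0.1)), 0.2, baseline = 0)
  mu <- mean_efficacies(k, spike_train(c(0, 0.1)))
  expect_equal(mu[1], 1)
  expect_equal(mu[2], plogis(0.2 * exp(-1) / 0.1) / plogis(0), tolerance = 1e-12)
  expect_equal(mu[2], 1.3521355, tolerance = 1e-6)
  # zero-amplitude kernel: constant potential, mu = 1 throughout
  k0 <- kernel(list(exp_basis(0.1)), 0, baseline = 1.3)
  expect_equal(mean_efficacies(k0, regular_train(100, 8)), rep(1, 8))
})

test_that("kernel polarity sets facilitation vs depression", {
  tr <- regular_train(50, 8)
  mu_pos <- mean_efficacies(kernel(list(exp_basis(0.1)), 0.1, baseline = -1), tr)
  mu_neg <- mean_efficacies(kernel(list(exp_basis(0.1)), -0.1, baseline = 1), tr)
  expect_true(all(diff(mu_pos) >= 0))
  expect_true(all(diff(mu_neg) <= 0))
  # and for multi-basis same-sign kernels
  mu_pos2 <- mean_efficacies(kernel(list(exp_basis(0.02), exp_basis(0.3)),
                                    c(0.05, 0.1), baseline = 0), tr)
  expect_true(all(diff(mu_pos2) >= 0))
})

test_that("sd_efficacies implements the three variance modes", {
  tr <- regular_train(100, 5)
  kmu <- kernel(list(exp_basis(0.1)), 0.1, baseline = -1)
  ksig <- kernel(list(exp_basis(0.1)), 0, baseline = -0.5)
  p <- srp_parameters(kmu, ksig, sigma_scale = 0.7)
  # zero sigma-kernel amplitudes: constant sigma_0 * f(b_sigma)
  expect_equal(sd_efficacies(p, tr), rep(0.7 * plogis(-0.5), 5))
  # first-pulse CV = sigma_0 * f(b_sigma) for any kernel-mode model
  ksig2 <- kernel(list(exp_basis(0.1)), 0.2, baseline = -0.5)
  p2 <- srp_parameters(kmu, ksig2, sigma_scale = 0.7)
  cv1 <- sd_efficacies(p2, tr)[1] / mean_efficacies(p2, tr)[1]
  expect_equal(cv1, 0.7 * plogis(-0.5))
  # proportional mode: sigma/mu constant = sigma_0
  pp <- srp_parameters(kmu, sigma_scale = 0.3, variance_mode = "proportional")
  expect_equal(sd_efficacies(pp, tr) / mean_efficacies(pp, tr), rep(0.3, 5))
  # constant mode
  pc <- srp_parameters(kmu, sigma_scale = 0.3, variance_mode = "constant")
  expect_equal(sd_efficacies(pc, tr), rep(0.3, 5))
  # identical kernels and baselines: constant CV; zero sigma-kernel: CV ~ 1/mu
  pi <- srp_parameters(kmu, kmu, sigma_scale = 0.5)
  cv <- sd_efficacies(pi, tr) / mean_efficacies(pi, tr)
  expect_equal(cv, rep(cv[1], 5), tolerance = 1e-12)
  cv0 <- sd_efficacies(p, tr) / mean_efficacies(p, tr)
  expect_equal(cv0 * mean_efficacies(p, tr), rep(sd_efficacies(p, tr)[1], 5))
})

test_that("sampled efficacies have the prescribed gamma moments and independence", {
  p <- srp_parameters(kernel(list(exp_basis(0.1)), 0.1, baseline = -1),
                      kernel(list(exp_basis(0.1)), 0.15, baseline = -1.2),
                      sigma_scale = 0.8)
  tr <- regular_train(50, 5)
  mu <- mean_efficacies(p, tr)
  sg <- sd_efficacies(p, tr)
  n <- 1e5
  y <- sample_efficacies(p, tr, n, seed = 11)
  expect_true(all(y > 0))
  for (j in 1:5) {
    expect_lt(abs(mean(y[, j]) - mu[j]), 3 * sg[j] / sqrt(n))
    expect_lt(abs(sd(y[, j]) - sg[j]) / sg[j], 0.05)
  }
  # successive-pulse deviations are uncorrelated
  dev <- sweep(y, 2, colMeans(y), "-")
  r <- cor(as.vector(dev[, 1:4]), as.vector(dev[, 2:5]))
  expect_lt(abs(r), 3 / sqrt(length(dev[, 1:4])))
  # reproducibility
  expect_identical(y, sample_efficacies(p, tr, n, seed = 11))
})

test_that("mu = sigma gives exponential amplitudes (gamma shape 1)", {
  p <- srp_parameters(kernel(list(exp_basis(0.1)), 0, baseline = 0),
                      kernel(list(exp_basis(0.1)), 0, baseline = 1e9),
                      sigma_scale = 1)  # sigma -> f(large) * 1 = 1 = mu
  tr <- spike_train(0)
  y <- sample_efficacies(p, tr, 4000, seed = 5)[, 1]
  ks <- suppressWarnings(ks.test(y, "pexp", rate = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("psc traces superpose peak-normalized shapes scaled by efficacy", {
  sh <- psc_shape(rise = 0.001, decay = 0.01)
  tg <- seq(0, 0.1, by = 1e-5)
  expect_equal(max(psc_value(sh, tg)), 1, tolerance = 1e-6)
  expect_equal(psc_value(sh, 0), 0)
  # single spike, mu = 1: trace peak 1 within grid resolution
  p <- srp_parameters(kernel(list(exp_basis(0.1)), 0, baseline = 0),
                      variance_mode = "constant", sigma_scale = 0.1)
  et1 <- efficacy_train(p, spike_train(0))
  tr1 <- psc_trace(et1, sh, dt = 1e-5, t_end = 0.1, trial = NULL)
  expect_equal(max(tr1$current), 1, tolerance = 1e-3)
  # two well-separated spikes: two peaks ~ mu_1, mu_2
  et2 <- list(times = c(0, 1), mu = c(1, 1.5), sigma = c(0.1, 0.1), samples = NULL)
  class(et2) <- "efficacy_train"
  tr2 <- psc_trace(et2, sh, dt = 1e-5, t_end = 1.2)
  expect_equal(max(tr2$current[tr2$time < 0.5]), 1, tolerance = 1e-3)
  expect_equal(max(tr2$current[tr2$time > 0.5]), 1.5, tolerance = 1e-3)
  # facilitating 100 Hz train: successive spike-time peaks increase
  pf <- srp_parameters(kernel(list(exp_basis(0.1)), 0.15, baseline = -1),
                      variance_mode = "constant", sigma_scale = 0.1)
  shf <- psc_shape(rise = 2e-4, decay = 2e-3)
  etf <- efficacy_train(pf, regular_train(100, 5))
  trf <- psc_trace(etf, shf, dt = 1e-5, t_end = 0.06, trial = NULL)
  peaks <- vapply(etf$times, function(ts)
    max(trf$current[trf$time > ts & trf$time <= ts + 0.01]), numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_error(psc_trace(etf, shf, dt = -1), "dt")
})

test_that("baseline switch turns sublinear into supralinear facilitation", {
  tr <- regular_train(50, 5)
  k <- function(b) kernel(list(exp_basis(0.1)), 0.15, baseline = b)
  inc_low <- diff(mean_efficacies(k(-4), tr))
  inc_high <- diff(mean_efficacies(k(1), tr))
  expect_true(all(diff(inc_low) > 0))   # supralinear: increments grow
  expect_true(all(diff(inc_high) < 0))  # sublinear: increments shrink
})

test_that("sigma-kernel polarity sets SD direction without changing means", {
  kmu <- kernel(list(exp_basis(0.1)), -0.12, baseline = 1.2)  # depressing mean
  tr <- regular_train(100, 5)
  res <- lapply(c(0.15, 0, -0.15), function(a) {
    p <- srp_parameters(kmu, kernel(list(exp_basis(0.1)), a, baseline = -1),
                        sigma_scale = 1)
    list(mu = mean_efficacies(p, tr), sd = sd_efficacies(p, tr))
  })
  expect_equal(res[[1]]$mu, res[[2]]$mu)
  expect_equal(res[[2]]$mu, res[[3]]$mu)
  expect_true(all(diff(res[[1]]$sd) > 0))
  expect_equal(diff(res[[2]]$sd), rep(0, 4))
  expect_true(all(diff(res[[3]]$sd) < 0))
})

test_that("a joint baseline shift switches the CV progression", {
  # fixed facilitating sigma-kernel, stronger than the mu-kernel; the
  # sigma baseline co-varies with the mu baseline (offset +1)
  tr <- regular_train(100, 5)
  cv_at <- function(b) {
    p <- srp_parameters(kernel(list(exp_basis(0.1)), 0.05, baseline = b),
                        kernel(list(exp_basis(0.1)), 0.065, baseline = b + 1),
                        sigma_scale = 1)
    sd_efficacies(p, tr) / mean_efficacies(p, tr)
  }
  expect_true(all(diff(cv_at(-4)) > 0))  # low baseline: CV grows
  expect_true(all(diff(cv_at(2)) < 0))   # high baseline: CV falls
})

test_that("delayed-facilitation Gaussian kernel potentiates the test spike", {
  # three normalized Gaussians; printed amplitudes are per-ms, so /1000 in
  # second-normalized units
  kg <- kernel(list(gaussian_basis(1.0, 0.6), gaussian_basis(2.5, 1.3),
                    gaussian_basis(6.0, 2.8)),
               c(0.125, 0.620, 1.300), baseline = 0)
  eff <- vapply(1:8, function(n) {
    tr <- burst_plus_test(n, 100, 3)
    tail(mean_efficacies(kg, tr), 1)
  }, numeric(1))
  expect_true(all(diff(eff) > 0))
  expect_gt(eff[8], 1)  # the test response is potentiated relative to baseline
})
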