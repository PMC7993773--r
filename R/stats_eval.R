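#' Reference surrogate-data parameter set
#'
#' The SRP parameter set used as ground truth for surrogate-data
#' experiments: mono-exponential efficacy and variance kernels with a
#' 100 ms time constant, a facilitating efficacy kernel (amplitude 0.08,
#' baseline -1.0), a facilitating variance kernel (amplitude 0.10,
#' baseline -1.5) and \eqn{\sigma_0 = 1}. Per-spike potential jumps are
#' 0.8 and 1.0 and the first-pulse CV is \eqn{\sigma_0 f(b_\sigma) \approx
#' 0.18}, typical of a facilitating central synapse.
#'
#' @param tau Kernel time constant in seconds.
#' @return An [srp_parameters()] object.
#' @export
surrogate_srp_parameters <- function(tau = 0.1) {
  srp_parameters(
    mu_kernel = kernel(list(exp_basis(tau)), 0.08, baseline = -1.0),
    sigma_kernel = kernel(list(exp_basis(tau)), 0.10, baseline = -1.5),
    sigma_scale = 1.0, variance_mode = "kernel")
}

#' Simulate a surrogate dataset from an SRP model
#'
#' Generates a Poisson stimulation train and samples gamma-distributed
#' amplitudes from the model — surrogate data with exactly the statistical
#' structure the inference machinery assumes.
#'
#' @param params An [srp_parameters()].
#' @param rate Poisson rate in Hz.
#' @param n_spikes Number of stimulation spikes.
#' @param n_trials Trials (rows) to sample.
#' @param seed Integer seed (controls both the train and the samples).
#' @param label Protocol label.
#' @return An [amplitude_data()] with a single protocol.
#' @export
simulate_surrogate <- function(params, rate = 10, n_spikes = 4000,
                               n_trials = 1, seed = NULL, label = "surrogate") {
  train <- poisson_train(rate, n_spikes, seed = seed, label = label)
  y <- sample_efficacies(params, train, n_trials,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  ad <- list(); ad[[label]] <- list(train = train, amplitudes = y)
  amplitude_data(ad)
}

#' Per-pulse amplitude statistics
#'
#' Column-wise mean, unbiased SD, coefficient of variation (SD/mean) and
#' trial count of an amplitude table.
#'
#' @param amplitudes A trials x pulses matrix (>= 2 trials), or an
#'   [amplitude_data()] (statistics are computed per protocol).
#' @return A data.frame with columns `pulse`, `mean`, `sd`, `cv`, `n`
#'   (plus `protocol` for `amplitude_data` input).
#' @export
pulse_statistics <- function(amplitudes) {
  if (inherits(amplitudes, "amplitude_data")) {
    out <- lapply(names(amplitudes$protocols), function(nm) {
      s <- pulse_statistics(amplitudes$protocols[[nm]]$amplitudes)
      s$protocol <- nm
      s
    })
    return(do.call(rbind, out))
  }
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) < 2)
    stop("pulse_statistics requires >= 2 trials for SD and CV")
  m <- colMeans(amplitudes, na.rm = TRUE)
  s <- apply(amplitudes, 2, stats::sd, na.rm = TRUE)
  n <- colSums(!is.na(amplitudes))
  data.frame(pulse = seq_along(m), mean = m, sd = s, cv = s / m, n = n,
             row.names = NULL)
}

#' Noise correlation between successive pulses
#'
#' Tests the model's independence assumption: pools, across trials (and
#' protocols), all pairs of deviations from the trial-averaged amplitude at
#' one stimulus position versus the next, and computes the Pearson
#' correlation with a two-sided t-approximation p-value.
#'
#' @param data An [amplitude_data()] or a trials x pulses matrix
#'   (>= 2 trials and >= 2 pulses).
#' @return A list with `r`, `p` and `n_pairs`.
#' @export
noise_correlation <- function(data) {
  mats <- if (inherits(data, "amplitude_data"))
    lapply(data$protocols, `[[`, "amplitudes") else list(as.matrix(data))
  d1 <- d2 <- numeric(0)
  for (y in mats) {
    y <- as.matrix(y)
    if (nrow(y) < 2 || ncol(y) < 2)
      stop("noise_correlation requires >= 2 trials and >= 2 pulses")
    dev <- sweep(y, 2, colMeans(y, na.rm = TRUE), "-")
    j <- seq_len(ncol(y) - 1L)
    d1 <- c(d1, as.vector(dev[, j, drop = FALSE]))
    d2 <- c(d2, as.vector(dev[, j + 1L, drop = FALSE]))
  }
  keep <- !is.na(d1) & !is.na(d2)
  d1 <- d1[keep]; d2 <- d2[keep]
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
    stop("noise_correlation: degenerate (zero-variance) deviations")
  ct <- stats::cor.test(d1, d2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(d1))
}

# Flatten an srp_parameters object (mono- or multi-basis, kernel mode)
# into the named vector layout used by the optimizer.
srp_theta <- function(params) {
  c(b_mu = params$mu_kernel$baseline,
    stats::setNames(params$mu_kernel$amplitudes,
                    paste0("a", seq_along(params$mu_kernel$amplitudes))),
    b_sigma = params$sigma_kernel$baseline,
    stats::setNames(params$sigma_kernel$amplitudes,
                    paste0("c", seq_along(params$sigma_kernel$amplitudes))),
    sigma0 = params$sigma_scale)
}

#' Parameter-recovery experiment on surrogate data
#'
#' For each training size and seed: simulate a Poisson train, sample
#' surrogate amplitudes from `true_params`, fit the SRP model by maximum
#' likelihood, and record (i) relative parameter errors and (ii) held-out
#' MSE on an independent test train, compared with the true model's own
#' held-out MSE (the irreducible sampling error).
#'
#' @param true_params Generating [srp_parameters()] (variance mode `kernel`).
#' @param sizes Strictly increasing vector of training spike counts.
#' @param rate Poisson rate in Hz.
#' @param n_seeds Replicates per size.
#' @param seed Master seed; all sub-seeds derive from it.
#' @param n_starts Multistart points per fit.
#' @param n_test_spikes Length of the independent test train.
#' @param n_trials Training trials sampled per train.
#' @return Object of class `recovery_curve` with three tables: `details`
#'   (one row per size x seed: mean relative errors in percent, overall and
#'   split into efficacy-side and variance-side parameter groups, plus
#'   held-out MSEs), `errors_long` (one row per size x seed x parameter
#'   with the individual relative errors), and `curve` (per size: the
#'   median across seeds of the per-fit mean error, the pooled median over
#'   all individual parameter errors, and median MSEs).
#' @export
recovery_experiment <- function(true_params, sizes = c(100, 500, 2000),
                                rate = 10, n_seeds = 5, seed = 1,
                                n_starts = 16, n_test_spikes = 500,
                                n_trials = 1) {
  if (length(sizes) == 0) stop("sizes must be non-empty")
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  th_true <- srp_theta(true_params)
  n_mu <- length(true_params$mu_kernel$amplitudes) + 1L
  n_sig <- length(true_params$sigma_kernel$amplitudes) + 1L
  rows <- list()
  long <- list()
  for (i in seq_along(sizes)) {
    for (k in seq_len(n_seeds)) {
      sub <- (as.integer(seed) + 7919L * k + 104729L * i) %% 2000000000L
      dat <- simulate_surrogate(true_params, rate = rate, n_spikes = sizes[i],
                                n_trials = n_trials, seed = sub)
      fit <- tryCatch(
        fit_srp(dat, true_params$mu_kernel$bases,
                true_params$sigma_kernel$bases,
                n_starts = n_starts, seed = sub + 1L),
        error = function(e) stop(sprintf(
          "recovery_experiment: fit failed at size %d, seed %d: %s",
          sizes[i], k, conditionMessage(e))))
      th_fit <- srp_theta(fit$parameters)
      rel <- abs(th_fit - th_true) / abs(th_true) * 100
      # independent test set, same for the true and the fitted model
      test <- simulate_surrogate(true_params, rate = rate,
                                 n_spikes = n_test_spikes, n_trials = n_trials,
                                 seed = sub + 2L)
      ytest <- test$protocols[[1]]$amplitudes
      ttest <- test$protocols[[1]]$train
      mu_fit <- mean_efficacies(fit$parameters, ttest)
      mu_true <- mean_efficacies(true_params, ttest)
      mse_fit <- mean(sweep(ytest, 2, mu_fit, "-")^2)
      mse_true <- mean(sweep(ytest, 2, mu_true, "-")^2)
      rows[[length(rows) + 1L]] <- data.frame(
        size = sizes[i], seed = k,
        rel_error = mean(rel),
        rel_error_mu = mean(rel[seq_len(n_mu)]),
        rel_error_sigma = mean(rel[n_mu + seq_len(n_sig + 1L)]),
        mse_fit = mse_fit, mse_true = mse_true, nll = fit$objective)
      long[[length(long) + 1L]] <- data.frame(
        size = sizes[i], seed = k, parameter = names(th_true),
        rel_error = unname(rel))
    }
  }
  details <- do.call(rbind, rows)
  errors_long <- do.call(rbind, long)
  rownames(errors_long) <- NULL
  curve <- do.call(rbind, lapply(split(details, details$size), function(g)
    data.frame(size = g$size[1],
               rel_error = stats::median(g$rel_error),
               rel_error_pooled = stats::median(
                 errors_long$rel_error[errors_long$size == g$size[1]]),
               rel_error_mu = stats::median(g$rel_error_mu),
               rel_error_sigma = stats::median(g$rel_error_sigma),
               mse_fit = stats::median(g$mse_fit),
               mse_true = stats::median(g$mse_true))))
  curve <- curve[order(curve$size), ]
  rownames(curve) <- NULL
  structure(list(curve = curve, details = details, errors_long = errors_long,
                 sizes = sizes, n_seeds = n_seeds, seed = seed),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat("<recovery_curve> median relative parameter error (%) by training size:\n")
  print(x$curve, digits = 4)
  invisible(x)
}

#' Protocol hold-out with trial bootstrap
#'
#' The cross-validation design used for model comparison: for each of
#' `n_boot` bootstrap iterations, a fraction `drop_fraction` of trials
#' (whole traces, never individual pulses) is randomly excluded from every
#' protocol; then each protocol in turn is held out, the model is fitted on
#' the remaining protocols, and the held-out protocol's MSE (between its
#' trial-averaged amplitudes and the model prediction) is recorded. With
#' `drop_fraction = 0` and `n_boot = 1` this reduces to plain
#' leave-one-protocol-out.
#'
#' @param data An [amplitude_data()] with >= 2 protocols.
#' @param model `"srp"` or `"tm"`.
#' @param n_boot Number of bootstrap iterations (default 20).
#' @param drop_fraction Fraction of trials dropped per protocol, in \[0, 1).
#' @param seed Master seed for the bootstrap resampling.
#' @param ... Passed to [fit_srp()] (e.g. `mu_bases`, `n_starts`) or
#'   [fit_tm()] (e.g. `grid`, `variant`).
#' @return A matrix (`n_boot` x protocols) of held-out MSEs, with an
#'   attribute `"model"`.
#' @export
holdout_bootstrap <- function(data, model = c("srp", "tm"), n_boot = 20,
                              drop_fraction = 0.2, seed = NULL, ...) {
  model <- match.arg(model)
  stopifnot(inherits(data, "amplitude_data"))
  if (length(data$protocols) < 2) stop("holdout_bootstrap requires >= 2 protocols")
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  nms <- names(data$protocols)
  mse <- matrix(NA_real_, n_boot, length(nms), dimnames = list(NULL, nms))
  with_seed_if(seed, {
    for (b in seq_len(n_boot)) {
      sub <- data
      for (nm in nms) {
        y <- sub$protocols[[nm]]$amplitudes
        n_drop <- floor(drop_fraction * nrow(y))
        if (nrow(y) - n_drop < 1)
          stop(sprintf("protocol '%s': too few trials after dropping", nm))
        if (n_drop > 0) {
          keep <- sort(sample(nrow(y), nrow(y) - n_drop))
          sub$protocols[[nm]]$amplitudes <- y[keep, , drop = FALSE]
        }
      }
      for (h in seq_along(nms)) {
        train_data <- amplitude_data(sub$protocols[-h])
        fit <- if (model == "srp") fit_srp(train_data, ...)
               else fit_tm(train_data, ...)
        held <- sub$protocols[[h]]
        obs <- colMeans(held$amplitudes, na.rm = TRUE)
        pred <- predict_heldout(fit, held$train)$mu
        mse[b, h] <- mean((obs - pred)^2)
      }
    }
  })
  attr(mse, "model") <- model
  mse
}
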