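#' Sigmoidal readout of the SRP model
#'
#' The nonlinear readout mapping potential efficacy to (positive) efficacy.
#' The logistic function \eqn{f(x) = 1/(1+e^{-x})} is used throughout: it is
#' strictly positive (the gamma mean and SD must be positive), smooth and
#' saturating in both directions.
#'
#' @param x Potential efficacy (any real).
#' @return `f(x)` in (0, 1).
#' @export
srp_readout <- function(x) stats::plogis(x)

#' SRP model parameters
#'
#' Bundles the efficacy kernel (mean dynamics), the variance kernel
#' (SD dynamics), the SD scale \eqn{\sigma_0} and the variance mode:
#'
#' * `"kernel"`: \eqn{\sigma_j = \sigma_0 f(k_\sigma * S(t_j) + b_\sigma)}
#'   — the full heteroskedastic model.
#' * `"proportional"`: \eqn{\sigma_j = \sigma_0 \mu_j} (constant CV; the
#'   generalized-linear-model special case). `sigma_kernel` is ignored.
#' * `"constant"`: \eqn{\sigma_j = \sigma_0} for all pulses.
#'
#' @param mu_kernel A [kernel()]: amplitudes \eqn{\theta_\mu} and baseline
#'   \eqn{b_\mu}.
#' @param sigma_kernel A [kernel()] for the SD dynamics (mode `"kernel"`).
#' @param sigma_scale \eqn{\sigma_0 > 0}.
#' @param variance_mode One of `"kernel"`, `"proportional"`, `"constant"`.
#' @return Object of class `srp_parameters`.
#' @examples
#' p <- srp_parameters(kernel(list(exp_basis(0.1)), 0.08, baseline = -1),
#'                     kernel(list(exp_basis(0.1)), 0.10, baseline = -1.5),
#'                     sigma_scale = 1)
#' @export
srp_parameters <- function(mu_kernel, sigma_kernel = NULL, sigma_scale = 1,
                           variance_mode = c("kernel", "proportional", "constant")) {
  variance_mode <- match.arg(variance_mode)
  if (!inherits(mu_kernel, "stp_kernel")) stop("mu_kernel must be an stp_kernel")
  if (!is.finite(sigma_scale) || sigma_scale <= 0) stop("sigma_scale must be > 0")
  if (variance_mode == "kernel") {
    if (is.null(sigma_kernel)) stop("variance_mode 'kernel' needs a sigma_kernel")
    if (!inherits(sigma_kernel, "stp_kernel")) stop("sigma_kernel must be an stp_kernel")
  }
  structure(list(mu_kernel = mu_kernel, sigma_kernel = sigma_kernel,
                 sigma_scale = as.numeric(sigma_scale),
                 variance_mode = variance_mode),
            class = "srp_parameters")
}

#' @export
print.srp_parameters <- function(x, ...) {
  cat(sprintf("<srp_parameters> variance_mode=%s, sigma0=%g\n",
              x$variance_mode, x$sigma_scale))
  cat("  mu: "); print(x$mu_kernel)
  if (x$variance_mode == "kernel") { cat("  sigma: "); print(x$sigma_kernel) }
  invisible(x)
}

#' Mean synaptic efficacies along a spike train
#'
#' The deterministic SRP model: the efficacy of the j-th spike is
#' \deqn{\mu_j = f(k_\mu * S(t_j) + b_\mu) / f(b_\mu),}
#' a sigmoidal readout of the strictly causal convolution of the efficacy
#' kernel with the spike train, normalized so that the first pulse of any
#' train has efficacy exactly 1.
#'
#' @param params An [srp_parameters()] object (or a bare [kernel()], taken
#'   as the efficacy kernel).
#' @param train A [spike_train()].
#' @return Numeric vector of efficacies, one per spike; `mu[1] == 1`.
#' @export
mean_efficacies <- function(params, train) {
  k <- if (inherits(params, "srp_parameters")) params$mu_kernel else params
  ft <- filter_at_spikes(k$bases, train)
  pot <- drop(crossprod(ft$X, c(k$baseline, k$amplitudes)))
  srp_readout(pot) / srp_readout(k$baseline)
}

#' Dynamic standard deviations along a spike train
#'
#' The stochastic SRP model's per-pulse SD, by variance mode:
#' \eqn{\sigma_j = \sigma_0 f(k_\sigma * S(t_j) + b_\sigma)} (kernel mode;
#' note there is no baseline normalization, unlike the mean),
#' \eqn{\sigma_j = \sigma_0 \mu_j} (proportional), or
#' \eqn{\sigma_j = \sigma_0} (constant).
#'
#' @inheritParams mean_efficacies
#' @return Numeric vector of SDs, one per spike, all positive.
#' @export
sd_efficacies <- function(params, train) {
  stopifnot(inherits(params, "srp_parameters"))
  n <- length(train$times)
  switch(params$variance_mode,
    kernel = {
      k <- params$sigma_kernel
      ft <- filter_at_spikes(k$bases, train)
      pot <- drop(crossprod(ft$X, c(k$baseline, k$amplitudes)))
      params$sigma_scale * srp_readout(pot)
    },
    proportional = params$sigma_scale * mean_efficacies(params, train),
    constant = rep(params$sigma_scale, n)
  )
}

#' Efficacy train: per-spike mean, SD and optional samples
#'
#' @inheritParams mean_efficacies
#' @param n_trials If > 0, also draw `n_trials` gamma samples per pulse.
#' @param seed Optional seed for the samples.
#' @return Object of class `efficacy_train` with `times`, `mu`, `sigma`
#'   and (optionally) `samples` (trials x pulses matrix).
#' @export
efficacy_train <- function(params, train, n_trials = 0, seed = NULL) {
  mu <- mean_efficacies(params, train)
  sigma <- sd_efficacies(params, train)
  samples <- if (n_trials > 0) sample_efficacies(params, train, n_trials, seed) else NULL
  structure(list(times = train$times, mu = mu, sigma = sigma, samples = samples),
            class = "efficacy_train")
}

#' Sample stochastic synaptic efficacies
#'
#' Draws per-trial, per-pulse amplitudes from the gamma distribution with
#' mean \eqn{\mu_j} and SD \eqn{\sigma_j} (shape \eqn{\mu_j^2/\sigma_j^2},
#' scale \eqn{\sigma_j^2/\mu_j}). Successive pulses are statistically
#' independent given the train.
#'
#' @inheritParams mean_efficacies
#' @param n_trials Number of trials (rows) to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return Matrix (`n_trials` x pulses) of positive amplitudes.
#' @export
sample_efficacies <- function(params, train, n_trials, seed = NULL) {
  if (n_trials < 1 || n_trials != round(n_trials)) stop("n_trials must be a positive integer")
  mu <- mean_efficacies(params, train)
  sigma <- sd_efficacies(params, train)
  n <- length(mu)
  with_seed_if(seed, {
    y <- matrix(stats::rgamma(n_trials * n,
                              shape = rep(mu^2 / sigma^2, each = n_trials),
                              scale = rep(sigma^2 / mu, each = n_trials)),
                nrow = n_trials, ncol = n)
    colnames(y) <- paste0("pulse", seq_len(n))
    y
  })
}

#' Stereotypical PSC shape
#'
#' A peak-normalized difference of exponentials,
#' \eqn{s(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}} for `t > 0`, scaled so
#' the single maximum equals 1. Used only to synthesize current traces for
#' presentation; all fitting operates on amplitude tables.
#'
#' @param rise Rise time constant in seconds (> 0).
#' @param decay Decay time constant in seconds (> rise).
#' @return Object of class `psc_shape` with a `value(t)` evaluator.
#' @export
psc_shape <- function(rise = 0.001, decay = 0.01) {
  if (!is.finite(rise) || rise <= 0) stop("rise must be > 0")
  if (!is.finite(decay) || decay <= rise) stop("decay must be > rise")
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  structure(list(rise = rise, decay = decay, t_peak = t_peak, peak = peak),
            class = "psc_shape")
}

#' Evaluate a PSC shape
#' @param shape A [psc_shape()].
#' @param t Times in seconds; 0 for `t <= 0`.
#' @return Numeric vector with maximum value 1 at the peak time.
#' @export
psc_value <- function(shape, t) {
  ifelse(t > 0, (exp(-t / shape$decay) - exp(-t / shape$rise)) / shape$peak, 0)
}

#' Synthesize a postsynaptic current trace
#'
#' Superposes peak-normalized PSC shapes at the spike times, each scaled by
#' its efficacy: \eqn{I(t) = \sum_j y_j\, k_{PSC}(t - t_j)}. Sampled
#' amplitudes are used when present (one trace per trial), otherwise the
#' mean efficacies.
#'
#' @param et An [efficacy_train()].
#' @param shape A [psc_shape()].
#' @param dt Grid step in seconds (> 0).
#' @param t_end End of the grid in seconds.
#' @param trial Which sample trial to use (default 1) when samples exist;
#'   `NULL` forces the mean efficacies.
#' @return A data.frame with columns `time` and `current`.
#' @export
psc_trace <- function(et, shape = psc_shape(), dt = 1e-4, t_end = NULL, trial = 1) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(t_end)) t_end <- max(et$times) + 5 * shape$decay
  amp <- if (!is.null(et$samples) && !is.null(trial)) et$samples[trial, ] else et$mu
  tg <- seq(0, t_end, by = dt)
  cur <- numeric(length(tg))
  for (j in seq_along(et$times))
    cur <- cur + amp[j] * psc_value(shape, tg - et$times[j])
  data.frame(time = tg, current = cur)
}
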