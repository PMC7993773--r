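#' Amplitude data: per-protocol trial x pulse response tables
#'
#' The fitting target: for each stimulation protocol, a matrix of observed
#' postsynaptic response amplitudes with one row per trial and one column
#' per stimulus position. Missing values (`NA`) are allowed and skipped in
#' likelihoods.
#'
#' @param protocols A named list; each element is a list with components
#'   `train` (a [spike_train()]) and `amplitudes` (numeric matrix,
#'   trials x pulses, with `ncol` equal to the number of spikes).
#' @return Object of class `amplitude_data`.
#' @export
amplitude_data <- function(protocols) {
  if (!is.list(protocols) || length(protocols) == 0)
    stop("protocols must be a non-empty list")
  for (nm in names(protocols)) {
    p <- protocols[[nm]]
    if (!inherits(p$train, "spike_train")) stop("each protocol needs a spike_train")
    p$amplitudes <- as.matrix(p$amplitudes)
    if (ncol(p$amplitudes) != length(p$train$times))
      stop(sprintf("protocol '%s': amplitude columns (%d) must match spikes (%d)",
                   nm, ncol(p$amplitudes), length(p$train$times)))
    protocols[[nm]]$amplitudes <- p$amplitudes
  }
  structure(list(protocols = protocols), class = "amplitude_data")
}

#' @export
print.amplitude_data <- function(x, ...) {
  cat(sprintf("<amplitude_data> %d protocols\n", length(x$protocols)))
  for (nm in names(x$protocols)) {
    p <- x$protocols[[nm]]
    cat(sprintf("  %s: %d trials x %d pulses\n", nm,
                nrow(p$amplitudes), ncol(p$amplitudes)))
  }
  invisible(x)
}

#' Negative log-likelihood of gamma-distributed amplitudes
#'
#' The gamma distribution reparameterized by mean \eqn{\mu} and standard
#' deviation \eqn{\sigma} (shape \eqn{\gamma = \mu^2/\sigma^2}, scale
#' \eqn{\lambda = \sigma^2/\mu}) gives the per-observation negative
#' log-density
#' \deqn{\frac{y\mu}{\sigma^2} - \left(\frac{\mu^2}{\sigma^2}-1\right)
#'   \ln\frac{y\mu}{\sigma^2} + \ln\left(\Gamma\!\left(\frac{\mu^2}{\sigma^2}\right)
#'   \frac{\sigma^2}{\mu}\right),}
#' summed over observations. `NA` observations contribute 0 (missing data).
#'
#' @param y Observed amplitudes (> 0, or `NA`).
#' @param mu Means (> 0), recycled against `y`.
#' @param sigma Standard deviations (> 0), recycled against `y`.
#' @return The summed negative log-likelihood (scalar).
#' @export
gamma_nll <- function(y, mu, sigma) {
  if (any(!is.na(y) & y <= 0)) stop("amplitudes must be positive")
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  keep <- !is.na(y)
  if (!any(keep)) return(0)
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n)[rep_len(keep, n)]
  mu <- rep_len(mu, n)[rep_len(keep, n)]
  sigma <- rep_len(sigma, n)[rep_len(keep, n)]
  g <- mu^2 / sigma^2                       # shape
  z <- y * mu / sigma^2                     # y / scale
  sum(z - (g - 1) * log(z) + lgamma(g) + log(sigma^2 / mu))
}

# Precompute design matrices and observation matrices per protocol.
# Returns a list of lists with Xmu, Xsig ((L+1) x n, const row first) and y.
build_design <- function(data, mu_bases, sigma_bases = mu_bases) {
  stopifnot(inherits(data, "amplitude_data"))
  lapply(data$protocols, function(p) {
    list(Xmu = filter_at_spikes(mu_bases, p$train)$X,
         Xsig = filter_at_spikes(sigma_bases, p$train)$X,
         y = p$amplitudes, train = p$train)
  })
}

# NLL at a flat parameter vector theta = c(theta_mu, theta_sigma[, sigma0]).
# theta_mu = (b_mu, a_1..a_L); theta_sigma = (b_sigma, c_1..c_M).
srp_nll_theta <- function(theta, design, n_mu, n_sig, sigma_scale = NULL) {
  th_mu <- theta[seq_len(n_mu)]
  th_sig <- theta[n_mu + seq_len(n_sig)]
  s0 <- if (is.null(sigma_scale)) theta[n_mu + n_sig + 1L] else sigma_scale
  nll <- 0
  for (d in design) {
    mu <- srp_readout(drop(crossprod(d$Xmu, th_mu))) / srp_readout(th_mu[1L])
    sig <- s0 * srp_readout(drop(crossprod(d$Xsig, th_sig)))
    nll <- nll + gamma_nll(as.vector(d$y),
                           rep(mu, each = nrow(d$y)),
                           rep(sig, each = nrow(d$y)))
  }
  nll
}

#' SRP negative log-likelihood over a dataset
#'
#' Evaluates the heteroskedastic gamma likelihood of an
#' [amplitude_data()] set under a full SRP parameter set: means and SDs are
#' computed per protocol from the design matrices (first-pulse-normalized
#' means, unnormalized SDs) and passed to [gamma_nll()].
#'
#' @param params An [srp_parameters()] with `variance_mode = "kernel"`.
#' @param data An [amplitude_data()].
#' @return The total negative log-likelihood (scalar).
#' @export
srp_nll <- function(params, data) {
  stopifnot(inherits(params, "srp_parameters"))
  if (params$variance_mode != "kernel")
    stop("srp_nll expects variance_mode 'kernel'; use gamma_nll with sd_efficacies otherwise")
  design <- build_design(data, params$mu_kernel$bases, params$sigma_kernel$bases)
  theta <- c(params$mu_kernel$baseline, params$mu_kernel$amplitudes,
             params$sigma_kernel$baseline, params$sigma_kernel$amplitudes)
  srp_nll_theta(theta, design,
                n_mu = length(params$mu_kernel$amplitudes) + 1L,
                n_sig = length(params$sigma_kernel$amplitudes) + 1L,
                sigma_scale = params$sigma_scale)
}

# Default box constraints for SRP fitting. Exponential-basis amplitudes are
# bounded so the per-spike potential jump a/tau stays in [-10, 10] (keeping
# the logistic out of flat saturation); other amplitudes in [-10, 10];
# baselines in [-6, 6]; sigma0 in [1e-3, 10].
default_srp_bounds <- function(mu_bases, sigma_bases, sigma_free) {
  amp_bounds <- function(bases) {
    t(vapply(bases, function(b) {
      if (inherits(b, "exp_basis")) c(-10 * b$tau, 10 * b$tau) else c(-10, 10)
    }, numeric(2)))
  }
  lower <- c(-6, amp_bounds(mu_bases)[, 1], -6, amp_bounds(sigma_bases)[, 1])
  upper <- c(6, amp_bounds(mu_bases)[, 2], 6, amp_bounds(sigma_bases)[, 2])
  if (sigma_free) { lower <- c(lower, 1e-3); upper <- c(upper, 10) }
  list(lower = lower, upper = upper)
}

#' Fit the SRP model by maximum likelihood
#'
#' Minimizes the gamma negative log-likelihood over the SRP parameters
#' (efficacy-kernel baseline and amplitudes, variance-kernel baseline and
#' amplitudes, and the SD scale \eqn{\sigma_0} unless fixed) using bounded
#' L-BFGS-B with a multistart procedure: `n_starts` stratified
#' (Latin-hypercube) starting points over the bound box, keeping the
#' converged result with the minimum NLL. Deterministic given `seed` and
#' the data.
#'
#' Non-positive observed amplitudes (possible in noisy real data, but
#' outside the gamma support) are set to missing with a message before
#' fitting.
#'
#' @param data An [amplitude_data()] with at least one protocol of >= 2 pulses.
#' @param mu_bases List of basis objects for the efficacy kernel.
#' @param sigma_bases List of basis objects for the variance kernel
#'   (defaults to `mu_bases`).
#' @param bounds Optional list with `lower` and `upper` vectors over
#'   `c(b_mu, a_1..a_L, b_sigma, c_1..c_M[, sigma0])`; defaults keep the
#'   sigmoid out of flat saturation (see Details in the package vignette).
#' @param n_starts Number of multistart points (default 256).
#' @param seed Integer seed controlling the start points.
#' @param sigma_scale `NULL` to fit \eqn{\sigma_0} as a free parameter
#'   (the default), or a fixed positive value (the "standardized" mode,
#'   e.g. `1` after amplitude standardization).
#' @return Object of class `fit_result` with the fitted
#'   [srp_parameters()], final NLL, multistart provenance (start points
#'   and per-start objectives) and convergence metadata.
#' @export
fit_srp <- function(data, mu_bases, sigma_bases = mu_bases, bounds = NULL,
                    n_starts = 256, seed = NULL, sigma_scale = NULL) {
  stopifnot(inherits(data, "amplitude_data"))
  if (!any(vapply(data$protocols, function(p) length(p$train$times) >= 2, logical(1))))
    stop("need at least one protocol with >= 2 pulses")
  if (inherits(mu_bases, "basis_fn")) mu_bases <- list(mu_bases)
  if (inherits(sigma_bases, "basis_fn")) sigma_bases <- list(sigma_bases)

  # gamma support: exclude non-positive observations
  n_dropped <- 0L
  for (nm in names(data$protocols)) {
    y <- data$protocols[[nm]]$amplitudes
    bad <- !is.na(y) & y <= 0
    if (any(bad)) { y[bad] <- NA_real_; n_dropped <- n_dropped + sum(bad) }
    data$protocols[[nm]]$amplitudes <- y
  }
  if (n_dropped > 0)
    message(sprintf("fit_srp: excluded %d non-positive amplitude(s) from the likelihood", n_dropped))

  design <- build_design(data, mu_bases, sigma_bases)
  n_mu <- length(mu_bases) + 1L
  n_sig <- length(sigma_bases) + 1L
  sigma_free <- is.null(sigma_scale)
  if (is.null(bounds))
    bounds <- default_srp_bounds(mu_bases, sigma_bases, sigma_free)
  d <- length(bounds$lower)
  stopifnot(length(bounds$upper) == d,
            d == n_mu + n_sig + as.integer(sigma_free))

  objective <- function(theta) {
    v <- try(srp_nll_theta(theta, design, n_mu, n_sig, sigma_scale), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e12 else v
  }

  starts <- with_seed_if(seed, lhs::randomLHS(n_starts, d))
  starts <- sweep(sweep(starts, 2, bounds$upper - bounds$lower, "*"),
                  2, bounds$lower, "+")

  per_start <- data.frame(start = seq_len(n_starts), objective = NA_real_,
                          convergence = NA_integer_)
  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- try(stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                            lower = bounds$lower, upper = bounds$upper,
                            control = list(maxit = 500, factr = 1e2)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    per_start$objective[s] <- res$value
    per_start$convergence[s] <- res$convergence
    if (res$convergence == 0 &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    # fall back to the best non-converged finish rather than failing outright
    ok <- which(is.finite(per_start$objective))
    if (length(ok) == 0)
      stop("fit_srp: all optimization starts failed; per-start diagnostics:\n",
           paste(utils::capture.output(print(per_start)), collapse = "\n"))
    s <- ok[which.min(per_start$objective[ok])]
    best <- stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                         lower = bounds$lower, upper = bounds$upper,
                         control = list(maxit = 2000, factr = 1e2))
  }

  theta <- best$par
  s0 <- if (sigma_free) theta[n_mu + n_sig + 1L] else sigma_scale
  params <- srp_parameters(
    mu_kernel = kernel(mu_bases, theta[2:n_mu], baseline = theta[1L]),
    sigma_kernel = kernel(sigma_bases, theta[n_mu + 2:n_sig],
                          baseline = theta[n_mu + 1L]),
    sigma_scale = s0, variance_mode = "kernel")

  structure(list(model = "srp", parameters = params, theta = theta,
                 objective = best$value, converged = best$convergence == 0,
                 n_starts = n_starts, start_values = starts,
                 per_start = per_start, seed = seed,
                 sigma_scale_fixed = !sigma_free, bounds = bounds,
                 n_dropped = n_dropped),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, objective = %.6g, converged = %s\n",
              toupper(x$model), x$objective, x$converged))
  print(x$parameters)
  invisible(x)
}

#' Parameter grid for TM fitting
#'
#' Linear spacing in `U` and `f` over (0, 1), logarithmic spacing in the
#' two time constants over \[1 ms, 10 s\].
#'
#' @param n_U,n_f,n_tau_u,n_tau_R Points per dimension (product = grid size).
#' @param U_range,f_range Ranges within (0, 1).
#' @param tau_range Time-constant range in seconds.
#' @return A data.frame with columns `U`, `f`, `tau_u`, `tau_R`.
#' @export
tm_grid <- function(n_U = 10, n_f = 10, n_tau_u = 10, n_tau_R = 10,
                    U_range = c(0.02, 0.98), f_range = c(0.02, 0.98),
                    tau_range = c(0.001, 10)) {
  expand.grid(
    U = seq(U_range[1], U_range[2], length.out = n_U),
    f = seq(f_range[1], f_range[2], length.out = n_f),
    tau_u = exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_tau_u)),
    tau_R = exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_tau_R)),
    KEEP.OUT.ATTRS = FALSE)
}

# Vectorized TM efficacies over a grid of parameter vectors for one train.
# Returns a (grid rows) x (spikes) matrix of mu_n.
tm_mu_grid <- function(U, f, tau_u, tau_R, variant, times) {
  n <- length(times)
  G <- length(U)
  mu <- matrix(0, G, n)
  R <- rep(1, G); u <- U
  for (j in seq_len(n)) {
    mu[, j] <- R * u
    if (j < n) {
      dt <- times[j + 1] - times[j]
      u_plus <- if (variant == "classic") u + f * (1 - u) else u + u * f * (1 - u)
      R <- 1 - (1 - R * (1 - u)) * exp(-dt / tau_R)
      u <- U + (u_plus - U) * exp(-dt / tau_u)
    }
  }
  mu
}

#' Fit the TM model by exhaustive grid search
#'
#' Evaluates the mean squared error between TM-predicted efficacies and the
#' observed trial-averaged amplitudes over an exhaustive parameter grid and
#' returns the arg-min (ties broken by first-in-scan order). When
#' `normalize = TRUE` (the default, for first-pulse-normalized data), TM
#' predictions are divided by the model's first-pulse efficacy.
#'
#' @param data An [amplitude_data()]; trial averages are computed per
#'   protocol (missing values ignored).
#' @param grid A data.frame of candidate parameters from [tm_grid()].
#' @param variant `"classic"` or `"extended"`.
#' @param normalize Divide predictions by the first-pulse prediction?
#' @return A `fit_result` with the best [tm_parameters()] and the MSE.
#' @export
fit_tm <- function(data, grid = tm_grid(), variant = c("classic", "extended"),
                   normalize = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "amplitude_data"))
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("grid must be a non-empty data.frame")
  target <- lapply(data$protocols, function(p)
    colMeans(p$amplitudes, na.rm = TRUE))
  sse <- numeric(nrow(grid))
  n_pulses <- 0L
  for (nm in names(data$protocols)) {
    times <- data$protocols[[nm]]$train$times
    mu <- tm_mu_grid(grid$U, grid$f, grid$tau_u, grid$tau_R, variant, times)
    if (normalize) mu <- mu / mu[, 1L]
    err <- sweep(mu, 2, target[[nm]], "-")
    sse <- sse + rowSums(err^2)
    n_pulses <- n_pulses + length(times)
  }
  mse <- sse / n_pulses
  ix <- which.min(mse)     # which.min returns the first minimum: scan order
  params <- tm_parameters(grid$U[ix], grid$f[ix], grid$tau_u[ix],
                          grid$tau_R[ix], variant = variant)
  structure(list(model = "tm", parameters = params, objective = mse[ix],
                 converged = TRUE, n_starts = nrow(grid),
                 grid_index = ix, normalize = normalize, seed = NULL),
            class = "fit_result")
}

#' Predict per-pulse responses for a (possibly held-out) protocol
#'
#' Applies a fitted model to an arbitrary stimulation train, returning the
#' model's mean trajectory (and SD for the SRP model) in a common layout so
#' SRP and TM predictions can be compared directly.
#'
#' @param fit A `fit_result` from [fit_srp()] or [fit_tm()].
#' @param train A [spike_train()].
#' @return A data.frame with columns `time`, `pulse`, `mu` and `sigma`
#'   (`NA` for the TM model).
#' @export
predict_heldout <- function(fit, train) {
  stopifnot(inherits(fit, "fit_result"), inherits(train, "spike_train"))
  if (fit$model == "srp") {
    mu <- mean_efficacies(fit$parameters, train)
    sigma <- sd_efficacies(fit$parameters, train)
  } else {
    mu <- tm_efficacies(fit$parameters, train)$mu
    if (isTRUE(fit$normalize)) mu <- mu / mu[1L]
    sigma <- rep(NA_real_, length(mu))
  }
  data.frame(time = train$times, pulse = seq_along(train$times),
             mu = mu, sigma = sigma)
}

#' Count free parameters of a model configuration
#'
#' For the SRP model: one baseline plus one amplitude per basis for each of
#' the two kernels, plus the SD scale \eqn{\sigma_0} unless it has been
#' fixed by standardization (so 3 bases per kernel give 8 free parameters
#' with \eqn{\sigma_0} fixed, 9 with it free). For the TM model: 4.
#'
#' @param x An [srp_parameters()], [tm_parameters()] or `fit_result`.
#' @param sigma_scale_fixed Is \eqn{\sigma_0} fixed (standardized data)?
#'   For a `fit_result` the fit's own setting is used.
#' @return Integer count of free parameters.
#' @export
n_free_parameters <- function(x, sigma_scale_fixed = FALSE) {
  if (inherits(x, "fit_result")) {
    if (x$model == "tm") return(4L)
    sigma_scale_fixed <- isTRUE(x$sigma_scale_fixed)
    x <- x$parameters
  }
  if (inherits(x, "tm_parameters")) return(4L)
  stopifnot(inherits(x, "srp_parameters"))
  n <- length(x$mu_kernel$amplitudes) + 1L
  if (x$variance_mode == "kernel")
    n <- n + length(x$sigma_kernel$amplitudes) + 1L
  n + as.integer(!sigma_scale_fixed)
}
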