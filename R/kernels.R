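#' Causal basis functions
#'
#' Kernels in the SRP model are linear combinations of causal basis
#' functions. Two families are provided:
#'
#' * `exp_basis(tau)`: integral-normalized exponential decay,
#'   \eqn{h(t) = \Theta(t)\, e^{-t/\tau}/\tau}, which integrates to 1 over
#'   \eqn{(0, \infty)}. Amplitudes attached to this basis therefore have
#'   units of "potential per spike".
#' * `gaussian_basis(mu, sd)`: normalized Gaussian density centred at
#'   `mu > 0`, truncated to `t > 0` (value 0 at and before 0, without
#'   renormalization; the truncated mass is negligible for the delayed
#'   facilitation timescales this basis is used for).
#'
#' Both are strictly causal: the value at any `t <= 0` is exactly 0, so a
#' spike affects the potential efficacy only strictly after itself.
#'
#' @param tau Decay time constant in seconds (> 0).
#' @param mu,sd Center and width of the Gaussian in seconds (> 0).
#' @return A basis object of class `exp_basis` or `gaussian_basis`
#'   (both inherit from `basis_fn`).
#' @export
exp_basis <- function(tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  structure(list(tau = tau), class = c("exp_basis", "basis_fn"))
}

#' @rdname exp_basis
#' @export
gaussian_basis <- function(mu, sd) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  structure(list(mu = mu, sd = sd), class = c("gaussian_basis", "basis_fn"))
}

#' Evaluate a basis function
#'
#' @param basis A basis object from [exp_basis()] or [gaussian_basis()].
#' @param t Times in seconds (vectorized). Values at `t <= 0` are 0.
#' @return Numeric vector of basis densities.
#' @export
evaluate_basis <- function(basis, t) UseMethod("evaluate_basis")

#' @export
evaluate_basis.exp_basis <- function(basis, t) {
  ifelse(t > 0, exp(-t / basis$tau) / basis$tau, 0)
}

#' @export
evaluate_basis.gaussian_basis <- function(basis, t) {
  ifelse(t > 0, stats::dnorm(t, mean = basis$mu, sd = basis$sd), 0)
}

#' Kernel: linear combination of causal bases plus a baseline
#'
#' A kernel \eqn{k(t) = \sum_l a_l h_l(t)} together with the coefficient of
#' the constant basis (the baseline `b`). The kernel proper is strictly
#' causal (0 at `t <= 0`); the baseline is carried separately and added to
#' the convolution to form the potential \eqn{k*S + b}.
#'
#' @param bases List of basis objects ([exp_basis()] / [gaussian_basis()]).
#' @param amplitudes Numeric coefficients, one per basis.
#' @param baseline Coefficient of the constant basis.
#' @return An object of class `stp_kernel`.
#' @examples
#' kernel(list(exp_basis(0.1)), amplitudes = 0.08, baseline = -1)
#' @export
kernel <- function(bases, amplitudes, baseline = 0) {
  if (inherits(bases, "basis_fn")) bases <- list(bases)
  if (!all(vapply(bases, inherits, logical(1), "basis_fn")))
    stop("bases must be basis_fn objects")
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != length(bases))
    stop("need one amplitude per basis")
  structure(list(bases = bases, amplitudes = amplitudes,
                 baseline = as.numeric(baseline)),
            class = "stp_kernel")
}

#' @export
print.stp_kernel <- function(x, ...) {
  desc <- vapply(x$bases, function(b) {
    if (inherits(b, "exp_basis")) sprintf("exp(tau=%gs)", b$tau)
    else sprintf("gauss(mu=%gs, sd=%gs)", b$mu, b$sd)
  }, character(1))
  cat(sprintf("<stp_kernel> baseline %g; %s\n", x$baseline,
              paste(sprintf("%g*%s", x$amplitudes, desc), collapse = " + ")))
  invisible(x)
}

#' Evaluate a kernel (without baseline) at times t
#'
#' @param k An [kernel()] object.
#' @param t Times in seconds.
#' @return Numeric vector \eqn{\sum_l a_l h_l(t)}; exactly 0 for `t <= 0`.
#' @export
kernel_value <- function(k, t) {
  v <- numeric(length(t))
  for (i in seq_along(k$bases))
    v <- v + k$amplitudes[i] * evaluate_basis(k$bases[[i]], t)
  v
}

#' Filter a spike train through a set of basis functions
#'
#' Computes the design matrix of the filtered spike train evaluated strictly
#' causally at each spike: entry (l, j) is
#' \eqn{\sum_{i<j} h_l(t_j - t_i)}. The first row is the constant basis
#' (all 1), so that a coefficient vector `c(b, a_1, ..., a_L)` applied to
#' the matrix yields the potential \eqn{k*S(t_j) + b}. Exponential bases are
#' evaluated event-driven by per-spike recursive decay
#' (\eqn{x_{j+1} = (x_j + 1/\tau) e^{-\Delta t_j/\tau}}), which is exact; no
#' time grid is involved.
#'
#' @param bases List of basis objects, or an [kernel()] (its bases are used).
#' @param train A [spike_train()].
#' @return An object of class `filtered_train` with elements `X`
#'   (matrix, `length(bases) + 1` rows x spikes columns; row 1 constant),
#'   `train` and `bases`.
#' @export
filter_at_spikes <- function(bases, train) {
  if (inherits(bases, "stp_kernel")) bases <- bases$bases
  if (inherits(bases, "basis_fn")) bases <- list(bases)
  tj <- train$times
  n <- length(tj)
  X <- matrix(0, nrow = length(bases) + 1L, ncol = n)
  X[1L, ] <- 1
  for (l in seq_along(bases)) {
    b <- bases[[l]]
    if (inherits(b, "exp_basis") && n > 1) {
      x <- numeric(n)            # x[j] = sum_{i<j} h(t_j - t_i)
      d <- exp(-diff(tj) / b$tau)
      for (j in seq_len(n - 1L)) x[j + 1L] <- (x[j] + 1 / b$tau) * d[j]
      X[l + 1L, ] <- x
    } else if (n > 1) {
      dt <- outer(tj, tj, "-")   # dt[j, i] = t_j - t_i
      h <- matrix(evaluate_basis(b, dt), n, n)
      h[dt <= 0] <- 0            # strict causality: i < j only
      X[l + 1L, ] <- rowSums(h)
    }
  }
  rn <- c("const", vapply(seq_along(bases), function(l) paste0("h", l), character(1)))
  rownames(X) <- rn
  structure(list(X = X, train = train, bases = bases), class = "filtered_train")
}

#' Dense kernel-train convolution on a time grid
#'
#' Evaluates \eqn{(k * S)(t) + b} on a uniform grid, for visualization and
#' as a cross-check of the event-driven evaluation. Strictly causal: a spike
#' contributes only at grid times strictly after it.
#'
#' @param k A [kernel()].
#' @param train A [spike_train()].
#' @param dt Grid step in seconds (> 0).
#' @param t_end End of the grid in seconds (defaults to the train duration).
#' @return A data.frame with columns `time` and `value`.
#' @export
convolve_on_grid <- function(k, train, dt, t_end = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(t_end)) t_end <- train$duration
  tg <- seq(0, t_end, by = dt)
  v <- rep(k$baseline, length(tg))
  for (ts in train$times) v <- v + kernel_value(k, tg - ts)
  data.frame(time = tg, value = v)
}
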