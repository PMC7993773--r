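#' Tsodyks-Markram model parameters
#'
#' The four-parameter depletion/facilitation model used as a benchmark.
#' State variables: recovered fraction `R` (vesicle availability) and
#' utilized efficacy `u` (release probability). Between spikes `R` relaxes
#' to 1 with time constant `tau_R` and `u` to `U` with `tau_u`; at each
#' spike `R` is depleted by `u*R` and `u` jumps by `f*(1-u)` (classic) or
#' `u*f*(1-u)` (extended variant, which permits supralinear facilitation at
#' small `u`).
#'
#' @param U Baseline efficacy, in (0, 1).
#' @param f Facilitation constant, in (0, 1).
#' @param tau_u Facilitation timescale in seconds (> 0).
#' @param tau_R Depression (recovery) timescale in seconds (> 0).
#' @param variant `"classic"` or `"extended"`.
#' @return Object of class `tm_parameters`.
#' @export
tm_parameters <- function(U, f, tau_u, tau_R,
                          variant = c("classic", "extended")) {
  variant <- match.arg(variant)
  if (!is.finite(U) || U <= 0 || U >= 1) stop("U must be in (0, 1)")
  if (!is.finite(f) || f <= 0 || f >= 1) stop("f must be in (0, 1)")
  if (!is.finite(tau_u) || tau_u <= 0) stop("tau_u must be > 0")
  if (!is.finite(tau_R) || tau_R <= 0) stop("tau_R must be > 0")
  structure(list(U = U, f = f, tau_u = tau_u, tau_R = tau_R, variant = variant),
            class = "tm_parameters")
}

#' @export
print.tm_parameters <- function(x, ...) {
  cat(sprintf("<tm_parameters> %s: U=%g f=%g tau_u=%gs tau_R=%gs\n",
              x$variant, x$U, x$f, x$tau_u, x$tau_R))
  invisible(x)
}

#' Spike-triggered facilitation increment of the extended TM model
#'
#' \eqn{g(u) = u f (1 - u)}: increasing for `u < 0.5`, with its maximum at
#' `u = 0.5`, then decreasing — the mechanism by which the extended model
#' produces supralinear facilitation when the baseline `U` is small.
#'
#' @param u Utilized efficacy, in \[0, 1\] (vectorized).
#' @param f Facilitation constant.
#' @return The increment `u * f * (1 - u)`.
#' @export
extended_jump <- function(u, f) {
  if (any(u < 0 | u > 1)) stop("u must be in [0, 1]")
  u * f * (1 - u)
}

#' TM synaptic efficacies by exact integrated maps
#'
#' Evolves the TM state over a spike train using the between-spike
#' integrated updates. Release at spike n uses the pre-jump state:
#' \eqn{\mu_n = R_n u_n} with `R_0 = 1`, `u_0 = U` (no previous
#' activation). The transition to spike n+1 applies the spike-triggered
#' jump and then the exact exponential relaxation over the inter-spike
#' interval \eqn{\Delta t}:
#' \deqn{R_{n+1} = 1 - [1 - R_n(1 - u_n)] e^{-\Delta t/\tau_R}}
#' \deqn{u_{n+1} = U + [u_n^+ - U] e^{-\Delta t/\tau_u}}
#' where \eqn{u_n^+ = u_n + f(1-u_n)} (classic) or
#' \eqn{u_n + u_n f(1-u_n)} (extended).
#'
#' @param params A [tm_parameters()] object.
#' @param train A [spike_train()].
#' @return List with numeric vectors `mu`, `R`, `u` (per spike, pre-jump
#'   values).
#' @export
tm_efficacies <- function(params, train) {
  stopifnot(inherits(params, "tm_parameters"), inherits(train, "spike_train"))
  tj <- train$times
  n <- length(tj)
  R <- u <- mu <- numeric(n)
  Rc <- 1; uc <- params$U
  for (j in seq_len(n)) {
    R[j] <- Rc; u[j] <- uc
    mu[j] <- Rc * uc
    if (j < n) {
      dt <- tj[j + 1] - tj[j]
      u_plus <- if (params$variant == "classic")
        uc + params$f * (1 - uc) else uc + extended_jump(uc, params$f)
      R_plus <- Rc * (1 - uc)
      Rc <- 1 - (1 - R_plus) * exp(-dt / params$tau_R)
      uc <- params$U + (u_plus - params$U) * exp(-dt / params$tau_u)
    }
  }
  list(mu = mu, R = R, u = u)
}

#' Fixed-step ODE integration of the TM model
#'
#' Explicit Euler integration of the continuous TM dynamics
#' \eqn{dR/dt = (1-R)/\tau_R}, \eqn{du/dt = (U-u)/\tau_u} with
#' spike-triggered jumps applied to the left-limit values at spike times
#' (release recorded before the jump). Serves as the independent oracle for
#' [tm_efficacies()]: the two agree in the `dt -> 0` limit.
#'
#' @param params A [tm_parameters()].
#' @param train A [spike_train()].
#' @param dt Integration step in seconds (> 0).
#' @param t_end End time (defaults to just past the last spike).
#' @return List with `time`, `R`, `u` trajectories and per-spike `mu`
#'   (left-limit release values).
#' @export
tm_ode_integrate <- function(params, train, dt, t_end = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  tj <- train$times
  if (is.null(t_end)) t_end <- if (length(tj)) max(tj) + dt else dt
  nstep <- ceiling(t_end / dt) + 1L
  time <- (seq_len(nstep) - 1L) * dt
  R <- u <- numeric(nstep)
  Rc <- 1; uc <- params$U
  mu <- numeric(length(tj))
  next_spike <- 1L
  for (i in seq_len(nstep)) {
    t <- time[i]
    # apply any spikes in (t - dt, t]: release on left limits, then jump
    while (next_spike <= length(tj) && tj[next_spike] <= t + dt / 2) {
      mu[next_spike] <- Rc * uc
      u_plus <- if (params$variant == "classic")
        uc + params$f * (1 - uc) else uc + extended_jump(uc, params$f)
      Rc <- Rc * (1 - uc)
      uc <- u_plus
      next_spike <- next_spike + 1L
    }
    R[i] <- Rc; u[i] <- uc
    Rc <- Rc + dt * (1 - Rc) / params$tau_R
    uc <- uc + dt * (params$U - uc) / params$tau_u
  }
  list(time = time, R = R, u = u, mu = mu)
}
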