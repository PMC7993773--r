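---
title: "Modelling short-term synaptic dynamics with linear-nonlinear cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling short-term synaptic dynamics with linear-nonlinear cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srpdyn)
```

## The model

Synapses transmit action potentials with an efficacy that changes on
10 ms–10 s timescales (short-term plasticity, STP). `srpdyn` implements a
linear-nonlinear cascade description of these dynamics — the Spike Response
Plasticity (SRP) model. A presynaptic spike train
$S(t) = \sum_j \delta(t - t_j)$ is convolved with a strictly causal
*efficacy kernel* $k_\mu(t)$, shifted by a baseline $b_\mu$, and passed
through a sigmoidal readout $f$ to give the mean efficacy of the $j$-th
spike, normalized to the first spike of the train:

$$\mu_j \;=\; \frac{f\!\big(k_\mu * S(t_j) + b_\mu\big)}{f(b_\mu)},
\qquad \mu_1 = 1 .$$

Strict causality means $k_\mu(t) = 0$ for $t \le 0$: a spike influences the
efficacy only strictly after itself, so the first pulse always sees the
baseline alone and $\mu_1 = 1$ holds exactly for any kernel.

Observed response amplitudes are stochastic. Single-synapse amplitude
distributions are right-skewed and unimodal, so the model takes the
amplitude $Y_j$ of pulse $j$ to be gamma-distributed with mean $\mu_j$ and
standard deviation $\sigma_j$ (shape $\mu_j^2/\sigma_j^2$, scale
$\sigma_j^2/\mu_j$), independent across pulses given the train. The SD has
its own cascade — the *variance kernel* $k_\sigma$:

$$\sigma_j \;=\; \sigma_0\, f\!\big(k_\sigma * S(t_j) + b_\sigma\big),$$

with no baseline normalization (only the mean is first-pulse-normalized).
Two reduced variance modes are provided: `proportional`
($\sigma_j = \sigma_0\,\mu_j$, constant coefficient of variation — the
generalized-linear-model special case) and `constant`
($\sigma_j = \sigma_0$). For a kernel-mode model the first-pulse CV is
$\sigma_1/\mu_1 = \sigma_0 f(b_\sigma)$.

### The readout

The readout is described only as sigmoidal by the modelling framework; this
package fixes $f(x) = 1/(1+e^{-x})$ (the logistic). It is strictly
positive — the gamma mean and SD must be positive — smooth, and has both a
supralinear onset and a sublinear saturating regime, which is what lets a
*single* facilitating kernel produce either supralinear or sublinear
facilitation depending only on the baseline:

```{r baseline-switch}
tr <- regular_train(50, 5)                  # 5 pulses at 50 Hz
k <- function(b) kernel(list(exp_basis(0.1)), 0.15, baseline = b)
diff(mean_efficacies(k(-4), tr))            # low baseline: growing increments
diff(mean_efficacies(k(1), tr))             # high baseline: shrinking increments
```

### Kernels and bases

Kernels are linear combinations of causal basis functions. Exponential
bases $h_l(t) = \Theta(t)\,e^{-t/\tau_l}/\tau_l$ are integral-normalized,
so an amplitude $a_l$ has units of potential per spike and the potential
jump contributed by one spike is $a_l/\tau_l$. The default fitting basis
uses $\tau = \{15, 100, 650\}$ ms, a spread that tiles the physiological
STP range; the relative weighting of the bases, not the menu of $\tau$
values, determines the effective timescale. Gaussian bases (normalized
densities truncated at $t = 0$, without renormalization — the truncated
mass is negligible at the multi-second centers they are used for) express
*delayed* facilitation, where the efficacy of a test pulse keeps growing
for seconds after a burst.

A note on units: this package works in seconds throughout. Kernel
amplitudes quoted in the literature for per-millisecond-normalized bases
(e.g. Gaussian amplitudes in the hundreds) convert to this convention by
division by 1000; the delayed-facilitation example in the test suite uses
amplitudes $\{0.125, 0.620, 1.300\}$ for that reason. With
second-normalized bases the raw per-ms numbers would saturate the logistic
numerically.

### The Tsodyks–Markram benchmark

The classic two-state depletion/facilitation model is included for
comparison. Release at spike $n$ uses the pre-jump state,
$\mu_n = R_n u_n$ with $R_0 = 1$, $u_0 = U$, and the state advances by the
exact integrated maps

$$R_{n+1} = 1 - \big[1 - R_n(1-u_n)\big]e^{-\Delta t/\tau_R}, \qquad
u_{n+1} = U + \big[u_n^{+} - U\big]e^{-\Delta t/\tau_u},$$

with $u_n^{+} = u_n + f(1-u_n)$ (classic) or
$u_n^{+} = u_n + u_n f(1-u_n)$ (extended). The classic $u$-map is affine,
so facilitation increments decay geometrically by $(1-f)e^{-\Delta t/\tau_u}$
— facilitation is always sublinear. The extended increment $u f (1-u)$
grows while $u < 1/2$ (maximum exactly at $u = 1/2$) and lets a small $U$
produce supralinear onset. `tm_ode_integrate()` provides a fixed-step
explicit integration with spike-triggered jumps applied to left limits; it
serves as the independent oracle for the integrated maps, and the two agree
to $O(\mathrm{d}t)$.

## Inference

Fitting maximizes the gamma likelihood. Filtering the spike train through
the basis set once yields, per protocol, a design matrix $X$ (constant row
plus one row per basis, one column per spike, evaluated strictly causally —
exactly, by per-spike recursive decay for exponential bases); then
$\boldsymbol\mu = f(X^\top\theta_\mu)/f(b_\mu)$ and
$\boldsymbol\sigma = \sigma_0 f(X^\top\theta_\sigma)$, and the negative
log-likelihood is the sum of per-observation gamma terms. Missing
observations are skipped; non-positive amplitudes (outside the gamma
support) are excluded with a message.

Numerical choices, all overridable:

* **Optimizer**: bounded quasi-Newton (`optim`, L-BFGS-B) with a
  multistart of 256 stratified (Latin-hypercube) start points over the
  bound box by default; the converged start with the lowest NLL wins, ties
  broken by start order. The multistart is seeded, and its provenance
  (start table and per-start objectives) is kept in the `fit_result`.
* **Bounds**: baselines in $[-6, 6]$ and exponential-basis amplitudes with
  per-spike jumps $a/\tau \in [-10, 10]$, keeping the logistic out of flat
  saturation where gradients vanish; $\sigma_0 \in [10^{-3}, 10]$.
* **$\sigma_0$**: free by default; a standardized mode fixes it (e.g. to 1
  after amplitude standardization), which leaves 8 free parameters for a
  3-basis-per-kernel model (two baselines, six amplitudes) instead of 9.
  Both conventions appear in the literature; `n_free_parameters()` reports
  the count either way.
* **TM fitting**: exhaustive grid search minimizing the mean squared error
  between TM predictions and trial-averaged amplitudes, with $U, f$ linear
  over $(0,1)$ and both time constants log-spaced over $[1\,\mathrm{ms},
  10\,\mathrm{s}]$; ties broken by first-in-scan order. MSE is computed on
  trial averages because that is the quantity the deterministic TM model
  predicts. For first-pulse-normalized data the TM prediction is divided
  by its own first-pulse value (`normalize = TRUE`).

## Surrogate data: what it emulates, and what it does not

No experimental recordings ship with the package. `simulate_surrogate()`
generates amplitude tables with exactly the statistical structure the model
assumes: gamma amplitudes, independent across pulses, on a seeded Poisson
train. The reference parameter set (`surrogate_srp_parameters()`) is a
facilitating synapse with mono-exponential $\tau = 100$ ms kernels,
$a_\mu = 0.08$, $b_\mu = -1.0$, $a_\sigma = 0.10$, $b_\sigma = -1.5$,
$\sigma_0 = 1$: per-spike potential jumps of 0.8–1.0 and a first-pulse CV
of $\sigma_0 f(b_\sigma) \approx 0.18$, the same order as fitted kernels
reported for facilitating hippocampal synapses once converted to
second-normalized units. These defaults were fixed once as the package's
study conditions.

Passing recovery tests on such data shows that the estimator is consistent
and well-conditioned *when the model is true*. Real recordings violate the
assumptions in known ways — release failures (zero-inflation), quantal
multimodality, slow drift, correlated noise across pulses — none of which
the generator emulates, so surrogate results bound what can be expected
from real data from above. `noise_correlation()` exists precisely to check
the independence assumption on a given dataset.

The parameter-recovery experiment (`recovery_experiment()`) fits at
training sizes of 100, 500 and 2000 Poisson spikes at 10 Hz, five
replicates each, a single sampled trial per train, and reports relative
parameter errors (both the pooled per-parameter median and the per-fit
mean) and held-out MSE against the true model's own MSE on an independent
500-spike test train. These problem sizes were chosen to make the full
experiment comfortably runnable on a laptop while spanning the regime where
errors fall from tens of percent to below ten percent. The variance-side
parameters ($b_\sigma$, $\sigma_0$) carry the largest errors at any size:
they lie on an anti-correlation ridge of the likelihood (a higher baseline
trades off against a lower scale), which is visible in likelihood-landscape
slices and is an identifiability property of the model, not an optimizer
artifact.

## Heteroskedasticity design choices

With a fixed facilitating $\sigma$-kernel, which direction the CV takes
along a train depends on the baselines. One mathematical fact constrains
the design: the normalized efficacy growth $f(b + x)/f(b)$ is strictly
decreasing in $b$, so if $k_\sigma$, $b_\sigma$ and $\sigma_0$ are all held
fixed, lowering $b_\mu$ can only *decrease* CV growth. Reproducing the
experimentally observed switch — CV rising along the train in the
low-release (supralinear) condition and falling in the high-release
(sublinear) condition — therefore requires the variance baseline to
co-vary with the efficacy baseline, as it plausibly does when extracellular
calcium changes release probability globally. The package's reproduction
uses a shared baseline shift ($b_\sigma = b_\mu + 1$) with a
$\sigma$-kernel somewhat stronger than the $\mu$-kernel:

```{r cv-switch}
tr <- regular_train(100, 5)
cv_at <- function(b) {
  p <- srp_parameters(kernel(list(exp_basis(0.1)), 0.05, baseline = b),
                      kernel(list(exp_basis(0.1)), 0.065, baseline = b + 1),
                      sigma_scale = 1)
  sd_efficacies(p, tr) / mean_efficacies(p, tr)
}
round(cv_at(-4), 4)   # low baseline: CV grows along the train
round(cv_at(2), 4)    # high baseline: CV falls
```

## Degenerate inputs and edge conventions

* Empty trains are legal `spike_train`s; filtering them yields empty design
  matrices and `convolve_on_grid()` returns the bare baseline.
* A single-spike train has all non-constant design entries exactly zero
  (strict causality), so every model predicts $\mu_1 = 1$ there.
* Compound protocols join segments by the convention that the first spike
  of a segment follows the previous segment's last spike by the *incoming*
  segment's inter-spike interval (the recovery-pulse convention); a
  protocol of homogeneous segments is identical to the corresponding
  regular train.
* Sampled amplitudes are strictly positive by construction (gamma
  support); the model has no failure/zero mode — failures are effectively
  replaced by very small releases.
* Hold-out bootstrapping drops whole trials, never individual pulses, and
  errors out rather than fitting if a protocol would lose all trials.

## Limitations

* The efficacy and variance kernels are descriptive filters; their
  timescales are not estimates of the timescales of any specific synaptic
  mechanism.
* Only exponential and Gaussian bases are provided (no raised-cosine or
  spline bases).
* No Bayesian posterior machinery; point estimates with multistart only.
* The gamma likelihood excludes non-positive amplitudes, so datasets where
  failures are recorded as zeros need preprocessing (or a different noise
  model) before fitting.
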