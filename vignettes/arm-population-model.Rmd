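---
title: "Two-state Markov population dynamics of balanced networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state Markov population dynamics of balanced networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(armnet)
```

## The problem

Balanced random networks of excitatory and inhibitory spiking neurons settle
into an asynchronous irregular state in which the population activity
fluctuates around an attractive fixed point. In a network of finite size
these fluctuations are *self-generated*: they arise from the recurrent
dynamics itself, not from an external noise source, and their variance
depends on the instantaneous state of the network. A low-dimensional
description with additive Gaussian noise of fixed amplitude therefore cannot
be adequate. This package implements a self-consistent alternative — a
two-state Markov model per neuron whose population statistics reproduce the
mean-field flow, the state-dependent noise, the E/I cross-correlation and
the heavy-tailed (log-normal) spike-count distribution of the spiking
network — together with the full analysis chain needed to estimate it from
simulated data and to test it.

## The reference spiking network

The reference system (`network_params()` defaults) is the classical
inhibition-dominated balanced network: $N_e = 10{,}000$ excitatory and
$N_i = 2500$ inhibitory leaky integrate-and-fire neurons,

$$\tau \dot v_i(t) = -v_i(t) + \tau \sum_j J_{ij} S_j(t - t_d),$$

with $\tau = 20$ ms, threshold $\theta = 20$ mV, reset $v_r = 10$ mV, 2 ms
absolute refractoriness, delta-pulse synapses of amplitude $J = 0.1$ mV
(excitatory) and $-gJ = -0.6$ mV (inhibitory), fixed in-degree (each neuron
receives input from exactly 10% of either population, drawn without
replacement, self-connections excluded), an independent external Poisson
drive of 25 spikes/ms per neuron with weight $+J$, and a synaptic delay
equal to the 0.01 ms integration step.

The integrator (`simulate_lif()`) advances the membrane by exact exponential
decay between grid points and applies all synaptic and external events at
step boundaries; spikes emitted in a step are delivered one delay later
through a ring buffer. During refractoriness the membrane is clamped at the
reset and arriving events are discarded. Correctness is established in the
test suite against closed-form leak decay, a brute-force fine-step Euler
oracle on a three-neuron motif, and the stationary first-passage (Siegert)
rate of a single Poisson-driven neuron, which the integrator matches to
better than 0.1%. At the reference parameters the network settles at about
31 spikes per 0.1 ms bin in the excitatory population (≈ 31 Hz per neuron),
in agreement with the diffusion-approximation self-consistency equation
solved by `simulate_rate_model()`.

## The observable and its time scale

The central observable is the pair of binned population spike counts
$(S_e(t), S_i(t))$ (`bin_counts()`). The working resolution is $dt = 0.1$
ms: the first zero crossings of the two populations' count autocorrelations
(≈ 0.07 ms inhibitory, ≈ 0.20 ms excitatory at 0.01 ms resolution) bracket
it, and `select_bin_size()` confirms it as the scale at which a first-order
Markov description reproduces the count spectra best — surrogate chains
resampled from the empirical transition matrix (`estimate_transitions()`,
`sample_chain()`) are compared to the source by the mean squared log-power
distance of their Welch spectra. The low-frequency end of the spectrum is
*not* reproduced by any of the Markov descriptions here; that part of the
dynamics depends on a longer history and is a known limit of the approach.
A practical caveat: the excitatory autocorrelation decays onto a small
positive plateau (low-frequency network fluctuations) before crossing
zero, so its interpolated first-crossing lag is an ill-conditioned summary
— on 10 s runs it scatters severalfold across realizations, while the
inhibitory crossing and all count statistics are stable to a few percent.

## The ARM model

In the Active–Refractory Markov (ARM) model each neuron is either *active*
(membrane potential close to threshold) or *refractory* (far from it).
Three rates govern the transitions of a population of size $N$ with $A$
active neurons:

* $\alpha$: refractory → active,
* $\beta$: active → refractory without a spike (the leak branch),
* $\gamma$: active → refractory through spike emission.

Per bin, the outflow is $\Delta A^- \sim \mathrm{Bin}(A, (\beta+\gamma)dt)$,
the spike count is the thinning $S \sim \mathrm{Bin}(\Delta A^-,
\gamma/(\gamma+\beta))$, and the inflow is $\Delta A^+ \sim \mathrm{Bin}(N -
A, \alpha\,dt)$. Both populations share the same rates because every neuron
has the same in-degree; only $N$ differs. The link

$$\alpha = \exp(c_0 + c_1 S_e + c_2 S_i)$$

is evaluated on the spike counts of the *current* bin — the ones just drawn
— and shared by both populations. This sequencing choice matters: the
expected increment given the state then satisfies exactly

$$\dot S = \exp(c_0 + c_1 S_e + c_2 S_i)\,(N \gamma dt - S) -
(\beta+\gamma) S,$$

the two-dimensional mean-field system (`meanfield_rhs()`). Evaluating
$\alpha$ on the previous bin instead breaks the feedback loop: the next
count becomes conditionally independent of the current one given the latent
pools, the reconstructed flow flattens, and none of the model's
distinguishing statistics survive. The exponential (rather than sigmoidal)
form of the link is motivated by the stationary Fokker–Planck density of
the LIF membrane potential: its cumulative distribution is well
approximated by an exponential function of $v$ over a wide band between
reset and threshold (`stationary_density()`, `exponential_cdf_fit()`), and
$\alpha$ is proportional to the probability flux across the (unspecified)
boundary separating the two coarse states. Near threshold the CDF is
sub-exponential and the approximation degrades — visible both in the
analytic density and in the pointwise rate estimates.

Default parameters (`arm_params()`): $c_0 = -0.046$, $c_1 = 0.032$, $c_2 =
-0.152$, $\beta = 7.78$ /ms, $\gamma = 0.325$ /ms at $dt = 0.1$ ms, the
rates estimated from a full-size network run. $\alpha dt$ is clipped to
$[0,1]$ because the exponential link is unbounded; with the default
parameters the clip is hit only in states that are essentially never
visited. Stochastic runs start from the fixed-point occupancy $A^* =
S^*/(\gamma dt)$ and discard a $10^4$-step burn-in.

```{r arm-example}
p <- arm_params()
fixed_point(p)
s <- simulate_arm(p, n_steps = 2e5, seed = 1)
fit_lognormal_counts(s$S_e)
```

## Flow reconstruction and the state-dependent noise

`reconstruct_flow()` treats each joint count pair as a state, assigns the
forward difference $(S(t+dt) - S(t))/dt$ to the left state, and records
per-state visit counts, mean derivatives (the vector field) and unbiased
variances (the noise map). States with fewer than 20 visits are dropped —
below that the variance estimates are unusable. Isoclines
(`extract_isoclines()`) are traced by marching squares on the surface after
an occupancy-weighted 3×3 box smoothing; the excitatory nullcline is
clearly nonlinear, changing the sign of its slope across the state space,
while the inhibitory one is close to linear. The static transfer-function
baseline (`rate_model` functions), which replaces the dynamics by $\tau
\dot r = -r + F(r)$ with the Siegert rate $F$ and Poisson count generation,
produces near-straight nullclines and far too narrow log-count spread — the
contrast that motivates the ARM model in the first place.

Because neurons act independently given the state, the noise is binomial
and its variance scales linearly with population size: conditional on the
occupancy, the E/I variance ratio is exactly $N_e/N_i = 4$, and the
empirical per-state variance ratio of a stationary ARM run
(`variance_ratio()`) computes to ≈ 4 as well. The spiking network's
excitatory noise is several-fold larger than that — the ARM model
systematically underestimates the variance of the larger population, its
main known limitation (pairwise correlations among excitatory neurons are
ignored).

## Parameter estimation

`fit_arm_global()` estimates $(c_0, c_1, c_2, \beta, \gamma)$ by
occupancy-weighted nonlinear least squares of both mean-field components
jointly against the reconstructed flow, sharing one parameter vector across
populations. The optimization is two-staged: a coarse profile over
$(\beta, \gamma)$ — at fixed rates the pointwise $\alpha$ implied by the
excitatory component is log-linear in the counts, so the link coefficients
come from a weighted linear regression — selects the start for a
Levenberg–Marquardt refinement (`minpack.lm`), with $\beta$ and $\gamma$
parameterized on the log scale to keep them positive. On noiseless
model-generated flows the inverse problem is solved to $10^{-6}$. The
companion route (`pointwise_rates()` + `fit_exponential_link()`) solves a
2×2 linear system per state and regresses $\log \hat\alpha$ on the counts;
the two routes agree on the sign structure and approximate magnitudes of
the link.

Two estimation caveats are documented deliberately, because they shape what
the round trip can and cannot recover:

* **Attenuation of the offset.** The flow conditions on the observable
  counts, but the model's state is the latent occupancy $A$; given the
  counts, $A$ is shrunk toward its stationary mean relative to the
  identification $A = S/(\gamma dt)$. On stochastic data this loads mostly
  on $c_0$, which comes out high by roughly $+0.1$–$0.15$ while $c_1, c_2,
  \beta, \gamma$ are recovered well.
* **A shallow $(c_0, \gamma)$ valley.** In the regime where $S \ll N\gamma
  dt$ the product $e^{c_0} \cdot N\gamma dt$ is nearly the only identified
  combination; separating $\gamma$ from $c_0$ relies on the weak curvature
  contributed by rarely visited high-count states. On a 10 s network run
  the profile of the residual sum of squares over $\gamma$ is shallow, and
  the global optimum can sit at a smaller $\gamma$ (with a compensating
  positive $c_0$) than a 100 s run would give; $\beta$ and the link slopes
  $c_1, c_2$ — and their ratio $c_2/c_1 \approx -5$, reflecting the
  synaptic weight ratio $-g$ — are stable. The problem sizes used
  throughout ($10^6$ ARM steps, 10 s of network time) were chosen as the
  smallest runs at which all remaining statistics stabilize.

## Count statistics

`fit_lognormal_counts()` fits a log-normal distribution to integer counts
by maximum likelihood with the discreteness handled explicitly: $P(k) =
F(k+\tfrac12) - F(k-\tfrac12)$ for $k \ge 1$ and $P(0) = F(\tfrac12)$,
where $F$ is the log-normal CDF. Zero bins therefore enter through the
continuity-corrected mass below one half; constant series are reported as
degenerate rather than fitted. Consistency (bias and RMSE shrinking as
$1/\sqrt{n}$) is verified on rounded log-normal draws. Both the spiking
network and the ARM model produce clearly log-normal counts at 0.1 ms
resolution — mean and variance differ strongly, so the counts are not
Poisson — with the ARM's excitatory spread somewhat narrower than the
network's, consistent with its underestimated excitatory noise. For
small-count series (the inhibitory population, mean ≈ 8) the
discrete-aware maximum-likelihood location sits a few percent below what a
fit to the envelope of the log-histogram gives; the two conventions agree
for the excitatory population.

## Numerical choices

* Mean-field integration: fixed-step classical Runge–Kutta (`deSolve`,
  `rk4`) at $dt/10$; halving the step moves endpoints by $< 10^{-6}$.
* Fixed points: bisection (`uniroot`) on the reduced scalar equation in the
  normalized activity $X = S/N$ on $(0, \gamma dt)$; both populations share
  $X^*$ exactly because their equations are identical up to $N$.
* Welch spectra: averaged modified periodograms, Hann window, segment
  length $2^{14}$ bins (shortened to half the series when needed), 50%
  overlap, scaled so the PSD integrates to the series variance; the DC bin
  is dropped.
* Correlation functions: biased (divide-by-$n$) estimator via `stats::acf`
  / `stats::ccf`, guaranteeing positive semidefiniteness and ACF(0) = 1;
  zero crossings are linearly interpolated.
* Fokker–Planck density: the absorbing-boundary stationary solution is
  evaluated as a Gaussian factor times the voltage integral
  $\int_{\max(v, v_r)}^{\theta} e^{(x-\mu)^2/\sigma^2} dx$ computed by
  adaptive quadrature of the *ratio* (stable at large arguments), then
  normalized by trapezoid quadrature on a 2000-point grid spanning
  $[\mu - 8\sigma, \theta]$.
* Siegert transfer rate: the $e^{u^2}(1 + \mathrm{erf}\,u)$ integrand is
  replaced by its asymptotic series for $u < -4$ and the deeply
  subthreshold branch by the leading Kramers tail, avoiding overflow.
* Dead-end states in the empirical chain (observed only as the final
  sample) redirect to the nearest source state in Euclidean state distance.
* Randomness: every simulator takes an explicit integer seed;
  `derive_seed()` expands one run seed into per-component streams.

## What the generator emulates — and does not

All validation data are self-generated. The LIF simulator reproduces the
physics the model is about (balanced E/I recurrence, fixed in-degree,
self-generated state-dependent noise); the synthetic fixtures used by the
tests (a 500-neuron network with $J\sqrt{N}$ and the external drive mean
$\tau J \nu_{ext}$ held fixed, a reference ARM run, a three-state toy
chain) are scaled-down versions of the same conditions. None of this
emulates biological heterogeneity: parameters are homogeneous, delays are
uniform and minimal, synapses are instantaneous, and the input is
stationary. Passing tests therefore demonstrate internal consistency of
the model chain and agreement with the stated network physics, not
generalization to heterogeneous or non-stationary recordings. Multi-network
switching dynamics, conductance synapses, distributed delays and explicit
refractory chains are out of scope.

## A worked pass through the chain

```{r chain, eval = FALSE}
# 1. simulate the reference network (minutes of CPU time)
net <- network_params()
adj <- build_adjacency(net, seed = 7)
spikes <- simulate_lif(net, adj, duration = 10000, seed = 7)

# 2. bin, reconstruct the flow, estimate the ARM rates
counts <- bin_counts(spikes, 0.1)
flow <- reconstruct_flow(counts, min_visits = 20)
fit <- fit_arm_global(flow, n_exc = net$n_exc, n_inh = net$n_inh, dt = 0.1)
summary(fit)

# 3. resimulate from the fitted model and compare statistics
surrogate <- simulate(fit, nsim = 1e6, seed = 1)
fit_lognormal_counts(surrogate$S_e)
plot(extract_isoclines(flow, "exc", levels = 0))
plot(extract_isoclines(reconstruct_flow(surrogate), "exc", levels = 0),
     add = TRUE, col = "red")
```
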