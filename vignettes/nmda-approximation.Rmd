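---
title: "Aggregated NMDA dynamics in spiking networks: model, approximation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated NMDA dynamics in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdanet)
```

## The problem

NMDA-receptor-mediated currents have a slow decay (about 100 ms) that makes
them the backbone of persistent activity in attractor models of working
memory and decision making. In the standard kinetic formulation, each
presynaptic neuron $j$ drives a gating variable through a two-variable
system

$$\frac{dS_j}{dt} = -\frac{S_j}{\tau_d} + \alpha\, x_j\,(1 - S_j), \qquad
  \frac{dx_j}{dt} = -\frac{x_j}{\tau_r} + \sum_k \delta(t - t_j^k),$$

with the postsynaptic current
$I_\mathrm{NMDA} = g_\mathrm{NMDA}\,(V - V_E)\,B(V)\sum_j w_j S_j$ gated by
the magnesium-block factor $B(V) = 1/(1 + [\mathrm{Mg}^{2+}]
e^{-0.062 V}/3.57)$. Because the $(1 - S_j)$ saturation makes the system
nonlinear, the weighted sum $\sum_j w_j S_j$ cannot be maintained as a
single aggregated state: a general implementation must integrate one pair
of equations per synapse, which scales quadratically with network size.
Only fully connected networks with identical delays escape this, because
there the sum over presynaptic gating variables is the same for every
target and can be computed once globally.

## The jump approximation

The package implements an approximation that replaces the finite rise with
an instantaneous, history-dependent jump. Between spikes the approximate
variable decays as $\hat S_j(t) = S_\mathrm{post} e^{-t/\tau_d}$; the
post-spike value is fixed by requiring
$\lim_{t\to\infty} S_j(t)/\hat S_j(t) = 1$, i.e. the approximation is
asymptotically equal to the exact solution of the two-variable system
started from $x_j = 1$. Carrying out the matching integral with the
substitution $u = \alpha\tau_r e^{-t'/\tau_r}$ yields

$$S_\mathrm{post} = k_0 + k_1' S_j(t^-), \qquad
  k_0 = (\alpha\tau_r)^{\tau_r/\tau_d}\,
        \gamma\!\left[1 - \tfrac{\tau_r}{\tau_d},\, \alpha\tau_r\right],
  \qquad k_1' = e^{-\alpha\tau_r},$$

where $\gamma$ is the **unnormalized** lower incomplete gamma function.
`jump_constants()` computes it as `pgamma(x, s) * gamma(s)`; the test suite
cross-checks this against adaptive quadrature of the defining integral and
against the alternating series, because a silent confusion between the
regularized and unnormalized conventions is the most likely implementation
error. The derivation requires $\tau_r < \tau_d$ (the gamma argument
$1 - \tau_r/\tau_d$ must be positive) and the constructor enforces it.

The *change* transmitted to postsynaptic neurons at a spike is
$\Delta S_j = k_0 + k_1 S_j(t^-)$ with $k_1 = k_1' - 1 \in (-1, 0]$. Since
the between-event dynamics are now linear, every postsynaptic neuron can
maintain a single aggregated variable
$dS/dt = -S/\tau_d + \sum_{j,k} \Delta S_j\, \delta(t - t_j^k)$, whatever
the connectivity or delay structure. The jump magnitude shrinks as $S_j$
grows, so the single-synapse variable saturates — at the jump-map fixed
point $k_0/(-k_1) \approx 1.026$ for the default parameters, slightly above
the exact model's hard ceiling of 1. The approximate variable is therefore
no longer interpretable as a literal open-channel fraction; the error it
introduces is an instantaneous overshoot that decays on the $\tau_r$ time
scale, which is why the approximate current is transiently *larger* in
magnitude than the exact one after every spike.

The exact model's rise variable $x_j$ is uncapped and accumulates across
spikes ($x_j \mathrel{+}= 1$ per spike). The approximation assumes $x_j$
has decayed before the next spike; this assumption is never imposed on the
exact model.

## Numerical scheme

Neurons are conductance-based leaky integrate-and-fire units advanced on a
fixed grid ($dt = 0.1$ ms by default). Within each grid interval the
membrane potential is integrated with an embedded Fehlberg 4(5) pair and
adaptive substeps confined to the interval (absolute and relative tolerance
$10^{-6}$, initial substep $dt/10$, the accepted step size persisting
across intervals). Spikes are checked **only at grid points** — grid-based spike detection is
part of the method's definition, so fidelity wins over accuracy here — and the
refractory clamp lasts a whole number of grid steps
($\lceil t_\mathrm{ref}/dt \rceil$).

Three numerical choices are worth recording:

* AMPA, GABA and aggregated NMDA gating are linear between events, so they
  enter the membrane equation through exact exponential propagators rather
  than being co-integrated, removing one source of error. With a clamp
  drive $D$ the propagator becomes
  $S(t) = (S_0 - D\tau_d)e^{-t/\tau_d} + D\tau_d$.
* In the exact backends the per-source gating variables are integrated
  first over the interval (with $x$ substituted in closed form), and the
  weighted NMDA sum entering the membrane equation is interpolated linearly
  between the interval endpoints. The induced error is far below the
  integrator tolerance because $S$ varies on the 100 ms scale while
  $dt = 0.1$ ms.
* The magnesium-block exponential is evaluated from a linearly
  interpolated table at 0.01 mV spacing (relative error about $5\times
  10^{-8}$); membrane trajectories are insensitive to this at the $10^{-6}$
  tolerance, and identical spike trains are produced at tolerances from
  $10^{-4}$ to $10^{-8}$.

Simultaneous events at one grid point are applied in neuron-id order; the
aggregated update is additive, so the result is order-independent. Event
order within a step is: deliver arrivals, integrate, threshold check,
queue outgoing spikes at $t + \mathrm{delay}$ (delays are per-connection
constants on the grid, handled by ring buffers — heterogeneous delays are
exactly the case the aggregation exists for).

Two exact backends exist. `"exact"` uses the shared-source optimization
(one $(S, x)$ pair per presynaptic neuron, block-structured weights),
valid for all-to-all networks with one delay per source — the only regime
where the original model is practical. `"exact_per_synapse"` keeps one pair
per connection and is intended for small oracle tests; both run the same
integration routine, so their agreement (relative error $<10^{-12}$ at
$N = 20$, bit-identical spikes) checks the aggregation argument, not
floating-point luck.

## The decision-making network

The bundled `decision_network()` is the classic winner-take-all circuit:
two selective excitatory populations A and B (fraction $f = 0.15$ each of
$N_E = 1600$), a nonselective population, and $N_I = 400$ interneurons,
fully connected, with potentiated intra-selective weights $w_+ = 1.7$ and
depressed weights $w_- = 1 - f(w_+ - 1)/(1 - f) \approx 0.876$ elsewhere
into the selective populations. Every neuron receives an independent
2400 spikes/s Poisson background onto AMPA receptors; during the stimulus
window (1–3 s) the selective populations additionally receive Poisson
drives at rates $\mu_{A,B} = \mu_0 \pm \rho\,c'$ ($\mu_0 = 40$ sp/s,
$\rho = 0.4$ sp/s per % coherence), resampled every 50 ms from a Gaussian
with 4 sp/s standard deviation and clipped at zero. The winner is the
selective population with the higher mean 50-ms-binned rate over the final
500 ms, with a 5 sp/s dead band below which the trial counts as undecided.
The 500 ms window and the dead band are this package's operationalization
of picking the population with the highest post-stimulus activity.

### Parameter choices that required a decision

Four parameter values could not be taken at face value:

* **$w_-$**: two forms of the depressed-weight formula circulate,
  $1 - f(w_+-1)(1-f)$ and Wang (2002)'s $1 - f(w_+-1)/(1-f)$. The division form is the
  default (`w_minus()`), the product form is available via
  `literal = TRUE`.
* **External AMPA conductance and reversal potentials** are not part of
  the commonly printed parameter table; Wang (2002)'s values are used
  ($g_\mathrm{AMPA,ext} = 2.1/1.62$ nS, $V_E = 0$, $V_I = -70$ mV).
  Without a separate external conductance the stated background rate
  cannot drive any activity.
* **$\tau_\mathrm{GABA}$ and the interneuron capacitance**: the printed
  values (2 ms, 250 pF) produce a network with *no* stable low-rate
  spontaneous state — excitatory rates sit near 29 sp/s and the symmetric
  state collapses into a decision attractor within a second with no
  stimulus, so stimulus-driven decision making cannot be reproduced. With
  Wang (2002)'s values (5 ms, 200 pF) the spontaneous state is
  stable at the expected rates (about 3 sp/s excitatory, 8 sp/s
  inhibitory at full scale) and the psychometric behaviour emerges.
  However, the *sparse-network fragility* result — the asymmetric state
  destabilizing at 95% connectivity with $1/0.95$ conductance scaling — is
  expressed **only under the printed values**, and robustly so, while
  under the Wang (2002) values the asymmetric state survives 95%
  connectivity at both full and quarter scale. The two experiment families
  evidently used different parameter sets. The package therefore exposes
  both as `variant = "wang2002"` (default; used for decision trials and
  psychometrics) and `variant = "printed"` (default for
  `run_sparse_clamp()`), rather than pretending one set does both jobs.

### Scaling

`scale_network()` multiplies population sizes by a factor and divides the
recurrent receptor conductances by it, preserving the mean recurrent drive;
the external-drive conductance is untouched. The quarter-scale network
($N_E = 400$, $N_I = 100$) is the default test scale: recurrent
fluctuations are four times stronger than at full scale, so decisions are
noisier and spontaneous transitions somewhat more likely, but the
winner-take-all structure, zero-coherence symmetry and coherence-dependent
accuracy are preserved. Full-scale configurations build and run with the
same code; the psychometric experiment at its original size (400 trials
per coherence, full scale) is a cluster-scale computation and is replaced
in the routine suite by Weibull parameter recovery on synthetic Bernoulli
outcomes of the same size.

## The sparse-network clamp protocol

To probe which connectivities support decision making without waiting for
a stimulus-driven transition, the outgoing NMDA connections of the
selective populations are replaced, for the first two seconds, by a
constant drive added to each target's aggregated gating equation:
population A is clamped "to 1", population B "to 0", so the drive is
$D_X = N_A\,\epsilon_{AX}\,w_{AX}/\tau_d$, whose linear steady state
$D_X \tau_d$ is exactly the weighted sum the target would receive if every
$S_j$ in A were 1. (The printed drive formula carries a conductance factor
that is dimensionally inconsistent with the conductance-free gating
variable; the steady-state-matching form is the default and the literal
form is available via `include_conductance = TRUE`.) At release the
constant is removed, event delivery resumes, and the network either
relaxes into the asymmetric state ($E[S_A] > E[S_B]$ over seconds 4–6) or
loses it. AMPA connections from the selective populations remain active
throughout; delivery suppression applies at arrival time.

Sparse connectivity uses a fixed in-degree rule: each target draws exactly
$\mathrm{round}(\epsilon N_\mathrm{src})$ distinct partners without
replacement (no multapses, no autapses within a population; rounding to
nearest is this package's choice where the rule's rounding is unstated).
All-to-all connectivity *includes* autapses — that convention is what
reproduces the stated synapse count of the scaled benchmark network
(754,974,720 at 10.24× scale with paired AMPA/NMDA synapses).

The full connectivity sweep (33×33 grid, 8 seeds, full scale) is
cluster-scale; `run_connectivity_sweep()` defaults to a 5×5 grid with 2
seeds at quarter scale and accepts the full grid by argument.

## What the synthetic inputs do and do not emulate

All inputs are generated internally: background and stimulus drives are
independent per-neuron Bernoulli-per-bin Poisson processes (at most one
spike per 0.1 ms bin — indistinguishable from Poisson at the rates used,
but with slightly sub-Poisson bin counts at extreme rates), and stimulus
rate noise is Gaussian, piecewise constant over 50 ms, independent across
the two populations. Shared-input correlations, rate adaptation, and any
structure in real sensory drive are absent. Passing tests therefore
validate the simulator and the approximation against the model's own
definition, not against biological recordings.

## Problem sizes used by the routine test suite

The suite runs the single-neuron error characterization on a 4×4
(weight, $n_\mathrm{pre}$) grid at 10 s per cell with a 20 sp/s
presynaptic rate ($n_\mathrm{pre}$ up to 800, total input spanning
$2$–$1.6\times10^6$ sp/s); zero-coherence symmetry over 100 quarter-scale
trials; psychometric monotonicity at $c' \in \{1, 10, 40\}$ with 50 trials
each; and the clamp protocol at quarter scale with 8 seeds per
connectivity condition. These sizes were chosen so the full suite
completes on a single workstation core while keeping every stochastic
check at a sample size where its expected effect exceeds its sampling
noise by a comfortable margin.

## Known limitations

* The exact network backend is restricted to all-to-all block-weighted
  connectivity with one delay per source (the shared-source optimization);
  arbitrary-connectivity exact simulation exists only per-synapse and is
  quadratically expensive by nature — that cost is the approximation's
  reason to exist.
* Spike times are quantized to the grid (no within-step threshold
  interpolation), matching the stated method; comparisons against
  continuous-time integrators will show $O(dt)$ spike-time offsets.
* No spike-frequency adaptation, synaptic plasticity, or multi-compartment
  structure.
* Wall-clock benchmark comparisons against other simulators are out of
  scope; the package documents algorithmic complexity, not hardware
  timings.
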