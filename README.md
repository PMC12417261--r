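# nmdanet

Spiking-network simulation with exact and jump-approximated
NMDA-receptor-mediated currents, for computational neuroscientists studying
attractor dynamics — working memory, winner-take-all decision making — in
conductance-based leaky integrate-and-fire networks.

## The problem and the method

NMDA receptor gating in the standard kinetic model follows, per presynaptic
neuron *j*,

    dS_j/dt = -S_j/tau_d + alpha * x_j * (1 - S_j)
    dx_j/dt = -x_j/tau_r + sum_k delta(t - t_j^k)

and the postsynaptic current is `g_NMDA (V - V_E) B(V) sum_j w_j S_j` with
the magnesium block `B(V) = 1/(1 + [Mg2+] exp(-0.062 V)/3.57)`. The
`(1 - S_j)` saturation makes the system nonlinear, so the weighted sum
cannot be simulated as one aggregated variable: general connectivity
requires one equation pair per synapse — quadratic in network size.

The package implements an asymptotically matched approximation: between
spikes the gating variable decays as a pure exponential with `tau_d`, and
at each presynaptic spike it jumps by

    Delta S_j = k0 + k1 * S_j(t-)
    k0 = (alpha*tau_r)^(tau_r/tau_d) * gamma(1 - tau_r/tau_d, alpha*tau_r)
    k1 = exp(-alpha*tau_r) - 1

where `gamma` is the unnormalized lower incomplete gamma function. The
transmitted `Delta S_j` updates a single aggregated variable per
postsynaptic neuron, `dS/dt = -S/tau_d + sum Delta S_j delta(t - t_j)`,
valid for arbitrary connectivity and delay distributions. Both the exact
two-variable model and the approximation are provided as simulation
backends, together with the classic four-population binary decision-making
network, sparse fixed-in-degree connectivity, an S_NMDA clamp protocol,
and analysis tools (binned population rates, Weibull psychometric fits,
bootstrap confidence intervals).

## Worked example

```r
library(nmdanet)

# jump constants for the default kinetics (alpha = 0.5/ms, tau_r = 2 ms,
# tau_d = 100 ms)
jc <- jump_constants(gating_params())
jc$k0                    # 0.6484167
jc$k1                    # -0.6321206
gating_fixed_point(jc)   # 1.02578  -- saturation ceiling, slightly above 1

# quarter-scale decision network: 60+60 selective, 280 nonselective,
# 100 inhibitory neurons, fully connected
spec <- decision_network(scale = 0.25)
count_synapses(spec)     # 450000
count_synapses(scale_network(decision_network(f = 0), 10.24))  # 754974720

# one decision trial at 40% coherence (stimulus from 1 to 3 s)
tr <- run_decision_trial(spec, coherence = 40, seed = 3)
tr$winner                # "A"
tr$rate_A                # 38.8  spikes/s over the final 500 ms
tr$rate_B                # 0.63
```

The trial output means: population A (which receives the stronger
stimulus at positive coherence) settled into the high-activity attractor
state at about 39 spikes/s while population B was suppressed below one
spike/s — a correct decision. At `coherence = 0` the two populations win
with equal probability; accuracy rises with coherence along a Weibull-like
psychometric curve (`run_psychometric()`).

The exact-vs-approximate error characterization
(`run_error_experiment()`, `run_error_grid()`) feeds identical spike
trains to one neuron of each kind: the NMDA current error jumps at each
arrival and decays on the `tau_r` scale, and the voltage RMS difference
stays in the 1e-5 to 3e-2 mV range until the neuron starts firing, then
grows by two orders of magnitude as spike times shift.

A command-line wrapper with subcommands (`error-experiment`,
`decision-trial`, `psychometric`, `sparse-clamp`, `sweep`) is installed at
`inst/cli/nmdanet`.

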