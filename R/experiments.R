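#' Exact-vs-approximate error characterization for one neuron
#'
#' Two postsynaptic neurons — one integrating the exact two-variable NMDA
#' kinetics per source, one the aggregated jump approximation — receive
#' bit-identical Poisson input spike trains on their NMDA receptors.
#' Returns the signed current error (exact minus approximate), the
#' membrane-potential error, and the RMS of the voltage difference.
#'
#' @param n_pre number of presynaptic Poisson sources.
#' @param nu_pre per-source firing rate (spikes/s).
#' @param weight synaptic weight applied to every source.
#' @param T_total simulated time (ms).
#' @param seed seed for the input trains.
#' @param params postsynaptic \code{\link{neuron_params}}.
#' @param dt grid step (ms).
#' @return List with \code{time}, \code{I_error} (pA), \code{V_error} (mV),
#'   \code{rms} (mV), the two full results \code{exact} and \code{approx},
#'   and \code{spiking} (TRUE if either neuron fired).
#' @export
run_error_experiment <- function(n_pre, nu_pre, weight, T_total = 10000,
                                 seed = 1L, params = neuron_params(),
                                 dt = 0.1) {
  stopifnot(n_pre >= 1, nu_pre >= 0, T_total > 0)
  trains <- withr_seed(seed, {
    lapply(seq_len(n_pre), function(...) poisson_train(nu_pre, T_total, dt))
  })
  exact <- integrate_neuron(params, T_total, dt, input = trains,
                            weight = weight, backend = "exact")
  approx <- integrate_neuron(params, T_total, dt, input = trains,
                             weight = weight, backend = "approximate")
  list(time = exact$time,
       I_error = exact$I_NMDA - approx$I_NMDA,
       V_error = exact$V - approx$V,
       rms = rms_difference(exact$V, approx$V),
       exact = exact, approx = approx,
       spiking = length(exact$spikes) + length(approx$spikes) > 0)
}

#' RMS error grid over weight and presynaptic population size
#'
#' Runs \code{\link{run_error_experiment}} over a (weight, n_pre) grid at a
#' fixed presynaptic rate, recording the voltage-difference RMS and whether
#' the postsynaptic neuron fired. The total input of a cell is
#' \code{n_pre * nu_pre * weight}.
#'
#' @param weights weight grid.
#' @param n_pres presynaptic-count grid.
#' @param nu_pre per-source rate (spikes/s).
#' @param T_total duration per cell (ms).
#' @param seed base seed; each cell uses an offset substream.
#' @return Data frame with one row per cell: \code{weight}, \code{n_pre},
#'   \code{total_input}, \code{rms}, \code{spiking}.
#' @export
run_error_grid <- function(weights = c(0.1, 1, 10, 100),
                           n_pres = c(1, 10, 100, 800), nu_pre = 20,
                           T_total = 10000, seed = 1L) {
  grid <- expand.grid(weight = weights, n_pre = n_pres)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ex <- run_error_experiment(grid$n_pre[i], nu_pre, grid$weight[i],
                               T_total, seed = seed + i)
    data.frame(weight = grid$weight[i], n_pre = grid$n_pre[i],
               total_input = grid$n_pre[i] * nu_pre * grid$weight[i],
               rms = ex$rms, spiking = ex$spiking)
  })
  do.call(rbind, rows)
}

#' Run one decision trial
#'
#' Simulates the full decision protocol: background drive throughout,
#' selective stimulus during its window, free evolution afterwards. The
#' winner is the selective population with the higher mean 50-ms-binned
#' activity over the final window \code{decision_window}; if the two means
#' differ by less than \code{dead_band} spikes/s the trial is undecided
#' ("none").
#'
#' @param spec a \code{network_spec} (see \code{\link{decision_network}}).
#' @param coherence stimulus coherence c' (percent).
#' @param seed master seed for the trial.
#' @param backend simulation backend.
#' @param T_total trial duration (ms).
#' @param stimulus optional \code{\link{stimulus_spec}} override.
#' @param decision_window window for the winner rule (ms).
#' @param dead_band minimum rate difference for a decision (spikes/s).
#' @param record_every gating-trace cadence (ms).
#' @return List of class \code{trial_result}: \code{winner} ("A", "B" or
#'   "none"), \code{rate_A}, \code{rate_B} (mean final rates, spikes/s),
#'   \code{pop_activity} (50-ms binned rates per population), \code{spikes},
#'   \code{S_A}, \code{S_B} traces, and the raw simulation result.
#' @export
run_decision_trial <- function(spec, coherence, seed = 1L,
                               backend = c("approximate", "exact",
                                           "exact_per_synapse"),
                               T_total = 4000, stimulus = NULL,
                               decision_window = c(3500, 4000),
                               dead_band = 5, record_every = 1) {
  backend <- match.arg(backend)
  if (is.null(stimulus)) stimulus <- stimulus_spec(coherence = coherence)
  sim <- simulate_network(spec, T_total, seed = seed, backend = backend,
                          stimulus = stimulus, record_every = record_every)
  acts <- lapply(names(sim$sizes), function(lab) {
    binned_population_rate(sim$spikes, population_ids(sim, lab), 50, T_total)
  })
  names(acts) <- names(sim$sizes)
  in_win <- function(df) {
    df$rate[df$time > decision_window[1] & df$time < decision_window[2]]
  }
  rate_A <- mean(in_win(acts[["A"]]))
  rate_B <- mean(in_win(acts[["B"]]))
  winner <- if (abs(rate_A - rate_B) < dead_band) "none"
            else if (rate_A > rate_B) "A" else "B"
  structure(list(winner = winner, rate_A = rate_A, rate_B = rate_B,
                 coherence = coherence, seed = seed, backend = backend,
                 pop_activity = acts,
                 S_A = population_mean_gating(sim, "A"),
                 S_B = population_mean_gating(sim, "B"),
                 spikes = sim$spikes, sim = sim),
            class = "trial_result")
}

#' Psychometric curve from repeated decision trials
#'
#' Runs \code{n_trials} trials per coherence level and reports the
#' proportion of correct decisions (population A winning, since for
#' \eqn{c' > 0} it receives the stronger stimulus) with percentile
#' bootstrap confidence intervals.
#'
#' @param spec a \code{network_spec}.
#' @param coherences coherence levels (percent), all > 0.
#' @param n_trials trials per level.
#' @param seed base seed; trial \code{i} at level \code{j} uses a
#'   deterministic offset.
#' @param backend simulation backend.
#' @param T_total trial duration (ms).
#' @param ci_level,ci_resamples bootstrap settings.
#' @return Data frame with one row per coherence: \code{coherence},
#'   \code{n_trials}, \code{n_correct}, \code{n_undecided},
#'   \code{p_correct}, \code{ci_low}, \code{ci_high}. The per-trial winners
#'   are attached as attribute \code{"winners"}.
#' @export
run_psychometric <- function(spec, coherences = c(1, 5, 10, 20, 40),
                             n_trials = 50, seed = 1L,
                             backend = "approximate", T_total = 4000,
                             ci_level = 0.9, ci_resamples = 5000) {
  stopifnot(all(coherences > 0), n_trials >= 1)
  winners <- matrix("", nrow = n_trials, ncol = length(coherences))
  rows <- lapply(seq_along(coherences), function(j) {
    for (i in seq_len(n_trials)) {
      tr <- run_decision_trial(spec, coherences[j],
                               seed = seed + 1000L * j + i,
                               backend = backend, T_total = T_total,
                               record_every = 0)
      winners[i, j] <<- tr$winner
    }
    correct <- winners[, j] == "A"
    ci <- bootstrap_ci(correct, ci_resamples, ci_level,
                       seed = seed + 7L * j)
    data.frame(coherence = coherences[j], n_trials = n_trials,
               n_correct = sum(correct),
               n_undecided = sum(winners[, j] == "none"),
               p_correct = mean(correct), ci_low = ci[["low"]],
               ci_high = ci[["high"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "winners") <- winners
  out
}

#' Sparse-network clamp protocol
#'
#' For the first two seconds the outgoing NMDA connections of the selective
#' populations are replaced by the constant clamp drive (population A
#' clamped to 1, population B to 0); at release the network evolves freely
#' under background drive only. Reports the population-averaged gating
#' traces \eqn{S_A(t)}, \eqn{S_B(t)} and their time-averaged expectations
#' over \code{expect_window}, averaged over seeds.
#'
#' @param eps_selective intra-selective connectivity
#'   (\eqn{\epsilon_{AA} = \epsilon_{BB}}).
#' @param eps_inhibitory inhibitory-to-selective connectivity.
#' @param epsilon base connectivity for all other pairs.
#' @param seeds integer vector of seeds (one simulation each).
#' @param scale network scale factor.
#' @param T_total duration (ms), >= the expectation window end.
#' @param t_release clamp release time (ms).
#' @param expect_window window for the time-averaged expectations (ms).
#' @param conductance_scale extra multiplier applied to recurrent
#'   conductances (e.g. \code{1/0.95} for the 95%-connectivity run);
#'   1 leaves the standard values untouched.
#' @param variant neuron-parameter variant. This protocol defaults to the
#'   "printed" parameter column, under which the connectivity fragility of
#'   the asymmetric state is expressed; see \code{\link{neuron_params}} and
#'   the methods vignette.
#' @return List with \code{E_S_A}, \code{E_S_B}, \code{E_diff} (per-seed
#'   vectors), their means, and the traces per seed.
#' @export
run_sparse_clamp <- function(eps_selective = 1, eps_inhibitory = 1,
                             epsilon = 1, seeds = 1:8, scale = 1,
                             T_total = 6000, t_release = 2000,
                             expect_window = c(4000, 6000),
                             conductance_scale = 1, variant = "printed") {
  spec <- decision_network(scale = scale, epsilon = epsilon,
                           eps_selective = eps_selective,
                           eps_inhibitory = eps_inhibitory,
                           variant = variant)
  if (conductance_scale != 1) {
    for (i in seq_along(spec$populations)) {
      for (g in c("g_AMPA", "g_GABA", "g_NMDA"))
        spec$populations[[i]]$params[[g]] <-
          spec$populations[[i]]$params[[g]] * conductance_scale
    }
  }
  clamp <- clamp_spec(high = "A", low = "B", t_release = t_release)
  traces <- vector("list", length(seeds))
  e_a <- e_b <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_network(spec, T_total, seed = seeds[i],
                            backend = "approximate", clamp = clamp,
                            record_every = 1)
    sa <- population_mean_gating(sim, "A")
    sb <- population_mean_gating(sim, "B")
    win <- sa$time >= expect_window[1] & sa$time <= expect_window[2]
    e_a[i] <- mean(sa$S[win])
    e_b[i] <- mean(sb$S[win])
    traces[[i]] <- data.frame(time = sa$time, S_A = sa$S, S_B = sb$S,
                              seed = seeds[i])
  }
  list(E_S_A = e_a, E_S_B = e_b, E_diff = e_a - e_b,
       mean_E_S_A = mean(e_a), mean_E_diff = mean(e_a - e_b),
       traces = traces, seeds = seeds,
       eps_selective = eps_selective, eps_inhibitory = eps_inhibitory)
}

#' Connectivity sweep of the sparse clamp protocol
#'
#' Iterates \code{\link{run_sparse_clamp}} over a grid of intra-selective
#' and inhibitory-selective connectivities at a fixed base connectivity,
#' with recurrent conductances kept at their standard values.
#'
#' @param eps_selective,eps_inhibitory grid values in (0, 1].
#' @param epsilon base connectivity.
#' @param seeds seeds per grid point.
#' @param scale network scale factor.
#' @param ... further arguments to \code{\link{run_sparse_clamp}}.
#' @return Data frame with one row per grid point: the two connectivities,
#'   \code{E_S_A} and \code{E_diff} (seed-averaged).
#' @export
run_connectivity_sweep <- function(eps_selective = seq(0.2, 1, length.out = 5),
                                   eps_inhibitory = seq(0.2, 1,
                                                        length.out = 5),
                                   epsilon = 0.2, seeds = 1:2, scale = 0.25,
                                   ...) {
  grid <- expand.grid(eps_selective = eps_selective,
                      eps_inhibitory = eps_inhibitory)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- run_sparse_clamp(grid$eps_selective[i], grid$eps_inhibitory[i],
                          epsilon = epsilon, seeds = seeds, scale = scale,
                          ...)
    data.frame(eps_selective = grid$eps_selective[i],
               eps_inhibitory = grid$eps_inhibitory[i],
               E_S_A = r$mean_E_S_A, E_diff = r$mean_E_diff)
  })
  do.call(rbind, rows)
}
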