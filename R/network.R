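#' Population specification
#'
#' @param name population label.
#' @param size number of neurons (>= 0; empty populations are dropped at
#'   build time).
#' @param kind "excitatory" or "inhibitory"; determines which receptors the
#'   population's outgoing connections target (AMPA+NMDA vs GABA).
#' @param params a \code{\link{neuron_params}} object; defaults to the kind's
#'   standard column.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(name, size, kind = c("excitatory", "inhibitory"),
                            params = NULL) {
  kind <- match.arg(kind)
  stopifnot(size >= 0, size == round(size))
  if (is.null(params)) params <- neuron_params(kind)
  structure(list(name = name, size = as.integer(size), kind = kind,
                 params = params), class = "population_spec")
}

#' Connectivity specification between two populations
#'
#' @param source,target population labels.
#' @param weight dimensionless synaptic weight.
#' @param delay transmission delay (ms); must be a positive multiple of the
#'   grid step.
#' @param rule "all_to_all" (autapses included when source == target) or
#'   "fixed_indegree" (each target draws exactly \code{round(epsilon * N_src)}
#'   distinct sources without replacement; no multapses, no autapses).
#' @param epsilon in-degree fraction for \code{fixed_indegree}; ignored for
#'   \code{all_to_all}.
#' @return An object of class \code{connectivity_spec}. Excitatory sources
#'   project onto paired AMPA and NMDA receptors, inhibitory sources onto
#'   GABA; the receptor set is resolved from the source population's kind at
#'   build time.
#' @export
connectivity_spec <- function(source, target, weight, delay = 0.5,
                              rule = c("all_to_all", "fixed_indegree"),
                              epsilon = 1) {
  rule <- match.arg(rule)
  stopifnot(weight >= 0, delay > 0, epsilon > 0, epsilon <= 1)
  structure(list(source = source, target = target, weight = weight,
                 delay = delay, rule = rule, epsilon = epsilon),
            class = "connectivity_spec")
}

#' Depressed weight of the decision network
#'
#' The potentiated intra-selective weight \eqn{w_+} is balanced by a
#' depressed weight on connections into a selective population from the
#' other excitatory populations, \eqn{w_- = 1 - f(w_+ - 1)/(1 - f)}
#' (Wang 2002), so that the mean recurrent excitatory drive is independent
#' of \eqn{w_+} in the unstructured state. A variant without the division,
#' \eqn{1 - f(w_+ - 1)(1 - f)}, is available via \code{literal = TRUE}.
#'
#' @param f selective-population fraction.
#' @param w_plus potentiated weight.
#' @param literal use the product form instead of the division form.
#' @return The depressed weight \eqn{w_-}.
#' @export
w_minus <- function(f = 0.15, w_plus = 1.7, literal = FALSE) {
  if (literal) 1 - f * (w_plus - 1) * (1 - f)
  else 1 - f * (w_plus - 1) / (1 - f)
}

#' Build the binary decision-making network specification
#'
#' Four recurrently connected populations: two selective excitatory
#' populations (A and B, each a fraction \code{f} of the excitatory cells),
#' one nonselective excitatory population, and one inhibitory population.
#' All pairs are connected (all-to-all by default, fixed in-degree when
#' \code{epsilon < 1} or selective overrides are given). Intra-selective
#' weights are \code{w_plus}; cross- and nonselective-to-selective weights
#' are \eqn{w_-}; all other weights are 1.
#'
#' @param scale network scale factor: population sizes are multiplied by
#'   \code{scale} and recurrent conductances divided by it (the external
#'   drive conductance is untouched). \code{scale = 1} gives
#'   \eqn{N_E = 1600}, \eqn{N_I = 400}.
#' @param f selective fraction (default 0.15).
#' @param w_plus potentiated weight (default 1.7).
#' @param w_minus_value depressed weight; computed via \code{\link{w_minus}}
#'   when NULL.
#' @param delay synaptic delay (ms, default 0.5).
#' @param dt grid step (ms, default 0.1).
#' @param epsilon base connection probability; 1 means all-to-all.
#' @param eps_selective intra-selective connection probability
#'   (\eqn{\epsilon_{AA} = \epsilon_{BB}}); defaults to \code{epsilon}.
#' @param eps_inhibitory inhibitory-to-selective connection probability
#'   (\eqn{\epsilon_{IA} = \epsilon_{IB}}); defaults to \code{epsilon}.
#' @param nu_ext background Poisson rate per neuron (spikes/s).
#' @param variant neuron-parameter variant, "wang2002" or "printed"; see
#'   \code{\link{neuron_params}}.
#' @return An object of class \code{network_spec}.
#' @examples
#' net <- decision_network(scale = 0.25)
#' count_synapses(decision_network())  # 7.2 million
#' @export
decision_network <- function(scale = 1, f = 0.15, w_plus = 1.7,
                             w_minus_value = NULL, delay = 0.5, dt = 0.1,
                             epsilon = 1, eps_selective = epsilon,
                             eps_inhibitory = epsilon, nu_ext = 2400,
                             variant = c("wang2002", "printed")) {
  variant <- match.arg(variant)
  N_E <- 1600 * scale
  N_I <- 400 * scale
  if (abs(N_E - round(N_E)) > 1e-9 || abs(N_I - round(N_I)) > 1e-9)
    stop("scale must yield integer population sizes")
  N_E <- round(N_E); N_I <- round(N_I)
  N_A <- round(f * N_E)
  N_N <- N_E - 2 * N_A
  if (N_N < 0) stop("f must not exceed 0.5")
  if (is.null(w_minus_value)) w_minus_value <- w_minus(f, w_plus)

  exc <- neuron_params("excitatory", variant)
  inh <- neuron_params("inhibitory", variant)
  for (g in c("g_AMPA", "g_GABA", "g_NMDA")) {
    exc[[g]] <- exc[[g]] / scale
    inh[[g]] <- inh[[g]] / scale
  }
  exc <- validate_neuron_params(exc)
  inh <- validate_neuron_params(inh)

  pops <- list(
    population_spec("A", N_A, "excitatory", exc),
    population_spec("B", N_A, "excitatory", exc),
    population_spec("N", N_N, "excitatory", exc),
    population_spec("I", N_I, "inhibitory", inh))
  pops <- Filter(function(p) p$size > 0, pops)
  labels <- vapply(pops, `[[`, "", "name")

  rule_for <- function(src, tgt, eps) {
    if (eps >= 1) connectivity_spec(src, tgt, weight_for(src, tgt), delay,
                                    "all_to_all")
    else connectivity_spec(src, tgt, weight_for(src, tgt), delay,
                           "fixed_indegree", epsilon = eps)
  }
  weight_for <- function(src, tgt) {
    if (src == tgt && src %in% c("A", "B")) return(w_plus)
    if (tgt %in% c("A", "B") && src %in% c("A", "B", "N")) return(w_minus_value)
    1
  }
  eps_for <- function(src, tgt) {
    if (src == tgt && src %in% c("A", "B")) return(eps_selective)
    if (src == "I" && tgt %in% c("A", "B")) return(eps_inhibitory)
    epsilon
  }
  conns <- list()
  for (src in labels) for (tgt in labels) {
    conns[[length(conns) + 1L]] <- rule_for(src, tgt, eps_for(src, tgt))
  }
  structure(list(populations = pops, connections = conns, dt = dt,
                 f = f, w_plus = w_plus, w_minus = w_minus_value,
                 delay = delay, scale = scale, nu_ext = nu_ext),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  sizes <- vapply(x$populations, `[[`, 0L, "size")
  names(sizes) <- vapply(x$populations, `[[`, "", "name")
  cat("network_spec:", sum(sizes), "neurons (",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), ")\n")
  cat("  f =", x$f, " w_+ =", x$w_plus, " w_- =", round(x$w_minus, 5),
      " delay =", x$delay, "ms  dt =", x$dt, "ms\n")
  cat("  synapses:", format(count_synapses(x), big.mark = ","), "\n")
  invisible(x)
}

pop_sizes <- function(spec) {
  s <- vapply(spec$populations, `[[`, 0L, "size")
  names(s) <- vapply(spec$populations, `[[`, "", "name")
  s
}

pop_index <- function(spec, label) {
  labels <- vapply(spec$populations, `[[`, "", "name")
  i <- match(label, labels)
  if (is.na(i)) stop("unknown population label: ", label)
  i
}

#' Rescale a network specification
#'
#' Population sizes are multiplied by \code{factor} and all recurrent
#' receptor conductances divided by it, approximately preserving the mean
#' recurrent drive; the external-drive conductance is unchanged.
#'
#' @param spec a \code{network_spec}.
#' @param factor positive scale factor yielding integer sizes.
#' @return The rescaled \code{network_spec}.
#' @export
scale_network <- function(spec, factor) {
  stopifnot(inherits(spec, "network_spec"), factor > 0)
  for (i in seq_along(spec$populations)) {
    p <- spec$populations[[i]]
    ns <- p$size * factor
    if (abs(ns - round(ns)) > 1e-9)
      stop("factor yields non-integer size for population ", p$name)
    p$size <- as.integer(round(ns))
    for (g in c("g_AMPA", "g_GABA", "g_NMDA"))
      p$params[[g]] <- p$params[[g]] / factor
    spec$populations[[i]] <- p
  }
  spec$scale <- spec$scale * factor
  spec
}

#' Count synapses in a network
#'
#' One synapse is counted per (connection, receptor) pair: excitatory
#' sources contribute paired AMPA and NMDA synapses, inhibitory sources one
#' GABA synapse. All-to-all connections include autapses.
#'
#' @param spec a \code{network_spec}.
#' @return Total synapse count.
#' @examples
#' count_synapses(decision_network())            # 2000*(2*1600+400) = 7.2e6
#' @export
count_synapses <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- pop_sizes(spec)
  kinds <- vapply(spec$populations, `[[`, "", "kind")
  names(kinds) <- names(sizes)
  total <- 0
  for (cn in spec$connections) {
    n_src <- sizes[[cn$source]]
    n_tgt <- sizes[[cn$target]]
    per_target <- if (cn$rule == "all_to_all") n_src
                  else round(cn$epsilon * n_src)
    n_rec <- if (kinds[[cn$source]] == "excitatory") 2 else 1
    total <- total + n_tgt * per_target * n_rec
  }
  total
}

#' Build the adjacency structure of a network
#'
#' \code{all_to_all} connects every source to every target (autapses
#' included when the populations coincide). \code{fixed_indegree} draws, for
#' every target independently, exactly \code{round(epsilon * N_src)}
#' distinct presynaptic partners uniformly without replacement (no
#' multapses; autapses excluded when source and target populations
#' coincide). Deterministic given the seed.
#'
#' @param spec a \code{network_spec}.
#' @param seed integer seed for the in-degree draws.
#' @return A list with CSR-style fields \code{src_ptr} (length n+1, 0-based
#'   offsets), \code{tgt} (0-based target ids), \code{w}, \code{delay_steps},
#'   plus \code{pop_of} (0-based population index per neuron) and
#'   \code{offsets} (first global id per population, 0-based).
#' @export
build_connectivity <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- pop_sizes(spec)
  n <- sum(sizes)
  offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offsets) <- names(sizes)
  pop_of <- rep(seq_along(sizes) - 1L, sizes)

  # vectorized per-connection edge lists (1-based src/tgt), then one CSR build
  e_src <- list(); e_tgt <- list(); e_w <- list(); e_d <- list()
  withr_seed(seed, {
    for (cn in spec$connections) {
      n_src <- sizes[[cn$source]]
      n_tgt <- sizes[[cn$target]]
      if (n_src == 0 || n_tgt == 0) next
      src0 <- offsets[[cn$source]]
      tgt0 <- offsets[[cn$target]]
      d_steps <- delay_to_steps(cn$delay, spec$dt)
      if (cn$rule == "all_to_all") {
        src <- rep(src0 + seq_len(n_src), each = n_tgt)
        tgt <- rep(tgt0 + seq_len(n_tgt), times = n_src)
      } else {
        same <- cn$source == cn$target
        k_in <- round(cn$epsilon * n_src)
        avail <- n_src - if (same) 1L else 0L
        if (k_in > avail)
          stop("requested in-degree ", k_in, " exceeds available sources (",
               avail, ") for ", cn$source, " -> ", cn$target)
        if (k_in == 0) next
        draws <- vapply(seq_len(n_tgt), function(tt) {
          cand <- if (same) seq_len(n_src)[-tt] else seq_len(n_src)
          if (k_in == length(cand)) cand
          else cand[sample.int(length(cand), k_in)]
        }, integer(k_in))
        src <- src0 + as.integer(draws)
        tgt <- rep(tgt0 + seq_len(n_tgt), each = k_in)
      }
      m <- length(src)
      e_src[[length(e_src) + 1L]] <- src
      e_tgt[[length(e_tgt) + 1L]] <- tgt
      e_w[[length(e_w) + 1L]] <- rep(cn$weight, m)
      e_d[[length(e_d) + 1L]] <- rep(d_steps, m)
    }
  })
  src <- unlist(e_src, use.names = FALSE)
  ord <- order(src, method = "radix")
  counts <- tabulate(src, nbins = n)
  list(src_ptr = c(0L, cumsum(counts)),
       tgt = unlist(e_tgt, use.names = FALSE)[ord] - 1L,
       w = unlist(e_w, use.names = FALSE)[ord],
       delay_steps = unlist(e_d, use.names = FALSE)[ord],
       pop_of = pop_of, offsets = offsets, n = n)
}

delay_to_steps <- function(delay, dt) {
  d <- delay / dt
  if (abs(d - round(d)) > 1e-6)
    stop("delay ", delay, " ms is not a multiple of dt = ", dt, " ms")
  d <- as.integer(round(d))
  if (d < 1) stop("delay must be at least one grid step")
  d
}

# evaluate expr with a temporary RNG state seeded from `seed`; the seed
# promise must be forced before the surrounding state is saved, or a draw
# made while computing it would be rolled back on exit
withr_seed <- function(seed, expr) {
  force(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a spiking network
#'
#' Time-driven simulation on the \code{dt} grid. Within each interval
#' neurons are advanced with adaptive RKF45; spikes are checked at grid
#' points only; spike deliveries respect per-connection delays through ring
#' buffers. Event order within one step: deliver arrivals, integrate,
#' threshold check, queue outgoing spikes at \code{t + delay}.
#'
#' @param spec a \code{network_spec}.
#' @param T_total simulated time (ms), a multiple of \code{dt}.
#' @param seed master seed; connectivity and the stochastic drive use
#'   deterministic substreams derived from it.
#' @param backend "approximate" (aggregated NMDA, arbitrary connectivity),
#'   "exact" (shared-source original kinetics; all-to-all block-weighted
#'   networks with one delay per source), or "exact_per_synapse" (one gating
#'   pair per edge; small networks only).
#' @param coherence stimulus coherence c' (percent); \code{NULL} disables
#'   the selective stimulus.
#' @param stimulus a \code{\link{stimulus_spec}}; defaults to the standard
#'   one when \code{coherence} is given.
#' @param clamp optional \code{\link{clamp_spec}}.
#' @param record_every recording cadence for gating traces (ms; 0 disables).
#' @param record_neurons integer vector of 1-based neuron ids for V and
#'   aggregated S_NMDA traces.
#' @param atol,rtol RKF45 tolerances.
#' @return List with \code{spikes} (data frame: neuron, time), \code{pop_S}
#'   (data frame of population-averaged source gating traces), per-neuron
#'   traces if requested, \code{deliveries} counters, \code{final_S_NMDA},
#'   and the population bookkeeping (\code{sizes}, \code{offsets}).
#' @export
simulate_network <- function(spec, T_total, seed = 1L,
                             backend = c("approximate", "exact",
                                         "exact_per_synapse"),
                             coherence = NULL, stimulus = NULL, clamp = NULL,
                             record_every = 1, record_neurons = integer(0),
                             atol = 1e-6, rtol = 1e-6) {
  stopifnot(inherits(spec, "network_spec"), T_total > 0)
  backend <- match.arg(backend)
  n_steps <- T_total / spec$dt
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop("T_total must be a multiple of dt")
  n_steps <- as.integer(round(n_steps))

  seeds <- derive_seeds(seed, c("connectivity", "drive"))
  adj <- build_connectivity(spec, seeds[["connectivity"]])
  sizes <- pop_sizes(spec)
  n_pops <- length(sizes)
  kinds <- vapply(spec$populations, `[[`, "", "kind")
  exc_pop <- kinds == "excitatory"
  pop_par <- t(vapply(spec$populations,
                      function(p) neuron_param_vector(p$params),
                      numeric(18)))

  p_ext <- rep(spec$nu_ext * spec$dt / 1000, n_pops)
  if (any(p_ext > 1)) stop("background rate too high for the grid step")

  stim_p <- matrix(numeric(0), nrow = 0, ncol = n_pops)
  if (!is.null(coherence) || !is.null(stimulus)) {
    if (is.null(stimulus)) stimulus <- stimulus_spec(coherence = coherence)
    stim_p <- stimulus_prob_matrix(stimulus, spec, n_steps,
                                   seeds[["drive"]] + 1L)
  }

  Wn <- matrix(0, n_pops, n_pops)
  if (backend == "exact") {
    labels <- names(sizes)
    for (cn in spec$connections) {
      if (kinds[[pop_index(spec, cn$source)]] != "excitatory") next
      if (cn$rule != "all_to_all")
        stop("exact backend requires all-to-all connectivity; use ",
             "'exact_per_synapse' for small sparse networks")
      Wn[pop_index(spec, cn$source), pop_index(spec, cn$target)] <- cn$weight
    }
  }

  cl_drive <- numeric(0)
  cl_end <- 0L
  cl_pop <- rep(FALSE, n_pops)
  if (!is.null(clamp)) {
    if (backend != "approximate")
      stop("the S_NMDA clamp is only supported by the approximate backend")
    cd <- clamp_drives(clamp, spec)
    cl_drive <- cd$drive
    cl_end <- as.integer(round(clamp$t_release / spec$dt))
    cl_pop[match(clamp$clamped, names(sizes))] <- TRUE
  }

  backend_code <- match(backend,
                        c("approximate", "exact", "exact_per_synapse")) - 1L
  res <- withr_seed(seeds[["drive"]], {
    cpp_simulate_network(
      adj$pop_of, pop_par, exc_pop, adj$src_ptr, adj$tgt, adj$w,
      adj$delay_steps, spec$dt, n_steps, backend_code, p_ext, stim_p, Wn,
      cl_drive, cl_end, cl_pop,
      if (record_every > 0) as.integer(round(record_every / spec$dt)) else 0L,
      as.integer(record_neurons) - 1L, atol, rtol)
  })
  pop_s <- as.data.frame(res$popS)
  names(pop_s) <- names(sizes)
  out <- list(
    spikes = data.frame(neuron = res$spike_id, time = res$spike_time),
    rec_times = res$rec_times, pop_S = pop_s,
    trace_V = res$traceV, trace_S_NMDA = res$traceSN,
    final_S_NMDA = res$final_SN, deliveries = res$deliveries,
    sizes = sizes, offsets = adj$offsets, T_total = T_total, dt = spec$dt,
    backend = backend)
  class(out) <- "network_sim"
  out
}

#' Global neuron ids of a population
#'
#' @param sim a result of \code{\link{simulate_network}}.
#' @param label population label.
#' @return Integer vector of 1-based neuron ids.
#' @export
population_ids <- function(sim, label) {
  if (!label %in% names(sim$sizes)) stop("unknown population label: ", label)
  sim$offsets[[label]] + seq_len(sim$sizes[[label]])
}
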