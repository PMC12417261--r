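test_that("all-to-all connectivity includes autapses and covers all pairs", {
  spec <- decision_network(scale = 0.01)  # 2/2/12/4 neurons
  adj <- build_connectivity(spec, seed = 1)
  n <- adj$n
  deg <- diff(adj$src_ptr)
  expect_true(all(deg == n))  # every source reaches every neuron
  # autapse present: source i connects to target i
  for (i in 1:3) {
    tgts <- adj$tgt[(adj$src_ptr[i] + 1):adj$src_ptr[i + 1]]
    expect_true((i - 1L) %in% tgts)
    expect_equal(sort(tgts), 0:(n - 1L))
  }
})

test_that("fixed in-degree draws exact distinct counts without autapses", {
  spec <- decision_network(scale = 0.025, epsilon = 0.2)  # 6/6/28/10
  adj <- build_connectivity(spec, seed = 3)
  sizes <- c(A = 6, B = 6, N = 28, I = 10)
  offs <- c(A = 0, B = 6, N = 12, I = 40)
  # reconstruct per-target in-degree per source population
  src_of_edge <- rep(seq_len(adj$n) - 1L, diff(adj$src_ptr))
  for (tp in names(sizes)) {
    for (sp in names(sizes)) {
      k_expect <- round(0.2 * sizes[[sp]])
      for (tt in offs[[tp]] + seq_len(sizes[[tp]]) - 1L) {
        e <- which(adj$tgt == tt &
                     src_of_edge >= offs[[sp]] &
                     src_of_edge < offs[[sp]] + sizes[[sp]])
        srcs <- src_of_edge[e]
        expect_length(srcs, k_expect)       # zero in-degree variance
        expect_false(anyDuplicated(srcs) > 0)  # no multapses
        if (sp == tp) expect_false(tt %in% srcs)  # no autapses
      }
    }
  }
})

test_that("full in-degree on distinct populations recovers all-to-all", {
  spec <- decision_network(scale = 0.01)
  spec$connections <- lapply(spec$connections, function(cn) {
    if (cn$source != cn$target) {
      cn$rule <- "fixed_indegree"
      cn$epsilon <- 1
    }
    cn
  })
  adj_fix <- build_connectivity(spec, seed = 9)
  adj_all <- build_connectivity(decision_network(scale = 0.01), seed = 9)
  key <- function(a) {
    src <- rep(seq_len(a$n), diff(a$src_ptr))
    o <- order(src, a$tgt)
    paste(src[o], a$tgt[o])
  }
  expect_identical(key(adj_fix), key(adj_all))
})

test_that("out-degree is binomial with mean epsilon * N_target", {
  # B -> N at epsilon = 0.5: every N target draws 3 of the 6 B sources, so
  # a B neuron's out-degree onto N is Binomial(28, 1/2) with mean
  # epsilon * N_target = 14
  spec <- decision_network(scale = 0.025, epsilon = 0.5)
  set.seed(1234)
  outdeg <- replicate(400, {
    adj <- build_connectivity(spec, seed = sample.int(1e6, 1))
    src_of_edge <- rep(seq_len(adj$n) - 1L, diff(adj$src_ptr))
    sum(src_of_edge == 6L & adj$tgt >= 12L & adj$tgt < 40L)
  })
  mu <- 0.5 * 28
  se <- stats::sd(outdeg) / sqrt(length(outdeg))
  expect_lt(abs(mean(outdeg) - mu), 4 * se + 1e-9)
  expect_gt(stats::sd(outdeg), 0)
})

test_that("synapse counting follows the AMPA/NMDA pairing rule", {
  expect_equal(count_synapses(decision_network()), 7.2e6)
  # the scaled benchmark network drops the selective split (f = 0)
  expect_equal(count_synapses(scale_network(decision_network(f = 0), 10.24)),
               754974720)
  lone <- structure(list(
    populations = list(population_spec("X", 1, "excitatory")),
    connections = list(), dt = 0.1, delay = 0.5, nu_ext = 0),
    class = "network_spec")
  expect_equal(count_synapses(lone), 0)
})

test_that("network rescaling: sizes, conductances, errors", {
  spec <- decision_network()
  expect_equal(pop_sizes <- vapply(scale_network(spec, 1)$populations,
                                   `[[`, 0L, "size"),
               vapply(spec$populations, `[[`, 0L, "size"))
  up <- scale_network(decision_network(f = 0), 10.24)
  expect_equal(sum(vapply(up$populations, `[[`, 0L, "size")), 20480)
  down <- scale_network(spec, 0.25)
  expect_equal(vapply(down$populations, `[[`, 0L, "size"),
               c(60L, 60L, 280L, 100L), ignore_attr = TRUE)
  expect_equal(down$populations[[1]]$params$g_NMDA, 0.165 * 4)
  expect_equal(down$populations[[1]]$params$g_AMPA_ext, 2.1)  # unscaled
  expect_error(scale_network(spec, 1 / 3), "non-integer")
})

test_that("simulation is deterministic given (spec, seed, backend)", {
  spec <- decision_network(scale = 0.025)
  s1 <- simulate_network(spec, 400, seed = 5, record_every = 0)
  s2 <- simulate_network(spec, 400, seed = 5, record_every = 0)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- simulate_network(spec, 400, seed = 6, record_every = 0)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("delivery counters equal summed out-degrees of spiking neurons", {
  spec <- decision_network(scale = 0.05, epsilon = 0.5)
  seed <- 21
  sim <- simulate_network(spec, 500, seed = seed, record_every = 0)
  seeds <- derive_seeds(seed, c("connectivity", "drive"))
  adj <- build_connectivity(spec, seeds[["connectivity"]])
  outdeg <- diff(adj$src_ptr)
  n_exc <- 80
  exc_spk <- sim$spikes$neuron[sim$spikes$neuron <= n_exc]
  inh_spk <- sim$spikes$neuron[sim$spikes$neuron > n_exc]
  expect_equal(sim$deliveries[["AMPA"]], sum(outdeg[exc_spk]))
  expect_equal(sim$deliveries[["NMDA"]], sum(outdeg[exc_spk]))
  expect_equal(sim$deliveries[["GABA"]], sum(outdeg[inh_spk]))
})

test_that("one source spike raises the target aggregate by w*k0 after the delay", {
  spec <- two_neuron_spec(weight = 0.7, delay = 0.5)
  sim <- simulate_network(spec, 400, seed = 2, record_every = 0.1,
                          record_neurons = 2)
  src_spikes <- sim$spikes$time[sim$spikes$neuron == 1]
  expect_gt(length(src_spikes), 0)
  t1 <- src_spikes[1]
  jc <- jump_constants(gating_params())
  sn <- sim$trace_S_NMDA[, 1]
  tt <- sim$rec_times
  # the jump is applied at the start of the grid interval beginning at
  # t1 + delay; records are taken at interval ends
  before <- sn[abs(tt - (t1 + 0.5)) < 1e-6]
  arrival <- sn[abs(tt - (t1 + 0.6)) < 1e-6]
  expect_equal(before, 0)
  expect_equal(arrival, 0.7 * jc$k0 * exp(-0.1 / 100), tolerance = 1e-10)
  # exponential decay with tau_d until the next source spike arrives
  t_next <- if (length(src_spikes) > 1) src_spikes[2] + 0.5 else 400
  win <- tt > t1 + 0.65 & tt < t_next
  expect_equal(sn[win], arrival * exp(-(tt[win] - (t1 + 0.6)) / 100),
               tolerance = 1e-9)
})

test_that("aggregated target variable equals the jump-map replay of source spikes", {
  # network-level aggregation oracle: replay the observed source spike
  # train through the jump map and the closed-form propagator in R
  spec <- two_neuron_spec(weight = 1.3, delay = 0.5)
  sim <- simulate_network(spec, 1500, seed = 8, record_every = 0.1,
                          record_neurons = 2)
  src_spikes <- sim$spikes$time[sim$spikes$neuron == 1]
  expect_gt(length(src_spikes), 3)
  p <- gating_params()
  jc <- jump_constants(p)
  s_loc <- 0
  last <- 0
  arr_bin <- integer(0)
  dS <- numeric(0)
  for (ts in src_spikes) {
    s_loc <- s_loc * exp(-(ts - last) / p$tau_d)
    last <- ts
    d <- jc$k0 + jc$k1 * s_loc
    s_loc <- s_loc + d
    arr_bin <- c(arr_bin, round((ts + 0.5) / 0.1))  # 0-based arrival bin
    dS <- c(dS, 1.3 * d)
  }
  # replay with the simulator's convention: increments at interval starts,
  # records after the end-of-interval decay
  n_steps <- 15000L
  dec <- exp(-0.1 / p$tau_d)
  s <- 0
  expected <- numeric(n_steps)
  for (k in seq_len(n_steps) - 1L) {
    hit <- which(arr_bin == k)
    if (length(hit)) s <- s + sum(dS[hit])
    s <- s * dec
    expected[k + 1L] <- s
  }
  got <- sim$trace_S_NMDA[, 1]
  expect_lt(max(abs(got - expected)), 1e-11)
})

test_that("grid-alignment and label errors are caught", {
  spec <- decision_network(scale = 0.01)
  spec$connections[[1]]$delay <- 0.55
  expect_error(build_connectivity(spec, 1), "multiple of dt")
  expect_error(simulate_network(decision_network(scale = 0.01), 333.33),
               "multiple of dt")
  sim <- simulate_network(decision_network(scale = 0.01), 100,
                          record_every = 0)
  expect_error(population_ids(sim, "Z"), "unknown population")
})
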