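test_that("magnesium block factor matches direct evaluation", {
  expect_equal(mg_block_factor(0, Mg = 0), 1)
  expect_equal(mg_block_factor(-123, Mg = 0), 1)
  expect_equal(mg_block_factor(0, Mg = 1), 1 / (1 + 1 / 3.57))
  expect_equal(mg_block_factor(-70, Mg = 1),
               1 / (1 + exp(0.062 * 70) / 3.57))
  expect_equal(mg_block_factor(-70, Mg = 1), 0.044471, tolerance = 1e-4)
  # strictly increasing in V, bounded in (0, 1]
  v <- seq(-90, 20, by = 1)
  b <- mg_block_factor(v)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
})

test_that("synaptic current: reversal potentials and composition", {
  p <- neuron_params("excitatory")
  expect_equal(synaptic_current(-60, 0, 0, 0, p)$total, 0)
  # at the excitatory reversal with no inhibition the current vanishes
  expect_equal(synaptic_current(p$V_E, 2, 0, 3, p)$total, 0)
  cur <- synaptic_current(-55, 0, 0, 1, p)
  expect_equal(cur$NMDA, p$g_NMDA * (-55 - 0) * mg_block_factor(-55))
  expect_equal(cur$total, cur$NMDA)
  # NMDA magnitude monotone in S_NMDA at fixed V
  mags <- vapply(c(0.5, 1, 2, 4),
                 function(s) abs(synaptic_current(-55, 0, 0, s, p)$NMDA),
                 numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("neuron parameter validation and variants", {
  expect_error(neuron_params(V_reset = -40), "V_reset")
  expect_error(neuron_params(nonsense = 1), "unknown")
  expect_equal(neuron_params("inhibitory")$C_m, 200)
  expect_equal(neuron_params("inhibitory", "printed")$C_m, 250)
  expect_equal(neuron_params("excitatory", "printed")$tau_GABA, 2)
})

test_that("leak fixed point and monotone convergence to rest", {
  p <- neuron_params()
  r <- integrate_neuron(p, 50, 0.1)
  expect_true(all(abs(r$V - p$E_L) < 1e-9))
  expect_length(r$spikes, 0)
  # from above and below, V approaches E_L monotonically
  hi <- integrate_neuron(p, 100, 0.1, V0 = -55)
  lo <- integrate_neuron(p, 100, 0.1, V0 = -90)
  expect_true(all(diff(hi$V) < 1e-12))
  expect_true(all(diff(lo$V) > -1e-12))
  expect_equal(hi$V[length(hi$V)], p$E_L, tolerance = 1e-2)
})

test_that("constant-current spike time matches the closed-form crossing", {
  p <- neuron_params()
  for (I0 in c(-550, -700, -1000)) {
    v_inf <- p$E_L - I0 / p$g_L
    t_star <- p$C_m / p$g_L *
      log((v_inf - p$E_L) / (v_inf - p$V_thr))
    r <- integrate_neuron(p, 200, 0.1, I_const = I0)
    expect_lt(abs(r$spikes[1] - t_star), 0.1 + 1e-9)
  }
})

test_that("refractory clamp lasts whole grid steps and blocks spiking", {
  p <- neuron_params()  # t_ref = 2 ms
  r <- integrate_neuron(p, 300, 0.1, I_const = -2000)
  isi <- diff(r$spikes)
  # reset + 2 ms clamp + at least one step to reach threshold again
  expect_true(all(isi >= p$t_ref + 0.1 - 1e-9))
  # V equals V_reset at every grid point inside the refractory window
  k1 <- round(r$spikes[1] / 0.1)
  expect_true(all(r$V[(k1 + 1):(k1 + 20)] == p$V_reset))
})

test_that("adaptive integration matches a fine-step RK4 reference", {
  p <- neuron_params()
  set.seed(11)
  bins <- poisson_train(200, 100, 0.1)
  r <- integrate_neuron(p, 100, 0.1, input = list(bins), weight = 1,
                        backend = "approximate")
  v_oracle <- rk4_lif_approx(p, 100, 0.1, bins, weight = 1, h = 1e-3)
  expect_lt(max(abs(r$V - v_oracle)), 1e-3)
})

test_that("excitatory NMDA input depolarizes the membrane", {
  p <- neuron_params()
  # the magnesium block keeps single-synapse NMDA currents small near rest,
  # so a strong compound weight is needed for a visible deflection
  r <- integrate_neuron(p, 100, 0.1, input = list(c(10)), weight = 100,
                        backend = "approximate")
  expect_gt(max(r$V), p$E_L + 0.5)
})
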