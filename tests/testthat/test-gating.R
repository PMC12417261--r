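test_that("jump constants match both incomplete-gamma oracles on a grid", {
  for (alpha in c(0.1, 0.5, 2)) {
    for (tau_r in c(0.5, 2, 5)) {
      for (tau_d in c(50, 100, 200)) {
        p <- gating_params(alpha, tau_r, tau_d)
        jc <- jump_constants(p)
        s <- 1 - tau_r / tau_d
        x <- alpha * tau_r
        pref <- x^(tau_r / tau_d)
        expect_equal(jc$k0, pref * gamma_lower_quad(s, x), tolerance = 1e-8)
        expect_equal(jc$k0, pref * gamma_lower_series(s, x),
                     tolerance = 1e-8)
        expect_identical(jc$k1_prime, exp(-x))
        expect_equal(jc$k1, jc$k1_prime - 1)
        expect_gt(jc$k0, 0)
        expect_true(jc$k1 > -1 && jc$k1 < 0)
      }
    }
  }
})

test_that("default-parameter jump constants and fixed point", {
  jc <- jump_constants(gating_params())
  expect_equal(jc$k1_prime, exp(-1))
  expect_equal(jc$k0, 0.6484167, tolerance = 1e-6)
  # the saturation ceiling of the approximation sits slightly above 1
  fp <- gating_fixed_point(jc)
  expect_equal(fp, 1.026, tolerance = 1e-3)
  expect_gt(fp, 1)
})

test_that("vanishing gain gives vanishing jump constants", {
  jc0 <- jump_constants(gating_params(alpha = 0))
  expect_identical(jc0$k0, 0)
  expect_identical(jc0$k1, 0)
  jc_small <- jump_constants(gating_params(alpha = 1e-6))
  expect_lt(jc_small$k0, 1e-5)
  expect_lt(-jc_small$k1, 1e-5)
})

test_that("invalid gating parameters are rejected", {
  expect_error(gating_params(tau_r = 100, tau_d = 100), "tau_r")
  expect_error(gating_params(tau_r = 150, tau_d = 100), "tau_r")
  expect_error(gating_params(alpha = -0.1), "alpha")
  expect_error(gating_params(tau_r = 0), "tau_r")
})

test_that("jump map: rest, fixed point and mid-range values", {
  jc <- jump_constants(gating_params())
  expect_equal(approx_jump(0, jc), jc$k0)
  expect_equal(approx_jump(gating_fixed_point(jc), jc), 0)
  expect_equal(approx_jump(0.5, jc), 0.6484167 - 0.6321206 * 0.5,
               tolerance = 1e-6)
  # strictly positive below the fixed point
  expect_true(all(approx_jump(seq(0, 1, 0.1), jc) > 0))
})

test_that("a presynaptic spike enters only the rise variable", {
  st <- exact_spike_update(list(S = 0, x = 0))
  expect_equal(st, list(S = 0, x = 1))
  st <- exact_spike_update(list(S = 0.3, x = 0.5))
  expect_equal(st, list(S = 0.3, x = 1.5))
  st <- exact_spike_update(list(S = 0.3, x = 0.5), n = 2)
  expect_equal(st$x, 2.5)
})

test_that("exact gating evolution: rest state, closed-form x, RK4 oracle", {
  p <- gating_params()
  tr0 <- exact_gating_evolve(0, 0, p, duration = 50, step = 1)
  expect_true(all(tr0$S == 0) && all(tr0$x == 0))

  tr <- exact_gating_evolve(0, 1, p, duration = 30, step = 0.1)
  expect_equal(tr$x, exp(-tr$time / p$tau_r), tolerance = 1e-12)

  oracle <- rk4_gating(0, 1, p, 30, h = 1e-3)
  idx <- round(tr$time / 1e-3) + 1L
  expect_lt(max(abs(tr$S - oracle$S[idx])), 1e-7)
  # single-spike response peaks below the hard saturation at 1
  expect_lt(max(tr$S), 1)
  expect_equal(tr$time[which.max(tr$S)],
               oracle$time[which.max(oracle$S)], tolerance = 0.2)
})

test_that("approximation is asymptotically equal to the exact solution", {
  p <- gating_params()
  jc <- jump_constants(p)
  tr <- exact_gating_evolve(0, 1, p, duration = 100, step = 0.5)
  shat <- jc$k0 * exp(-tr$time / p$tau_d)
  r50 <- tr$S[tr$time == 50] / shat[tr$time == 50]
  r100 <- tr$S[tr$time == 100] / shat[tr$time == 100]
  expect_lt(abs(r50 - 1), 1e-4)
  expect_lt(abs(r100 - 1), 1e-6)
})

test_that("exact model saturates in [0, 1] under random spike trains", {
  p <- gating_params()
  set.seed(42)
  for (rep in 1:5) {
    st <- list(S = runif(1), x = runif(1, 0, 2))
    n_seg <- 20
    for (seg in seq_len(n_seg)) {
      gap <- runif(1, 0.5, 20)
      tr <- exact_gating_evolve(st$S, st$x, p, duration = gap, step = gap / 20)
      expect_true(all(tr$S >= -1e-10 & tr$S <= 1 + 1e-10))
      expect_true(all(tr$x >= 0))
      st <- list(S = tr$S[nrow(tr)], x = tr$x[nrow(tr)])
      st <- exact_spike_update(st, n = sample(1:2, 1))
    }
  }
})

test_that("jump-map overshoot: approximate exceeds exact after a spike", {
  p <- gating_params()
  jc <- jump_constants(p)
  tr <- exact_gating_evolve(0, 1, p, duration = 20, step = 0.1)
  shat <- jc$k0 * exp(-tr$time / p$tau_d)
  # the approximation skips the finite rise, so it rides above the exact
  # trajectory over the rise transient
  expect_true(all(shat[-1] >= tr$S[-1]))
})

test_that("aggregated evolution: decay, linearity, periodic fixed point", {
  p <- gating_params()
  jc <- jump_constants(p)

  tr <- approx_gating_evolve(1, p, NULL, duration = p$tau_d, step = 1)
  expect_equal(tr$S[tr$time == p$tau_d], exp(-1), tolerance = 1e-12)

  # linearity: two synapses simulated separately then summed equals one
  # aggregated variable receiving both event streams
  set.seed(7)
  ev1 <- data.frame(time = sort(runif(15, 0, 500)),
                    delta_S = runif(15, 0.1, 0.6))
  ev2 <- data.frame(time = sort(runif(12, 0, 500)),
                    delta_S = runif(12, 0.1, 0.6))
  both <- rbind(ev1, ev2)
  both <- both[order(both$time), ]
  s1 <- approx_gating_evolve(0.2, p, ev1, 500, step = 0.5)
  s2 <- approx_gating_evolve(0.1, p, ev2, 500, step = 0.5)
  s12 <- approx_gating_evolve(0.3, p, both, 500, step = 0.5)
  expect_equal(s1$S + s2$S, s12$S, tolerance = 1e-13)

  # periodic spiking: closed-form pre-spike fixed point vs iterated map
  for (interval in c(10, 50, 200)) {
    s_star <- periodic_steady_state(jc, interval, p$tau_d)
    s <- 0
    for (i in 1:1000) s <- (jc$k0 + jc$k1_prime * s) * exp(-interval / p$tau_d)
    expect_equal(s, s_star, tolerance = 1e-12)
  }
})

test_that("negative aggregated gating is rejected", {
  ev <- data.frame(time = 10, delta_S = -0.5)
  expect_error(approx_gating_evolve(0.1, gating_params(), ev, 20),
               "negative")
})
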