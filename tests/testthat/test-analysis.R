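test_that("binned population rate normalization", {
  expect_error(binned_population_rate(data.frame(neuron = 1, time = 1),
                                      integer(0), 50, 100), "empty")
  none <- binned_population_rate(data.frame(neuron = integer(0),
                                            time = numeric(0)),
                                 1:10, 50, 500)
  expect_true(all(none$rate == 0))
  expect_equal(nrow(none), 10)

  # 100 neurons each firing once inside one 50 ms bin -> 20 spikes/s
  spk <- data.frame(neuron = 1:100, time = runif(100, 100.1, 149.9))
  r <- binned_population_rate(spk, 1:100, 50, 500)
  expect_equal(r$rate[3], 20)
  expect_equal(sum(r$rate), 20)

  # Poisson population recovers its rate
  set.seed(5)
  spk <- do.call(rbind, lapply(1:50, function(i) {
    data.frame(neuron = i, time = (poisson_train(30, 2000, 0.1) - 1) * 0.1)
  }))
  r <- binned_population_rate(spk, 1:50, 50, 2000)
  se <- sqrt(30 / (50 * 2))  # Poisson SE of the 2 s population mean
  expect_lt(abs(mean(r$rate) - 30), 4 * se)
})

test_that("RMS difference: closed-form cases", {
  expect_equal(rms_difference(1:10, 1:10), 0)
  expect_equal(rms_difference(rep(2, 64), rep(5.5, 64)), 3.5)
  t <- seq(0, 4 * pi, length.out = 4001)[-4001]
  expect_equal(rms_difference(3 * sin(t), rep(0, 4000)), 3 / sqrt(2),
               tolerance = 1e-3)
  expect_error(rms_difference(1:5, 1:6), "length")
})

test_that("Weibull fit inverts noiseless curves and flags degenerate data", {
  co <- c(1, 5, 10, 20, 40)
  p <- weibull_p(co, 9.2, 1.5)
  f <- fit_weibull(co, p * 1000, rep(1000, 5))
  expect_lt(abs(f$alpha - 9.2), 1e-6)
  expect_lt(abs(f$beta - 1.5), 1e-6)
  expect_true(f$identifiable)

  flat <- fit_weibull(co, rep(200, 5), rep(400, 5))
  expect_false(flat$identifiable)

  # invariant to trial order and to duplicating the whole dataset
  o <- sample(5)
  f2 <- fit_weibull(co[o], (p * 1000)[o], rep(1000, 5))
  f3 <- fit_weibull(rep(co, 2), rep(p * 1000, 2), rep(1000, 10))
  expect_equal(f2$alpha, f$alpha, tolerance = 1e-6)
  expect_equal(f3$alpha, f$alpha, tolerance = 1e-6)

  # zero coherence is excluded from the fit
  f4 <- fit_weibull(c(0, co), c(77, p * 1000), c(400, rep(1000, 5)))
  expect_equal(f4$alpha, f$alpha, tolerance = 1e-6)
})

test_that("bootstrap interval: endpoints, determinism, width", {
  expect_equal(bootstrap_ci(rep(1, 20), 200, seed = 1),
               c(low = 1, high = 1))
  x <- c(rep(1, 30), rep(0, 20))
  ci1 <- bootstrap_ci(x, 1000, seed = 42)
  ci2 <- bootstrap_ci(x, 1000, seed = 42)
  expect_identical(ci1, ci2)
  # endpoints are achievable empirical proportions (multiples of 1/n)
  expect_equal(ci1 * 50, round(ci1 * 50))

  set.seed(8)
  x <- rbinom(400, 1, 0.5)
  ci <- bootstrap_ci(x, 5000, level = 0.9, seed = 3)
  width <- ci[["high"]] - ci[["low"]]
  expect_lt(abs(width - 2 * 1.645 * sqrt(0.25 / 400)), 0.2 * 0.082)
})

test_that("bootstrap interval has near-nominal coverage", {
  set.seed(21)
  hits <- replicate(400, {
    x <- rbinom(100, 1, 0.7)
    ci <- bootstrap_ci(x, 600, level = 0.9)
    ci[["low"]] <= 0.7 && 0.7 <= ci[["high"]]
  })
  expect_lt(abs(mean(hits) - 0.9), 0.05)
})

test_that("population mean gating averages the recorded source variables", {
  fake <- list(rec_times = c(1, 2), pop_S = data.frame(A = c(1, 0.5),
                                                       B = c(0, 0)))
  tr <- population_mean_gating(fake, "A")
  expect_equal(tr$S, c(1, 0.5))
  expect_error(population_mean_gating(fake, "Z"), "unknown")
})
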