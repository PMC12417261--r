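# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# unnormalized lower incomplete gamma via the alternating series
# x^s * sum_n (-x)^n / (n! (s + n))
gamma_lower_series <- function(s, x, n_terms = 60) {
  n <- 0:(n_terms - 1)
  x^s * sum((-x)^n / (factorial(n) * (s + n)))
}

# unnormalized lower incomplete gamma via adaptive quadrature of the
# defining integral
gamma_lower_quad <- function(s, x) {
  stats::integrate(function(u) u^(s - 1) * exp(-u), 0, x,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# fine-step fixed RK4 integration of the exact two-variable gating model
# (x substituted in closed form)
rk4_gating <- function(S0, x0, params, duration, h = 1e-3) {
  n <- ceiling(duration / h)
  S <- numeric(n + 1)
  S[1] <- S0
  f <- function(t, S) {
    -S / params$tau_d +
      params$alpha * x0 * exp(-t / params$tau_r) * (1 - S)
  }
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(t, S[i])
    k2 <- f(t + h / 2, S[i] + h / 2 * k1)
    k3 <- f(t + h / 2, S[i] + h / 2 * k2)
    k4 <- f(t + h, S[i] + h * k3)
    S[i + 1] <- S[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  data.frame(time = seq(0, by = h, length.out = n + 1), S = S)
}

# fixed-step RK4 oracle for a single LIF neuron with aggregated
# jump-approximated NMDA input (gating in closed form between arrivals),
# spike checks on the dt grid like the package integrator
rk4_lif_approx <- function(params, T_total, dt, arrival_bins, weight,
                           h = 1e-3) {
  jc <- jump_constants(params$gating)
  tau_d <- params$gating$tau_d
  n_steps <- round(T_total / dt)
  sub <- round(dt / h)
  V <- params$E_L
  SN <- 0
  S_loc <- 0
  last_arr <- 0L
  ref_until <- 0L
  Vtr <- numeric(n_steps)
  arr <- sort(arrival_bins)
  ai <- 1L
  mg <- function(V) 1 / (1 + params$Mg * exp(-0.062 * V) / 3.57)
  rhs <- function(V, SN_t) {
    I <- params$g_NMDA * (V - params$V_E) * mg(V) * SN_t
    (-params$g_L * (V - params$E_L) - I) / params$C_m
  }
  for (k in seq_len(n_steps) - 1L) {
    while (ai <= length(arr) && arr[ai] - 1L == k) {
      S_loc <- S_loc * exp(-(k - last_arr) * dt / tau_d)
      last_arr <- k
      dS <- jc$k0 + jc$k1 * S_loc
      S_loc <- S_loc + dS
      SN <- SN + weight * dS
      ai <- ai + 1L
    }
    if (k >= ref_until) {
      for (m in seq_len(sub) - 1L) {
        s0 <- m * h
        k1 <- rhs(V, SN * exp(-s0 / tau_d))
        k2 <- rhs(V + h / 2 * k1, SN * exp(-(s0 + h / 2) / tau_d))
        k3 <- rhs(V + h / 2 * k2, SN * exp(-(s0 + h / 2) / tau_d))
        k4 <- rhs(V + h * k3, SN * exp(-(s0 + h) / tau_d))
        V <- V + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    } else {
      V <- params$V_reset
    }
    SN <- SN * exp(-dt / tau_d)
    if (k >= ref_until && V >= params$V_thr) {
      V <- params$V_reset
      ref_until <- k + 1L + ceiling(params$t_ref / dt)
    }
    Vtr[k + 1L] <- V
  }
  Vtr
}

# small custom two-neuron network: one source population projecting onto
# one target population with a single connection
two_neuron_spec <- function(weight = 0.7, delay = 0.5, dt = 0.1,
                            nu_ext = 2400) {
  structure(list(
    populations = list(
      population_spec("S", 1, "excitatory"),
      population_spec("T", 1, "excitatory")),
    connections = list(
      connectivity_spec("S", "T", weight, delay, "all_to_all")),
    dt = dt, f = NA, w_plus = NA, w_minus = NA, delay = delay,
    scale = NA, nu_ext = nu_ext), class = "network_spec")
}
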