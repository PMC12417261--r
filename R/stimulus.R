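#' Poisson spike train on the simulation grid
#'
#' Per-bin Bernoulli process with \eqn{p = rate \cdot dt / 1000}, i.e. at
#' most one spike per grid bin. Uses the current RNG state unless a seed is
#' given.
#'
#' @param rate firing rate (spikes/s), >= 0.
#' @param T_total duration (ms).
#' @param dt bin width (ms).
#' @param seed optional seed for a self-contained draw.
#' @return Integer vector of 1-based bin indices containing a spike; spike
#'   times are \code{(bins - 1) * dt}.
#' @export
poisson_train <- function(rate, T_total, dt = 0.1, seed = NULL) {
  stopifnot(rate >= 0, T_total > 0, dt > 0)
  p <- rate * dt / 1000
  if (p > 1) stop("rate too high for this grid step (p = ", p, " > 1)")
  n_bins <- as.integer(round(T_total / dt))
  draw <- function() which(stats::runif(n_bins) < p)
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Mean selective-stimulus rates at a given coherence
#'
#' \eqn{\mu_A = \mu_0 + \rho_A c'}, \eqn{\mu_B = \mu_0 - \rho_B c'}.
#'
#' @param coherence coherence c' (percent).
#' @param mu0 base rate (spikes/s).
#' @param rho_A,rho_B coherence scaling (spikes/s per percent); default
#'   \eqn{\mu_0/100}.
#' @return Named vector \code{c(mu_A, mu_B)}.
#' @examples
#' coherence_rates(40)  # c(56, 24)
#' @export
coherence_rates <- function(coherence, mu0 = 40, rho_A = mu0 / 100,
                            rho_B = mu0 / 100) {
  c(mu_A = mu0 + rho_A * coherence, mu_B = mu0 - rho_B * coherence)
}

#' Selective-stimulus specification
#'
#' The two selective populations receive an additional Poisson drive onto
#' AMPA receptors (weight 1) during a stimulus window. Within the window the
#' rate of each drive is redrawn every \code{resample_interval} from a
#' Gaussian centred on the coherence-dependent mean with spread
#' \code{rate_sd} (standard deviation, in spikes/s), clipped at zero.
#'
#' @param coherence coherence c' (percent).
#' @param mu0 base rate (spikes/s).
#' @param rho_A,rho_B coherence scaling factors (spikes/s per percent).
#' @param window stimulus window \code{c(t_on, t_off)} (ms).
#' @param resample_interval rate-resampling interval (ms).
#' @param rate_sd Gaussian spread of the resampled rates; interpreted as a
#'   standard deviation (set \code{sd_is_variance = TRUE} to interpret it as
#'   a variance).
#' @param sd_is_variance see \code{rate_sd}.
#' @param target_A,target_B population labels receiving the two drives.
#' @return An object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(coherence = 0, mu0 = 40, rho_A = mu0 / 100,
                          rho_B = mu0 / 100, window = c(1000, 3000),
                          resample_interval = 50, rate_sd = 4,
                          sd_is_variance = FALSE,
                          target_A = "A", target_B = "B") {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] > window[1],
            resample_interval > 0, rate_sd >= 0)
  structure(list(coherence = coherence, mu0 = mu0, rho_A = rho_A,
                 rho_B = rho_B, window = window,
                 resample_interval = resample_interval,
                 rate_sd = if (sd_is_variance) sqrt(rate_sd) else rate_sd,
                 target_A = target_A, target_B = target_B),
            class = "stimulus_spec")
}

#' Piecewise-constant resampled stimulus rate trace
#'
#' @param mu mean rate within the window (spikes/s).
#' @param T_total total duration (ms).
#' @param dt grid step (ms).
#' @param window stimulus window \code{c(t_on, t_off)} (ms).
#' @param resample_interval segment length (ms).
#' @param rate_sd Gaussian standard deviation of the segment rates
#'   (spikes/s); draws are clipped at zero.
#' @return Numeric vector of per-bin rates (spikes/s), zero outside the
#'   window. Uses the current RNG state.
#' @export
resampled_stimulus <- function(mu, T_total, dt = 0.1, window = c(1000, 3000),
                               resample_interval = 50, rate_sd = 4) {
  stopifnot(window[1] >= 0, window[2] <= T_total)
  n_bins <- as.integer(round(T_total / dt))
  rates <- numeric(n_bins)
  n_seg <- ceiling((window[2] - window[1]) / resample_interval)
  seg_rates <- pmax(0, stats::rnorm(n_seg, mean = mu, sd = rate_sd))
  for (s in seq_len(n_seg)) {
    t0 <- window[1] + (s - 1) * resample_interval
    t1 <- min(window[1] + s * resample_interval, window[2])
    b0 <- as.integer(round(t0 / dt)) + 1L
    b1 <- as.integer(round(t1 / dt))
    if (b1 >= b0) rates[b0:b1] <- seg_rates[s]
  }
  rates
}

# per-bin spike probabilities for the two selective drives, as an
# (n_steps x n_pops) matrix aligned with the network's population order
stimulus_prob_matrix <- function(stim, spec, n_steps, seed) {
  sizes <- pop_sizes(spec)
  T_total <- n_steps * spec$dt
  mu <- coherence_rates(stim$coherence, stim$mu0, stim$rho_A, stim$rho_B)
  out <- matrix(0, nrow = n_steps, ncol = length(sizes))
  withr_seed(seed, {
    for (pp in c("A", "B")) {
      lab <- if (pp == "A") stim$target_A else stim$target_B
      if (!lab %in% names(sizes)) next
      mu_p <- if (pp == "A") mu[["mu_A"]] else mu[["mu_B"]]
      r <- resampled_stimulus(mu_p, T_total, spec$dt, stim$window,
                              stim$resample_interval, stim$rate_sd)
      out[, match(lab, names(sizes))] <- r * spec$dt / 1000
    }
  })
  if (any(out > 1)) stop("stimulus rate too high for this grid step")
  out
}

#' S_NMDA clamp specification for the sparse-network protocol
#'
#' For the first \code{t_release} ms, all outgoing NMDA connections from the
#' clamped populations are replaced by a constant drive added to the
#' right-hand side of each target's aggregated gating equation. The drive is
#' chosen so that the linear steady state \eqn{D \tau_d} equals the weighted
#' sum the target would receive if every gating variable in population
#' \code{high} were exactly 1 (and every one in the other clamped
#' populations 0): \eqn{D_X = N_{high}\,\epsilon_{high,X}\, w_{high,X} /
#' \tau_d}. At \code{t_release} the drive is removed and event-driven
#' delivery resumes.
#'
#' @param high label of the population clamped to 1 (default "A").
#' @param low labels clamped to 0 (default "B").
#' @param t_release clamp release time (ms).
#' @param include_conductance if TRUE, the drive additionally carries the
#'   target's NMDA conductance factor (an alternative normalization; the
#'   default keeps the aggregated gating variable conductance-free).
#' @return An object of class \code{clamp_spec}.
#' @export
clamp_spec <- function(high = "A", low = "B", t_release = 2000,
                       include_conductance = FALSE) {
  stopifnot(t_release > 0)
  structure(list(high = high, low = low, clamped = c(high, low),
                 t_release = t_release,
                 include_conductance = include_conductance),
            class = "clamp_spec")
}

#' Per-target constant drives implementing the clamp
#'
#' Resolves a \code{\link{clamp_spec}} against a network: for every target
#' population the constant added to the aggregated gating equation is the
#' summed contribution of the clamped-high population's connections,
#' \eqn{N_{high}\,\epsilon\,w / \tau_d}.
#'
#' @param clamp a \code{\link{clamp_spec}}.
#' @param spec a \code{network_spec}.
#' @return List with \code{drive} (per neuron, 1/ms) and \code{drive_pop}
#'   (per population).
#' @export
clamp_drives <- function(clamp, spec) {
  stopifnot(inherits(clamp, "clamp_spec"), inherits(spec, "network_spec"))
  sizes <- pop_sizes(spec)
  kinds <- vapply(spec$populations, `[[`, "", "kind")
  if (any(kinds[match(clamp$clamped, names(sizes))] != "excitatory"))
    stop("only excitatory (NMDA-projecting) populations can be clamped")
  drive_pop <- numeric(length(sizes))
  n_high <- sizes[[clamp$high]]
  for (cn in spec$connections) {
    if (cn$source != clamp$high) next
    tgt_i <- match(cn$target, names(sizes))
    eps <- if (cn$rule == "all_to_all") 1 else cn$epsilon
    tau_d <- spec$populations[[tgt_i]]$params$gating$tau_d
    d <- n_high * eps * cn$weight / tau_d
    if (clamp$include_conductance)
      d <- d * spec$populations[[tgt_i]]$params$g_NMDA
    drive_pop[tgt_i] <- drive_pop[tgt_i] + d
  }
  pop_of <- rep(seq_along(sizes), sizes)
  list(drive = drive_pop[pop_of], drive_pop = drive_pop)
}
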