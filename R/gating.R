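#' Synaptic kinetics parameters for the NMDA gating variable
#'
#' The NMDA receptor gating variable \eqn{S} follows a two-variable kinetic
#' scheme: an auxiliary rise variable \eqn{x} is incremented by 1 at each
#' presynaptic spike and decays with time constant \code{tau_r}, while
#' \eqn{S} obeys \eqn{dS/dt = -S/\tau_d + \alpha x (1 - S)}. The saturating
#' \eqn{(1 - S)} factor keeps \eqn{S} in \eqn{[0, 1]}.
#'
#' @param alpha gain factor of the rise term (1/ms).
#' @param tau_r rise time constant (ms). Must satisfy \code{tau_r < tau_d}:
#'   the jump-constant derivation requires the gamma-function argument
#'   \eqn{1 - \tau_r/\tau_d} to be positive.
#' @param tau_d decay time constant (ms).
#' @return An object of class \code{gating_params}.
#' @examples
#' gating_params() # defaults: alpha = 0.5/ms, tau_r = 2 ms, tau_d = 100 ms
#' @export
gating_params <- function(alpha = 0.5, tau_r = 2, tau_d = 100) {
  stopifnot(is.numeric(alpha), is.numeric(tau_r), is.numeric(tau_d),
            length(alpha) == 1L, length(tau_r) == 1L, length(tau_d) == 1L)
  if (alpha < 0) stop("alpha must be non-negative")
  if (tau_r <= 0) stop("tau_r must be positive")
  if (tau_r >= tau_d)
    stop("tau_r must be smaller than tau_d (gamma argument 1 - tau_r/tau_d ",
         "must be positive)")
  structure(list(alpha = alpha, tau_r = tau_r, tau_d = tau_d),
            class = "gating_params")
}

#' Jump-map constants of the approximate NMDA model
#'
#' The approximation replaces the finite rise of the gating variable by an
#' instantaneous jump \eqn{\Delta S = k_0 + k_1 S(t^-)} at each presynaptic
#' spike, chosen so that the post-spike exponential decay matches the exact
#' solution asymptotically. The constants are
#' \deqn{k_0 = (\alpha\tau_r)^{\tau_r/\tau_d}\,
#'       \gamma\!\left[1 - \tau_r/\tau_d,\ \alpha\tau_r\right], \qquad
#'       k_1' = e^{-\alpha\tau_r}, \qquad k_1 = k_1' - 1,}
#' where \eqn{\gamma} is the \emph{unnormalized} lower incomplete gamma
#' function (computed here as \code{pgamma(x, s) * gamma(s)}). They depend
#' only on the synaptic parameters.
#'
#' @param params a \code{\link{gating_params}} object.
#' @return An object of class \code{jump_constants} with fields \code{k0},
#'   \code{k1} (in \eqn{(-1, 0]}) and \code{k1_prime} \eqn{= k_1 + 1}.
#' @examples
#' jc <- jump_constants(gating_params())
#' jc$k0                       # about 0.6484
#' jc$k0 / (-jc$k1)            # jump-map fixed point, slightly above 1
#' @export
jump_constants <- function(params) {
  stopifnot(inherits(params, "gating_params"))
  a_tr <- params$alpha * params$tau_r
  s <- 1 - params$tau_r / params$tau_d
  k1_prime <- exp(-a_tr)
  k0 <- if (a_tr == 0) 0 else a_tr^(params$tau_r / params$tau_d) *
    stats::pgamma(a_tr, s) * gamma(s)
  structure(list(k0 = k0, k1 = k1_prime - 1, k1_prime = k1_prime),
            class = "jump_constants")
}

#' Fixed point of the jump map
#'
#' The largest value the approximate gating variable of a single synapse can
#' attain: the solution of \eqn{\Delta S = k_0 + k_1 S = 0}. For the default
#' parameters this is about 1.026, slightly above the exact model's hard
#' saturation at 1.
#'
#' @param jc a \code{\link{jump_constants}} object.
#' @return The fixed point \eqn{k_0 / (-k_1)}.
#' @export
gating_fixed_point <- function(jc) {
  stopifnot(inherits(jc, "jump_constants"))
  if (jc$k1 == 0) return(Inf)
  jc$k0 / (-jc$k1)
}

#' Per-spike update of the approximate gating variable
#'
#' @param S_pre gating value immediately before the spike (vectorized).
#' @param jc a \code{\link{jump_constants}} object.
#' @return The increment \eqn{\Delta S = k_0 + k_1 S_{pre}}. Positive for
#'   \code{S_pre} below the fixed point, zero at it.
#' @export
approx_jump <- function(S_pre, jc) {
  stopifnot(inherits(jc, "jump_constants"), all(S_pre >= 0))
  jc$k0 + jc$k1 * S_pre
}

#' Apply a presynaptic spike to the exact gating state
#'
#' In the exact model a spike enters only the rise equation: \eqn{x} is
#' incremented by exactly 1 (by \code{n} for \code{n} simultaneous spikes)
#' and \eqn{S} is unchanged. \eqn{x} is uncapped and accumulates across
#' spikes.
#'
#' @param state list with fields \code{S} and \code{x}.
#' @param n number of simultaneous spikes (default 1).
#' @return The updated state.
#' @export
exact_spike_update <- function(state, n = 1) {
  stopifnot(is.list(state), state$x >= 0, n >= 0)
  state$x <- state$x + n
  state
}

#' Evolve the exact two-variable gating model between spikes
#'
#' Integrates \eqn{dS/dt = -S/\tau_d + \alpha x (1-S)},
#' \eqn{dx/dt = -x/\tau_r} from \code{(S0, x0)} over \code{duration} with no
#' spikes in the interval. \eqn{x} has the closed form
#' \eqn{x_0 e^{-t/\tau_r}} and is substituted directly; \eqn{S} is integrated
#' with \code{deSolve::ode} (lsoda) at tight tolerance.
#'
#' @param S0,x0 initial conditions (\code{S0} in \eqn{[0,1]},
#'   \code{x0 >= 0}).
#' @param params a \code{\link{gating_params}} object.
#' @param duration interval length (ms), > 0.
#' @param step output sampling step (ms), > 0.
#' @param rtol,atol integrator tolerances.
#' @return A data frame with columns \code{time}, \code{S}, \code{x}.
#' @export
exact_gating_evolve <- function(S0 = 0, x0 = 0, params = gating_params(),
                                duration, step = 0.1,
                                rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "gating_params"), duration > 0)
  if (step <= 0) stop("step must be positive")
  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  if (S0 == 0 && x0 == 0) {
    return(data.frame(time = times, S = 0, x = 0))
  }
  rhs <- function(t, y, p) {
    x <- x0 * exp(-t / p$tau_r)
    list(-y[1] / p$tau_d + p$alpha * x * (1 - y[1]))
  }
  sol <- deSolve::ode(y = c(S = S0), times = times, func = rhs, parms = params,
                      rtol = rtol, atol = atol)
  data.frame(time = sol[, "time"], S = sol[, "S"],
             x = x0 * exp(-sol[, "time"] / params$tau_r))
}

#' Evolve the aggregated (approximate) gating variable
#'
#' The aggregated variable obeys \eqn{dS/dt = -S/\tau_d} between events and
#' jumps by the transmitted \eqn{\Delta S} at each event. Both pieces have
#' exact closed forms, so no ODE solver is involved: between events the
#' exponential propagator is applied directly.
#'
#' @param S0 initial value (>= 0).
#' @param params a \code{\link{gating_params}} object (only \code{tau_d} is
#'   used).
#' @param events data frame with columns \code{time} (ms, sorted, within
#'   \code{[0, duration]}) and \code{delta_S}. Negative increments are
#'   allowed only if the trajectory stays non-negative.
#' @param duration total time (ms).
#' @param step output sampling step (ms).
#' @return Data frame with columns \code{time}, \code{S}; event increments
#'   are included at output points at or after the event time.
#' @export
approx_gating_evolve <- function(S0 = 0, params = gating_params(), events,
                                 duration, step = 0.1) {
  stopifnot(S0 >= 0, duration > 0, step > 0)
  if (missing(events) || is.null(events) || nrow(events) == 0) {
    events <- data.frame(time = numeric(0), delta_S = numeric(0))
  }
  stopifnot(!is.unsorted(events$time),
            all(events$time >= 0), all(events$time <= duration))
  tau_d <- params$tau_d
  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  S <- numeric(length(times))
  cur <- S0
  t_cur <- 0
  ev <- 1L
  n_ev <- nrow(events)
  for (i in seq_along(times)) {
    t_out <- times[i]
    # apply all events with time <= t_out (events at exactly t_out included)
    while (ev <= n_ev && events$time[ev] <= t_out) {
      cur <- cur * exp(-(events$time[ev] - t_cur) / tau_d)
      t_cur <- events$time[ev]
      cur <- cur + events$delta_S[ev]
      if (cur < 0)
        stop("aggregated gating became negative at t = ", t_cur,
             " (inconsistent upstream bookkeeping)")
      ev <- ev + 1L
    }
    cur <- cur * exp(-(t_out - t_cur) / tau_d)
    t_cur <- t_out
    S[i] <- cur
  }
  data.frame(time = times, S = S)
}

#' Steady-state pre-spike gating value under periodic spiking
#'
#' For a single synapse spiking periodically with interval \eqn{\Delta t},
#' the jump-decay map \eqn{S \mapsto (k_0 + k_1' S) e^{-\Delta t/\tau_d}}
#' has fixed point
#' \deqn{S^* = \frac{k_0 e^{-\Delta t/\tau_d}}{1 - k_1' e^{-\Delta t/\tau_d}},}
#' the pre-spike value the approximate variable converges to.
#'
#' @param jc a \code{\link{jump_constants}} object.
#' @param interval inter-spike interval (ms).
#' @param tau_d decay time constant (ms).
#' @return The steady-state pre-spike value.
#' @export
periodic_steady_state <- function(jc, interval, tau_d) {
  stopifnot(inherits(jc, "jump_constants"), interval > 0, tau_d > 0)
  d <- exp(-interval / tau_d)
  jc$k0 * d / (1 - jc$k1_prime * d)
}
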