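#' Conductance-based LIF neuron parameters
#'
#' Defaults follow the binary decision-making network of Wang (2002), with
#' one parameter column for excitatory (pyramidal) and one for inhibitory
#' (interneuron) cells. The external Poisson drive enters AMPA receptors
#' through its own conductance \code{g_AMPA_ext} (2.1 nS excitatory, 1.62 nS
#' inhibitory), separate from the recurrent \code{g_AMPA}, so that recurrent
#' conductances can be rescaled with network size while the external drive
#' stays fixed.
#'
#' Two parameter variants are available. \code{"wang2002"} (the default)
#' uses the GABA decay constant and interneuron capacitance of the
#' replicated study (\eqn{\tau_{GABA} = 5} ms, \eqn{C_{m,I} = 200} pF),
#' which yield a stable low-rate spontaneous state (about 3 spikes/s
#' excitatory, 8 spikes/s inhibitory at full scale) and winner-take-all
#' decision dynamics. \code{"printed"} uses \eqn{\tau_{GABA} = 2} ms and
#' \eqn{C_{m,I} = 250} pF; under these values the network has no stable
#' low-rate spontaneous state, but the sparse-network clamp experiments
#' reproduce the reported connectivity fragility, so that protocol uses
#' this variant by default. See the methods vignette for the full analysis.
#'
#' @param type "excitatory" or "inhibitory"; selects the default column.
#' @param variant "wang2002" or "printed"; see Details.
#' @param ... named overrides for any field: \code{C_m} (pF), \code{g_L}
#'   (nS), \code{E_L}, \code{V_thr}, \code{V_reset}, \code{V_E}, \code{V_I}
#'   (mV), \code{t_ref} (ms), \code{g_AMPA}, \code{g_AMPA_ext},
#'   \code{g_GABA}, \code{g_NMDA} (nS), \code{Mg} (mM), \code{tau_AMPA},
#'   \code{tau_GABA} (ms), \code{gating} (a \code{\link{gating_params}}).
#' @return An object of class \code{neuron_params}.
#' @examples
#' neuron_params("excitatory")$C_m    # 500 pF
#' neuron_params("inhibitory")$t_ref  # 1 ms
#' @export
neuron_params <- function(type = c("excitatory", "inhibitory"),
                          variant = c("wang2002", "printed"), ...) {
  type <- match.arg(type)
  variant <- match.arg(variant)
  p <- if (type == "excitatory") {
    list(C_m = 500, g_L = 25, E_L = -70, V_thr = -50, V_reset = -55,
         t_ref = 2, g_AMPA = 0.05, g_AMPA_ext = 2.1, g_GABA = 1.3,
         g_NMDA = 0.165, V_E = 0, V_I = -70, Mg = 1,
         tau_AMPA = 2, tau_GABA = 5, gating = gating_params())
  } else {
    list(C_m = 200, g_L = 20, E_L = -70, V_thr = -50, V_reset = -55,
         t_ref = 1, g_AMPA = 0.04, g_AMPA_ext = 1.62, g_GABA = 1.0,
         g_NMDA = 0.13, V_E = 0, V_I = -70, Mg = 1,
         tau_AMPA = 2, tau_GABA = 5, gating = gating_params())
  }
  if (variant == "printed") {
    p$tau_GABA <- 2
    if (type == "inhibitory") p$C_m <- 250
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown neuron parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p$type <- type
  validate_neuron_params(structure(p, class = "neuron_params"))
}

validate_neuron_params <- function(p) {
  stopifnot(p$C_m > 0, p$g_L > 0, p$t_ref >= 0,
            p$tau_AMPA > 0, p$tau_GABA > 0,
            inherits(p$gating, "gating_params"))
  if (p$V_reset >= p$V_thr) stop("V_reset must be below V_thr")
  p
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' @param V membrane potential (mV), vectorized.
#' @param Mg magnesium concentration (mM).
#' @return \eqn{1 / (1 + [Mg^{2+}] e^{-0.062 V} / 3.57)}, in \eqn{(0, 1]}
#'   for \code{Mg >= 0} and strictly increasing in \code{V}.
#' @examples
#' mg_block_factor(0)    # about 0.781
#' mg_block_factor(-70)  # about 0.044: strong block at rest
#' @export
mg_block_factor <- function(V, Mg = 1) {
  1 / (1 + Mg * exp(-0.062 * V) / 3.57)
}

#' Total synaptic current of a neuron
#'
#' \deqn{I_{syn} = I_{AMPA} + I_{NMDA} + I_{GABA}} with
#' \eqn{I_{AMPA} = g_{AMPA}(V - V_E) S_{AMPA}},
#' \eqn{I_{GABA} = g_{GABA}(V - V_I) S_{GABA}}, and the NMDA current gated by
#' the magnesium block. Synaptic weights are already folded into the
#' aggregated \code{S} variables. Units: nS x mV = pA. A positive value is a
#' hyperpolarizing current in the membrane equation
#' \eqn{C_m dV/dt = -g_L (V - E_L) - I_{syn}}.
#'
#' @param V membrane potential (mV).
#' @param S_AMPA,S_GABA,S_NMDA aggregated, weight-scaled gating values.
#' @param params a \code{\link{neuron_params}} object.
#' @param S_AMPA_ext aggregated external-drive AMPA gating (uses
#'   \code{g_AMPA_ext}).
#' @return List with components \code{AMPA}, \code{NMDA}, \code{GABA},
#'   \code{total} (pA).
#' @export
synaptic_current <- function(V, S_AMPA, S_GABA, S_NMDA, params,
                             S_AMPA_ext = 0) {
  stopifnot(inherits(params, "neuron_params"))
  i_ampa <- params$g_AMPA * (V - params$V_E) * S_AMPA +
    params$g_AMPA_ext * (V - params$V_E) * S_AMPA_ext
  i_gaba <- params$g_GABA * (V - params$V_I) * S_GABA
  i_nmda <- params$g_NMDA * (V - params$V_E) *
    mg_block_factor(V, params$Mg) * S_NMDA
  list(AMPA = i_ampa, NMDA = i_nmda, GABA = i_gaba,
       total = i_ampa + i_nmda + i_gaba)
}

#' Integrate a single neuron over a time span
#'
#' Advances a conductance-based LIF neuron on the \code{dt} grid using
#' embedded RKF45 with adaptive substeps confined to each interval. Spikes
#' are checked only at grid points; on threshold crossing the membrane is
#' reset and clamped for the refractory period (rounded up to whole grid
#' steps) while the synaptic gating continues to evolve. Input spike trains
#' drive the NMDA receptor (exact two-variable kinetics or the jump
#' approximation) with connection weight \code{weight}; a constant current
#' can be injected instead of, or in addition to, synaptic input.
#'
#' @param params a \code{\link{neuron_params}} object.
#' @param T_total simulated time (ms).
#' @param dt grid step (ms).
#' @param input optional list of integer vectors: for each presynaptic
#'   source, the 1-based grid-bin indices at which it spikes.
#' @param weight synaptic weight applied to every source.
#' @param backend "approximate" or "exact" NMDA kinetics.
#' @param I_const constant injected current (pA; negative depolarizes,
#'   matching the sign convention of the membrane equation).
#' @param V0 initial membrane potential (default \code{E_L}).
#' @param record_current if TRUE, the NMDA current trace is returned.
#' @param atol,rtol RKF45 tolerances.
#' @return List with \code{time} (grid, ms), \code{V} (mV), \code{spikes}
#'   (spike times, ms), \code{S_NMDA} (weighted aggregated gating trace) and
#'   optionally \code{I_NMDA} (pA).
#' @export
integrate_neuron <- function(params, T_total, dt = 0.1, input = list(),
                             weight = 1, backend = c("approximate", "exact"),
                             I_const = 0, V0 = NULL,
                             record_current = TRUE,
                             atol = 1e-6, rtol = 1e-6) {
  stopifnot(inherits(params, "neuron_params"), T_total > 0)
  if (dt <= 0) stop("dt must be positive")
  backend <- match.arg(backend)
  n_steps <- as.integer(round(T_total / dt))
  src_bins <- lapply(input, function(b) as.integer(b) - 1L)
  res <- cpp_single_neuron(
    src_bins, weight, neuron_param_vector(params), dt, n_steps,
    backend == "exact", I_const,
    if (is.null(V0)) params$E_L else V0, atol, rtol)
  out <- list(time = res$time, V = res$V, spikes = res$spikes,
              S_NMDA = res$S_NMDA)
  if (record_current) out$I_NMDA <- res$I_NMDA
  out
}

# flatten neuron + gating params into the numeric layout the C++ core expects
neuron_param_vector <- function(p) {
  g <- p$gating
  c(C_m = p$C_m, g_L = p$g_L, E_L = p$E_L, V_thr = p$V_thr,
    V_reset = p$V_reset, t_ref = p$t_ref, g_AMPA = p$g_AMPA,
    g_AMPA_ext = p$g_AMPA_ext, g_GABA = p$g_GABA, g_NMDA = p$g_NMDA,
    V_E = p$V_E, V_I = p$V_I, Mg = p$Mg, tau_AMPA = p$tau_AMPA,
    tau_GABA = p$tau_GABA, alpha = g$alpha, tau_r = g$tau_r,
    tau_d = g$tau_d)
}
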