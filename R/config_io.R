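#' Default run configuration
#'
#' All fields of a run configuration with the standard decision-network
#' values pre-populated. Units are fixed package-wide: ms, mV, nS, pF, pA,
#' spikes/s.
#'
#' @return A named list (class \code{run_config}).
#' @export
default_config <- function() {
  structure(list(
    network = list(scale = 1, f = 0.15, w_plus = 1.7, w_minus = NULL,
                   w_minus_literal = FALSE, delay_ms = 0.5, dt_ms = 0.1,
                   epsilon = 1, eps_selective = NULL, eps_inhibitory = NULL),
    stimulus = list(nu_ext = 2400, mu0 = 40, rho_A = 0.4, rho_B = 0.4,
                    coherence = 0, resample_interval_ms = 50, rate_sd = 4,
                    window_ms = c(1000, 3000)),
    clamp = NULL,
    backend = "approximate",
    T_ms = 4000,
    master_seed = 1,
    record = list(every_ms = 1, neurons = integer(0)),
    output_dir = "."),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills omitted fields with the defaults of
#' \code{\link{default_config}}, and validates; every violation found is
#' reported at once.
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @return A validated \code{run_config}.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

merge_config <- function(base, user, prefix = "") {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                prefix = paste0(prefix, k, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Validate a run configuration
#'
#' @param cfg a \code{run_config} list.
#' @return The config, invisibly extended with derived fields; stops with a
#'   message listing every violation otherwise.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  nw <- cfg$network
  dt <- nw$dt_ms
  if (!is.numeric(dt) || dt <= 0) push("network.dt_ms must be positive")
  grid_ok <- function(x) {
    is.numeric(x) && all(abs(x / dt - round(x / dt)) < 1e-6)
  }
  if (is.numeric(dt) && dt > 0) {
    if (!grid_ok(nw$delay_ms) || nw$delay_ms < dt)
      push("network.delay_ms must be a multiple of dt_ms and >= dt_ms")
    if (!grid_ok(cfg$T_ms)) push("T_ms must be a multiple of dt_ms")
    if (!grid_ok(cfg$stimulus$window_ms))
      push("stimulus.window_ms must lie on the dt grid")
    p <- cfg$stimulus$nu_ext * dt / 1000
    if (is.numeric(p) && p > 1)
      push("stimulus.nu_ext too high for dt_ms (per-bin probability > 1)")
  }
  if (!cfg$backend %in% c("approximate", "exact", "exact_per_synapse"))
    push("backend must be approximate, exact or exact_per_synapse")
  if (nw$f < 0 || nw$f > 0.5) push("network.f must lie in [0, 0.5]")
  for (e in c("epsilon", "eps_selective", "eps_inhibitory")) {
    v <- nw[[e]]
    if (!is.null(v) && (v <= 0 || v > 1))
      push(paste0("network.", e, " must lie in (0, 1]"))
  }
  if (cfg$master_seed != round(cfg$master_seed) ||
      cfg$master_seed < 0 || cfg$master_seed >= 2^31)
    push("master_seed must be a non-negative integer below 2^31")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  if (cfg$backend == "exact" && cfg$network$scale >= 1)
    message("note: the exact backend at full scale is computationally ",
            "expensive; consider the approximate backend")
  invisible(cfg)
}

#' Build a network specification from a run configuration
#'
#' @param cfg a validated \code{run_config}.
#' @return A \code{\link{decision_network}} specification.
#' @export
config_to_network <- function(cfg) {
  nw <- cfg$network
  wm <- nw$w_minus
  if (is.null(wm)) wm <- w_minus(nw$f, nw$w_plus, literal = nw$w_minus_literal)
  decision_network(
    scale = nw$scale, f = nw$f, w_plus = nw$w_plus, w_minus_value = wm,
    delay = nw$delay_ms, dt = nw$dt_ms, epsilon = nw$epsilon,
    eps_selective = if (is.null(nw$eps_selective)) nw$epsilon
                    else nw$eps_selective,
    eps_inhibitory = if (is.null(nw$eps_inhibitory)) nw$epsilon
                     else nw$eps_inhibitory,
    nu_ext = cfg$stimulus$nu_ext)
}

#' Save a run configuration to YAML
#'
#' @param cfg a \code{run_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Derive independent substream seeds from a master seed
#'
#' Deterministic, collision-resistant fan-out of one master seed into named
#' substreams (connectivity, background drive, stimulus, bootstrap, ...):
#' each label is hashed with a polynomial rolling hash and combined with the
#' master seed modulo a Mersenne prime below 2^31.
#'
#' @param master_seed non-negative integer below 2^31.
#' @param labels distinct character labels.
#' @return Named integer vector of seeds.
#' @examples
#' derive_seeds(42, c("connectivity", "drive"))
#' @export
derive_seeds <- function(master_seed, labels) {
  stopifnot(master_seed >= 0, master_seed == round(master_seed))
  if (anyDuplicated(labels)) stop("duplicate stream labels")
  m <- 2147483647  # 2^31 - 1
  out <- vapply(labels, function(lab) {
    h <- 0
    for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% m
    as.integer((h * 48271 + master_seed * 69621 + 7919) %% m)
  }, integer(1))
  names(out) <- labels
  out
}

#' Write spikes as delimited text
#'
#' Two tab-separated columns (\code{neuron_id}, \code{time_ms}) with a
#' header, one row per spike, stably sorted by (time, neuron).
#'
#' @param spikes data frame with columns \code{neuron}, \code{time}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  ord <- order(spikes$time, spikes$neuron)
  df <- data.frame(neuron_id = spikes$neuron[ord],
                   time_ms = spikes$time[ord])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spikes written by \code{\link{write_spikes}}
#'
#' @param path input path.
#' @return Data frame with columns \code{neuron}, \code{time}.
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(neuron = df$neuron_id, time = df$time_ms)
}
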