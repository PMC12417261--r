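#' Binned population firing rate
#'
#' Summed population spiking histogram averaged over fixed bins:
#' per-bin spike count divided by (population size x bin duration), in
#' spikes/s.
#'
#' @param spikes data frame with columns \code{neuron}, \code{time} (ms).
#' @param ids neuron ids belonging to the population.
#' @param bin bin width (ms, default 50).
#' @param T_total total duration (ms).
#' @return Data frame with columns \code{time} (bin centers, ms) and
#'   \code{rate} (spikes/s).
#' @export
binned_population_rate <- function(spikes, ids, bin = 50, T_total) {
  stopifnot(bin > 0, T_total > 0)
  if (length(ids) == 0) stop("empty population")
  n_bins <- ceiling(T_total / bin)
  sel <- spikes$time[spikes$neuron %in% ids]
  idx <- pmin(pmax(ceiling(sel / bin), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(time = (seq_len(n_bins) - 0.5) * bin,
             rate = counts / (length(ids) * bin / 1000))
}

#' Root-mean-square difference of two sampled traces
#'
#' @param a,b numeric vectors on the same sampling grid.
#' @return \eqn{\sqrt{mean((a-b)^2)}}.
#' @export
rms_difference <- function(a, b) {
  if (length(a) != length(b)) stop("traces differ in length")
  sqrt(mean((a - b)^2))
}

#' Weibull psychometric function
#'
#' \deqn{P(correct) = 1 - 0.5\,e^{-(c'/\alpha)^\beta}}
#'
#' @param coherence coherence values (percent).
#' @param alpha coherence scale (percent), > 0.
#' @param beta shape, > 0.
#' @return Probability of a correct decision.
#' @export
weibull_p <- function(coherence, alpha, beta) {
  1 - 0.5 * exp(-(coherence / alpha)^beta)
}

#' Maximum-likelihood Weibull fit to psychometric data
#'
#' Fits Bernoulli outcomes (number correct out of number of trials at each
#' coherence) to the Weibull psychometric function by maximizing the
#' binomial log-likelihood over \eqn{(\log\alpha, \log\beta)} with a fixed
#' optimizer start, so the fit is deterministic given the data. Zero
#' coherence carries no correctness information and is excluded.
#'
#' @param coherence coherence levels (percent).
#' @param n_correct correct-decision counts per level.
#' @param n_trials trial counts per level.
#' @param start starting values \code{c(alpha, beta)}.
#' @return List with \code{alpha}, \code{beta}, \code{logLik},
#'   \code{identifiable} (FALSE when the curve is degenerate: all outcomes
#'   identical or the scale runs away), and \code{fitted} probabilities.
#' @export
fit_weibull <- function(coherence, n_correct, n_trials,
                        start = c(alpha = 10, beta = 1)) {
  stopifnot(length(coherence) == length(n_correct),
            length(coherence) == length(n_trials), all(n_trials >= 1),
            all(n_correct >= 0), all(n_correct <= n_trials))
  keep <- coherence > 0
  coherence <- coherence[keep]
  n_correct <- n_correct[keep]
  n_trials <- n_trials[keep]
  if (length(coherence) < 2)
    stop("need at least two positive-coherence points")
  nll <- function(par) {
    p <- weibull_p(coherence, exp(par[1]), exp(par[2]))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(n_correct * log(p) + (n_trials - n_correct) * log(1 - p))
  }
  fit <- stats::optim(log(start), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  # quasi-Newton polish from the simplex optimum
  fit <- stats::optim(fit$par, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  alpha <- exp(fit$par[[1]])
  beta <- exp(fit$par[[2]])
  phat <- n_correct / n_trials
  identifiable <- !(all(phat == phat[1]) || alpha > 100 * max(coherence) ||
                      alpha < min(coherence) / 100)
  list(alpha = alpha, beta = beta, logLik = -fit$value,
       identifiable = identifiable,
       fitted = weibull_p(coherence, alpha, beta))
}

#' Percentile bootstrap confidence interval for a proportion
#'
#' Resamples binary outcomes with replacement and takes percentile bounds of
#' the resampled proportions. Deterministic given the seed; the endpoints
#' are achievable empirical proportions (type-1 quantiles).
#'
#' @param outcomes binary vector (0/1 or logical).
#' @param n_resamples number of bootstrap resamples (default 5000).
#' @param level confidence level (default 0.90).
#' @param seed optional seed for a self-contained draw.
#' @return Named vector \code{c(low, high)}.
#' @export
bootstrap_ci <- function(outcomes, n_resamples = 5000, level = 0.9,
                         seed = NULL) {
  outcomes <- as.numeric(outcomes)
  n <- length(outcomes)
  stopifnot(n >= 1, n_resamples >= 1, level > 0, level < 1)
  draw <- function() {
    props <- vapply(seq_len(n_resamples), function(...) {
      mean(outcomes[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    stats::quantile(props, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE, type = 1)
  }
  ci <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  c(low = ci[1], high = ci[2])
}

#' Population-averaged source gating trace
#'
#' Arithmetic mean over a population's own (outgoing) NMDA gating variables:
#' the local jump-map variables of the approximate backend, or the exact
#' source gating variables.
#'
#' @param sim a result of \code{\link{simulate_network}} run with
#'   \code{record_every > 0}.
#' @param label population label.
#' @return Data frame with columns \code{time}, \code{S}.
#' @export
population_mean_gating <- function(sim, label) {
  if (!label %in% names(sim$pop_S)) stop("unknown population label: ", label)
  data.frame(time = sim$rec_times, S = sim$pop_S[[label]])
}
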