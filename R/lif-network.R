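#' Parameters of a balanced random LIF network
#'
#' Bundles the structural and single-neuron constants of a fixed in-degree
#' balanced random network of leaky integrate-and-fire (LIF) neurons with
#' delta-pulse synapses. The defaults are the classical inhibition-dominated
#' configuration: 10000 excitatory and 2500 inhibitory neurons, each receiving
#' input from a randomly chosen 10% of either population, excitatory PSP
#' amplitude \eqn{J = 0.1} mV, inhibition/excitation weight ratio \eqn{g = 6},
#' membrane time constant \eqn{\tau = 20} ms, threshold \eqn{\theta = 20} mV,
#' reset at 10 mV, 2 ms absolute refractoriness, a synaptic delay equal to the
#' 0.01 ms integration step, and an external Poisson drive of 25 spikes/ms per
#' neuron delivered with weight \eqn{+J}.
#'
#' @param n_exc,n_inh number of excitatory / inhibitory neurons.
#' @param epsilon in-degree fraction: every neuron receives exactly
#'   `round(epsilon * n_exc)` excitatory and `round(epsilon * n_inh)`
#'   inhibitory inputs.
#' @param j_psp excitatory post-synaptic potential amplitude (mV).
#' @param g ratio of inhibitory to excitatory synaptic weight (dimensionless);
#'   inhibitory events deflect the membrane by `-g * j_psp`.
#' @param tau_m membrane time constant (ms).
#' @param theta spike threshold (mV).
#' @param v_reset reset potential (mV); must be below `theta`.
#' @param t_ref absolute refractory period (ms).
#' @param t_delay synaptic transmission delay (ms), a multiple of `dt_sim`.
#' @param nu_ext total external Poisson rate per neuron (spikes/ms).
#' @param dt_sim integration step (ms).
#'
#' @return An object of class `network_params` (a named list).
#' @seealso [build_adjacency()], [simulate_lif()]
#' @export
network_params <- function(n_exc = 10000L, n_inh = 2500L, epsilon = 0.1,
                           j_psp = 0.1, g = 6, tau_m = 20, theta = 20,
                           v_reset = 10, t_ref = 2, t_delay = 0.01,
                           nu_ext = 25, dt_sim = 0.01) {
  p <- list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
            epsilon = epsilon, j_psp = j_psp, g = g, tau_m = tau_m,
            theta = theta, v_reset = v_reset, t_ref = t_ref,
            t_delay = t_delay, nu_ext = nu_ext, dt_sim = dt_sim)
  if (p$theta <= p$v_reset) stop("theta must exceed v_reset")
  if (p$epsilon < 0 || p$epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (p$tau_m <= 0 || p$dt_sim <= 0) stop("tau_m and dt_sim must be positive")
  if (p$t_ref < 0 || p$nu_ext < 0) stop("t_ref and nu_ext must be nonnegative")
  if (p$t_delay < p$dt_sim - 1e-12) stop("t_delay must be at least dt_sim")
  if (abs(p$t_delay / p$dt_sim - round(p$t_delay / p$dt_sim)) > 1e-9)
    stop("t_delay must be an integer multiple of dt_sim")
  structure(p, class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("Balanced LIF network parameters\n")
  cat(sprintf("  populations: %d excitatory, %d inhibitory (epsilon = %g)\n",
              x$n_exc, x$n_inh, x$epsilon))
  cat(sprintf("  synapses: J = %g mV, g = %g, delay = %g ms\n",
              x$j_psp, x$g, x$t_delay))
  cat(sprintf("  neuron: tau = %g ms, theta = %g mV, reset = %g mV, t_ref = %g ms\n",
              x$tau_m, x$theta, x$v_reset, x$t_ref))
  cat(sprintf("  drive: %g spikes/ms external Poisson; dt_sim = %g ms\n",
              x$nu_ext, x$dt_sim))
  invisible(x)
}

# sample k distinct sources for one target, excluding the target itself when
# it belongs to the source population
sample_sources <- function(n_pop, k, exclude) {
  if (k == 0L) return(integer(0))
  if (is.na(exclude)) {
    sample.int(n_pop, k)
  } else {
    s <- sample.int(n_pop - 1L, k)
    s + (s >= exclude)
  }
}

#' Draw a fixed in-degree random adjacency
#'
#' Every neuron receives exactly `round(epsilon * n_exc)` excitatory and
#' `round(epsilon * n_inh)` inhibitory presynaptic partners, drawn uniformly
#' without replacement and excluding the neuron itself. Neurons are indexed
#' `1..n_exc` (excitatory) and `n_exc+1..n_exc+n_inh` (inhibitory).
#'
#' @param params a [network_params()] object.
#' @param seed integer seed; the adjacency is reproducible for a fixed seed.
#' @return An object of class `adjacency`: a list with integer matrices
#'   `exc_sources` (`k_exc` rows) and `inh_sources` (`k_inh` rows), one column
#'   per neuron, entries in global neuron indices.
#' @export
build_adjacency <- function(params, seed = 1L) {
  stopifnot(inherits(params, "network_params"))
  k_exc <- as.integer(round(params$epsilon * params$n_exc))
  k_inh <- as.integer(round(params$epsilon * params$n_inh))
  n_tot <- params$n_exc + params$n_inh
  if (params$n_exc > 0L && k_exc >= params$n_exc && k_exc > 0L)
    stop("cannot draw ", k_exc, " distinct excitatory sources excluding self ",
         "from a population of ", params$n_exc)
  if (params$n_inh > 0L && k_inh >= params$n_inh && k_inh > 0L)
    stop("cannot draw ", k_inh, " distinct inhibitory sources excluding self ",
         "from a population of ", params$n_inh)
  set.seed(seed)
  exc <- matrix(0L, nrow = k_exc, ncol = n_tot)
  inh <- matrix(0L, nrow = k_inh, ncol = n_tot)
  for (i in seq_len(n_tot)) {
    excl_e <- if (i <= params$n_exc) i else NA_integer_
    excl_i <- if (i > params$n_exc) i - params$n_exc else NA_integer_
    if (k_exc > 0L)
      exc[, i] <- sample_sources(params$n_exc, k_exc, excl_e)
    if (k_inh > 0L)
      inh[, i] <- sample_sources(params$n_inh, k_inh, excl_i) + params$n_exc
  }
  structure(list(exc_sources = exc, inh_sources = inh,
                 n_exc = params$n_exc, n_inh = params$n_inh),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("Fixed in-degree adjacency: %d neurons, %d exc + %d inh sources each\n",
              x$n_exc + x$n_inh, nrow(x$exc_sources), nrow(x$inh_sources)))
  invisible(x)
}

#' Simulate the spiking network
#'
#' Integrates the LIF dynamics
#' \deqn{\tau \dot v_i(t) = -v_i(t) + \tau \sum_j J_{ij} S_j(t - t_d)}
#' on a fixed grid of step `dt_sim`: between steps the membrane decays exactly
#' (factor \eqn{e^{-dt/\tau}}); recurrent events arriving within a step are
#' accumulated and applied at the step boundary after the transmission delay;
#' each neuron additionally receives an independent external Poisson stream of
#' rate `nu_ext` with increment `+j_psp`. Crossing `theta` emits a spike and
#' clamps the potential at `v_reset` for `t_ref`; events arriving during
#' refractoriness are discarded.
#'
#' @param params a [network_params()] object.
#' @param adjacency an [build_adjacency()] result consistent with `params`.
#' @param duration simulated time (ms).
#' @param seed integer seed; identical `(params, adjacency, seed)` give
#'   bit-identical spike sets.
#' @param v0 optional vector of initial membrane potentials (mV); defaults to
#'   all zeros.
#' @param record_v optional integer vector of neuron indices whose membrane
#'   potential trace is returned (attribute `v_trace`, one column per neuron).
#' @return A `spike_train_set`: a data frame with columns `neuron` and
#'   `time_ms`, with attributes `n_exc`, `n_inh`, `duration_ms` and `dt_sim`.
#' @export
simulate_lif <- function(params, adjacency, duration, seed = 1L,
                         v0 = NULL, record_v = integer(0)) {
  stopifnot(inherits(params, "network_params"), inherits(adjacency, "adjacency"))
  if (duration <= 0) stop("duration must be positive")
  if (adjacency$n_exc != params$n_exc || adjacency$n_inh != params$n_inh)
    stop("adjacency was built for a different network size")
  n_tot <- params$n_exc + params$n_inh
  if (is.null(v0)) v0 <- numeric(n_tot)
  if (length(v0) != n_tot) stop("v0 must have one entry per neuron")
  set.seed(seed)
  res <- lif_simulate_cpp(params$n_exc, params$n_inh,
                          adjacency$exc_sources, adjacency$inh_sources,
                          params$j_psp, params$g, params$tau_m, params$theta,
                          params$v_reset, params$t_ref, params$t_delay,
                          params$nu_ext, params$dt_sim, duration,
                          as.numeric(v0), as.integer(record_v))
  spike_train_set(res$neuron, res$time_ms,
                  n_exc = params$n_exc, n_inh = params$n_inh,
                  duration_ms = duration, dt_sim = params$dt_sim,
                  v_trace = if (length(record_v)) res$v_trace else NULL)
}

#' Construct a spike train set
#'
#' @param neuron integer neuron indices (1-based; excitatory first).
#' @param time_ms spike times in ms.
#' @param n_exc,n_inh population sizes.
#' @param duration_ms total duration (ms).
#' @param dt_sim time resolution of the generating process (ms), if known.
#' @param v_trace optional membrane trace matrix carried as an attribute.
#' @return A data frame of class `spike_train_set`.
#' @export
spike_train_set <- function(neuron, time_ms, n_exc, n_inh, duration_ms,
                            dt_sim = NA_real_, v_trace = NULL) {
  if (length(neuron) != length(time_ms))
    stop("neuron and time_ms must have equal length")
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) > duration_ms))
    stop("spike times must lie in [0, duration_ms]")
  x <- data.frame(neuron = as.integer(neuron), time_ms = as.numeric(time_ms))
  attr(x, "n_exc") <- as.integer(n_exc)
  attr(x, "n_inh") <- as.integer(n_inh)
  attr(x, "duration_ms") <- duration_ms
  attr(x, "dt_sim") <- dt_sim
  if (!is.null(v_trace)) attr(x, "v_trace") <- v_trace
  class(x) <- c("spike_train_set", "data.frame")
  x
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike train set: %d events, %d exc + %d inh neurons, %g ms\n",
              nrow(x), attr(x, "n_exc"), attr(x, "n_inh"),
              attr(x, "duration_ms")))
  invisible(x)
}
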