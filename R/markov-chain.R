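#' Estimate an empirical state-transition model
#'
#' Maximum-likelihood (frequency) estimate of the transition probabilities of
#' the joint count process: for every observed source state \eqn{(i, j)} the
#' successor counts are normalized into a row-stochastic distribution over the
#' observed successor states.
#'
#' @param series a [count_series()].
#' @return An object of class `transition_model`: a data frame with columns
#'   `i`, `j`, `i_next`, `j_next`, `prob` (sparse triplet form), plus
#'   attributes `dt` and `states` (the distinct source states).
#' @export
estimate_transitions <- function(series) {
  stopifnot(inherits(series, "count_series"))
  n <- nrow(series)
  if (n < 2) stop("series must have at least two bins")
  m <- max(series$S_i) + 1L
  key <- series$S_e * m + series$S_i
  from <- key[-n]; to <- key[-1]
  kmax <- max(key) + 1
  pair <- from * kmax + to           # < 2^53 for any realistic count range
  o <- order(pair)
  pair <- pair[o]
  grp <- cumsum(c(TRUE, diff(pair) != 0))
  cnt <- tabulate(grp)
  upair <- pair[!duplicated(pair)]
  uf <- floor(upair / kmax)
  ut <- upair - uf * kmax
  row_tot <- rowsum(cnt, uf, reorder = FALSE)[, 1]
  prob <- cnt / rep(row_tot, times = tabulate(cumsum(c(TRUE, diff(uf) != 0))))
  out <- data.frame(i = as.integer(uf %/% m), j = as.integer(uf %% m),
                    i_next = as.integer(ut %/% m), j_next = as.integer(ut %% m),
                    prob = prob)
  attr(out, "dt") <- attr(series, "dt")
  attr(out, "m") <- m
  class(out) <- c("transition_model", "data.frame")
  out
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Empirical transition model: %d transitions over %d source states (dt = %g ms)\n",
              nrow(x), length(unique(x$i * attr(x, "m") + x$j)), attr(x, "dt")))
  invisible(x)
}

#' Sample a count series from a transition model
#'
#' Generates a trajectory by iterating the empirical chain. A visited state
#' with no outgoing transitions (a state observed only as the final sample of
#' the training series) redirects to the nearest source state in Euclidean
#' \eqn{(i, j)} distance before drawing the successor.
#'
#' @param model a [estimate_transitions()] result.
#' @param n_steps trajectory length.
#' @param init integer pair `c(i, j)`; must be a source state of the model.
#' @param seed integer seed.
#' @return A [count_series()] at the model's `dt`.
#' @export
sample_chain <- function(model, n_steps, init, seed = 1L) {
  stopifnot(inherits(model, "transition_model"))
  m <- attr(model, "m")
  key_from <- model$i * m + model$j
  rows <- split(seq_len(nrow(model)), key_from)
  src_keys <- as.numeric(names(rows))
  src_i <- floor(src_keys / m); src_j <- src_keys - src_i * m
  k0 <- init[1] * m + init[2]
  if (!k0 %in% src_keys) stop("init state not present in the model")
  set.seed(seed)
  S_e <- integer(n_steps); S_i <- integer(n_steps)
  key <- k0
  for (t in seq_len(n_steps)) {
    idx <- rows[[as.character(key)]]
    if (is.null(idx)) {  # dead end: snap to nearest observed source state
      ci <- floor(key / m); cj <- key - ci * m
      near <- which.min((src_i - ci)^2 + (src_j - cj)^2)
      key <- src_keys[near]
      idx <- rows[[near]]
    }
    r <- if (length(idx) == 1L) idx else
      idx[sample.int(length(idx), 1L, prob = model$prob[idx])]
    S_e[t] <- model$i_next[r]
    S_i[t] <- model$j_next[r]
    key <- S_e[t] * m + S_i[t]
  }
  count_series(S_e, S_i, attr(model, "dt"))
}

#' Select the PSTH bin size by spectral self-consistency
#'
#' For every candidate bin width: bins the spike set, estimates the empirical
#' transition model, resamples a surrogate chain of equal length, and compares
#' the Welch power spectra of surrogate and original counts for both
#' populations via [spectrum_distance()]. Returns the candidate with the
#' smallest summed distance — the time scale at which a first-order Markov
#' description reproduces the spectral content of the population activity
#' best. The candidates should bracket the first zero crossings of the two
#' populations' autocorrelations; `c(0.05, 0.07, 0.1, 0.15, 0.2)` ms by
#' default.
#'
#' @param spikes a `spike_train_set`.
#' @param candidates bin widths (ms), multiples of the spike set resolution.
#' @param seed integer seed for the surrogate chains.
#' @param nseg Welch segment length passed to [power_spectrum()].
#' @return The selected bin width (ms), with the per-candidate summed
#'   distances as attribute `distances`.
#' @export
select_bin_size <- function(spikes, candidates = c(0.05, 0.07, 0.1, 0.15, 0.2),
                            seed = 1L, nseg = 2^12) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!length(candidates)) stop("empty candidate list")
  if (length(candidates) == 1L) return(candidates)
  dist <- vapply(seq_along(candidates), function(ci) {
    dt <- candidates[ci]
    series <- bin_counts(spikes, dt)
    model <- estimate_transitions(series)
    surr <- sample_chain(model, nrow(series),
                         c(series$S_e[1], series$S_i[1]), seed = seed + ci)
    d <- 0
    for (pop in c("S_e", "S_i")) {
      pa <- power_spectrum(series[[pop]], dt, nseg = nseg)
      pb <- power_spectrum(surr[[pop]], dt, nseg = nseg)
      d <- d + spectrum_distance(pa, pb)
    }
    d
  }, numeric(1))
  structure(candidates[which.min(dist)],
            distances = stats::setNames(dist, candidates))
}

#' Row sums of a transition model
#'
#' Utility for checking row-stochasticity: returns the summed outgoing
#' probability per source state.
#'
#' @param model a [estimate_transitions()] result.
#' @return Named numeric vector of row sums, one per source state.
#' @export
transition_row_sums <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  key <- model$i * attr(model, "m") + model$j
  rowsum(model$prob, key)[, 1]
}
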