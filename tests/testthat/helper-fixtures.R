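# Shared, lazily computed simulation products. Heavy runs are produced once
# per test session and reused by several test files.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# stationary ARM run at the default fitted constants (reference conditions)
arm_reference_run <- function() {
  memo("arm_ref", simulate_arm(arm_params(), n_steps = 1e6, seed = 101L))
}

# shorter ARM run for fitting round trips
arm_short_run <- function() {
  memo("arm_short", simulate_arm(arm_params(), n_steps = 2e5, seed = 202L))
}

# small balanced network in the same dynamical regime, weights scaled 1/sqrt(N)
tiny_network <- function() {
  memo("tiny_net", {
    j <- 0.1 * sqrt(12500 / 500)   # keep J*sqrt(N) fixed
    par <- network_params(n_exc = 400L, n_inh = 100L, j_psp = j,
                          nu_ext = 25 * 0.1 / j)  # keep the drive mean tau*J*nu_ext
    adj <- build_adjacency(par, seed = 11L)
    spk <- simulate_lif(par, adj, duration = 2000, seed = 11L)
    list(params = par, adjacency = adj, spikes = spk)
  })
}

# full-size 10 s network run shared by the acceptance tests
snn_acceptance_run <- function() {
  memo("snn_acc", {
    par <- network_params()
    adj <- build_adjacency(par, seed = 7L)
    spk <- simulate_lif(par, adj, duration = 10000, seed = 7L)
    list(params = par, spikes = spk)
  })
}

# drop a settling window from the start of a count series
drop_transient <- function(series, t0_ms) {
  keep <- series$time_ms >= t0_ms
  count_series(series$S_e[keep], series$S_i[keep], attr(series, "dt"),
               origin_ms = t0_ms)
}

# brute-force Euler reference integrator for small LIF motifs (event-driven
# oracle): weights[j, i] is the PSP neuron i receives when j spikes.
# Returns a data frame of spike events.
euler_lif_reference <- function(params, weights, duration, h = 0.001,
                                v0 = NULL) {
  n <- nrow(weights)
  n_steps <- round(duration / h)
  delay_steps <- round(params$t_delay / h)
  refr_steps <- round(params$t_ref / h)
  v <- if (is.null(v0)) numeric(n) else v0
  ref_until <- rep(-1L, n)
  pend <- matrix(0, n_steps + delay_steps + 1L, n)
  out_n <- integer(0); out_t <- numeric(0)
  for (t in seq_len(n_steps)) {
    for (i in seq_len(n)) {
      if (t <= ref_until[i]) { v[i] <- params$v_reset; next }
      v[i] <- v[i] + h * (-v[i]) / params$tau_m + pend[t, i]
      if (v[i] >= params$theta) {
        out_n <- c(out_n, i); out_t <- c(out_t, (t - 1) * h)
        v[i] <- params$v_reset
        ref_until[i] <- t + refr_steps - 1L
        pend[t + delay_steps, ] <- pend[t + delay_steps, ] + weights[i, ]
      }
    }
  }
  data.frame(neuron = out_n, time_ms = out_t)
}
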