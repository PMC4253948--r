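test_that("adjacency has exact fixed in-degree, no self-connections, distinct sources", {
  par <- network_params(n_exc = 60L, n_inh = 40L, epsilon = 0.25)
  adj <- build_adjacency(par, seed = 3)
  expect_equal(nrow(adj$exc_sources), 15L)  # round(0.25 * 60)
  expect_equal(nrow(adj$inh_sources), 10L)
  for (i in c(1L, 30L, 61L, 100L)) {
    e <- adj$exc_sources[, i]
    h <- adj$inh_sources[, i]
    expect_false(any(duplicated(e)))
    expect_false(any(duplicated(h)))
    expect_true(all(e >= 1 & e <= 60))
    expect_true(all(h >= 61 & h <= 100))
    expect_false(i %in% c(e, h))
  }
})

test_that("adjacency is seed-reproducible and varies across seeds with fixed in-degree", {
  par <- network_params(n_exc = 20L, n_inh = 20L, epsilon = 0.5)
  a1 <- build_adjacency(par, seed = 1)
  a2 <- build_adjacency(par, seed = 1)
  a3 <- build_adjacency(par, seed = 2)
  expect_identical(a1$exc_sources, a2$exc_sources)
  expect_false(identical(a1$exc_sources, a3$exc_sources))
  expect_equal(dim(a3$exc_sources), dim(a1$exc_sources))
  expect_equal(dim(a3$inh_sources), dim(a1$inh_sources))
})

test_that("full in-degree without self-connections is rejected", {
  par <- network_params(n_exc = 10L, n_inh = 10L, epsilon = 1.0)
  expect_error(build_adjacency(par), "distinct")
})

test_that("an isolated neuron decays exponentially from its initial potential", {
  par <- network_params(n_exc = 1L, n_inh = 0L, epsilon = 0, nu_ext = 0)
  adj <- build_adjacency(par, seed = 1)
  spk <- simulate_lif(par, adj, duration = 50, seed = 1, v0 = 15,
                      record_v = 1L)
  v <- attr(spk, "v_trace")[, 1]
  t_grid <- seq_len(length(v)) * par$dt_sim
  expect_equal(v, 15 * exp(-t_grid / 20), tolerance = 1e-12)
  expect_equal(nrow(spk), 0L)
})

test_that("an excitatory event pushes a near-threshold neuron over, with reset and clamp", {
  # neuron 1 starts above threshold and fires once; its spike (J = 0.1 mV)
  # arrives at neuron 2, sitting at 19.96 mV, after the one-step delay
  par <- network_params(n_exc = 2L, n_inh = 0L, epsilon = 0, nu_ext = 0)
  adj <- build_adjacency(par, seed = 1)
  adj$exc_sources <- matrix(c(2L, 1L), nrow = 1)  # neuron 2 listens to 1
  spk <- simulate_lif(par, adj, duration = 5, seed = 1,
                      v0 = c(25, 19.96), record_v = 2L)
  expect_equal(spk$neuron, c(1L, 2L))
  expect_equal(spk$time_ms[2] - spk$time_ms[1], par$t_delay)
  v2 <- attr(spk, "v_trace")[, 1]
  # clamped at v_reset for the full 2 ms refractory period
  i_spike <- round(spk$time_ms[2] / par$dt_sim) + 1L
  clamp <- v2[(i_spike):(i_spike + round(par$t_ref / par$dt_sim) - 1L)]
  expect_true(all(clamp == par$v_reset))
  # afterwards it decays again
  expect_lt(v2[i_spike + round(par$t_ref / par$dt_sim) + 5L], par$v_reset)
})

test_that("no inter-spike interval is shorter than the refractory period", {
  spk <- tiny_network()$spikes
  isi <- tapply(spk$time_ms, spk$neuron, function(t) diff(sort(t)))
  isi <- unlist(isi[lengths(isi) > 0])
  expect_gte(min(isi), tiny_network()$params$t_ref - 1e-9)
})

test_that("identical parameters and seed give bit-identical spike sets", {
  net <- tiny_network()
  again <- simulate_lif(net$params, net$adjacency, duration = 2000, seed = 11L)
  expect_identical(net$spikes$neuron, again$neuron)
  expect_identical(net$spikes$time_ms, again$time_ms)
})

test_that("subthreshold responses superpose linearly", {
  # two source neurons fire once each; target response to both equals the
  # sum of the responses to each alone while below threshold
  par <- network_params(n_exc = 3L, n_inh = 0L, epsilon = 0, nu_ext = 0,
                        theta = 100)
  base_adj <- build_adjacency(par, seed = 1)
  run <- function(sources) {
    k <- length(sources)
    adj <- base_adj
    # columns are targets; neurons 1-2 listen to neuron 1 (inert: it is
    # refractory when its own spike would arrive), neuron 3 to `sources`
    adj$exc_sources <- matrix(1L, nrow = k, ncol = 3)
    if (k) adj$exc_sources[, 3] <- sources
    spk <- simulate_lif(par, adj, duration = 30, seed = 1,
                        v0 = c(150, 150, 0), record_v = 3L)
    attr(spk, "v_trace")[, 1]
  }
  v_both <- run(c(1L, 2L))
  v_1 <- run(1L)
  v_2 <- run(2L)
  v_none <- run(integer(0))
  expect_equal(v_both - v_none, (v_1 - v_none) + (v_2 - v_none),
               tolerance = 1e-10)
})

test_that("production integrator matches a fine-step Euler oracle on a 3-neuron motif", {
  # chain 1 -> 2 -> 3 with strong weights so each spike triggers the next
  par <- network_params(n_exc = 3L, n_inh = 0L, epsilon = 0, nu_ext = 0,
                        j_psp = 12)
  adj <- build_adjacency(par, seed = 1)
  # columns are targets: 2 listens to 1, 3 listens to 2, 1 listens to 2
  adj$exc_sources <- matrix(c(2L, 1L, 2L), nrow = 1)
  spk <- simulate_lif(par, adj, duration = 10, seed = 1,
                      v0 = c(21, 12, 12))
  W <- matrix(0, 3, 3)
  W[1, 2] <- par$j_psp; W[2, 3] <- par$j_psp; W[2, 1] <- par$j_psp
  ref <- euler_lif_reference(par, W, duration = 10, h = 0.001,
                             v0 = c(21, 12, 12))
  expect_equal(nrow(spk), nrow(ref))
  ord <- order(spk$time_ms, spk$neuron)
  ord_r <- order(ref$time_ms, ref$neuron)
  expect_equal(spk$neuron[ord], ref$neuron[ord_r])
  expect_true(all(abs(spk$time_ms[ord] - ref$time_ms[ord_r]) <=
                    par$dt_sim + 1e-9))
})

test_that("the balanced network fires irregularly at a plausible rate", {
  net <- tiny_network()
  rate <- nrow(net$spikes) / 500 / 2  # spikes / neuron / s -> Hz over 2 s
  expect_gt(rate, 5)
  expect_lt(rate, 200)
  # excitation and inhibition both active
  expect_gt(sum(net$spikes$neuron > 400), 0)
})
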