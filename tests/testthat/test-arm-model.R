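test_that("the exponential link evaluates the printed constants correctly", {
  p <- arm_params()
  expect_equal(alpha_rate(0, 0, p), exp(-0.046), tolerance = 1e-12)
  expect_equal(alpha_rate(25, 7, p), exp(-0.046 + 0.032 * 25 - 0.152 * 7),
               tolerance = 1e-12)
  p0 <- arm_params(c1 = 0, c2 = 0)
  expect_equal(alpha_rate(13, 99, p0), exp(-0.046))
})

test_that("parameter validation enforces the step-probability bound", {
  expect_error(arm_params(beta = 8, gamma = 3, dt = 0.1), "exceeds 1")
  expect_error(arm_params(beta = -1), "positive")
})

test_that("single-step expectations match the binomial model", {
  p <- arm_params()
  set.seed(30)
  reps <- 4000
  dm <- rbinom(reps, 800, (7.78 + 0.325) * 0.1)
  expect_equal(mean(dm), 800 * 0.8105, tolerance = 0.01)
  # spike thinning: E[S] = E[dA-] * gamma / (beta + gamma)
  s <- rbinom(reps, dm, 0.325 / 8.105)
  expect_equal(mean(s), 800 * 0.8105 * 0.325 / 8.105, tolerance = 0.05)
  # empty active pool emits nothing
  st <- list(A_e = 0L, A_i = 0L, S_e = 0L, S_i = 0L)
  out <- arm_step(st, p)
  expect_equal(out$S_e, 0L)
  expect_equal(out$dA_minus_e, 0L)
})

test_that("the clipped regime transfers all refractory neurons at once", {
  # huge alpha: alpha*dt clips to 1 so the whole refractory pool re-activates
  p <- arm_params(c0 = 10, c1 = 0, c2 = 0, beta = 1, gamma = 0.5, dt = 0.5,
                  n_exc = 100L, n_inh = 25L)
  set.seed(31)
  out <- arm_step(list(A_e = 40L, A_i = 10L, S_e = 0L, S_i = 0L), p)
  expect_equal(out$A_e, 100L - out$dA_minus_e)
  expect_equal(out$A_i, 25L - out$dA_minus_i)
})

test_that("compiled simulator reproduces the R reference step for step", {
  p <- arm_params(n_exc = 500L, n_inh = 125L)
  init <- list(A_e = 50L, A_i = 12L, S_e = 2L, S_i = 0L)
  sim <- simulate_arm(p, n_steps = 200, init = init, seed = 42, burn_in = 0)
  set.seed(42)
  st <- init
  ref_e <- integer(200); ref_a <- integer(200)
  for (t in 1:200) {
    st <- arm_step(st, p)
    ref_e[t] <- st$S_e; ref_a[t] <- st$A_e
  }
  expect_identical(sim$S_e, ref_e)
  expect_identical(attr(sim, "A_e"), ref_a)
})

test_that("occupation bookkeeping conserves neurons and orders S <= dA- <= A", {
  p <- arm_params(n_exc = 800L, n_inh = 200L)
  set.seed(33)
  st <- list(A_e = 100L, A_i = 25L, S_e = 3L, S_i = 1L)
  for (t in 1:500) {
    prev <- st
    st <- arm_step(st, p)
    expect_lte(st$S_e, st$dA_minus_e)
    expect_lte(st$dA_minus_e, prev$A_e)
    expect_lte(st$S_i, st$dA_minus_i)
    expect_lte(st$dA_minus_i, prev$A_i)
    expect_true(st$A_e >= 0 && st$A_e <= 800)
    expect_true(st$A_i >= 0 && st$A_i <= 200)
  }
})

test_that("gamma = 0 in the thinning silences the model", {
  # direct thinning check: with gamma -> 0 the spike branch has zero mass
  p <- arm_params(gamma = 1e-12)
  set.seed(34)
  st <- list(A_e = 5000L, A_i = 1200L, S_e = 0L, S_i = 0L)
  for (t in 1:50) {
    st <- arm_step(st, p)
    expect_equal(st$S_e, 0L)
    expect_equal(st$S_i, 0L)
  }
})

test_that("stationary means satisfy E[S] = E[A] gamma dt and match the fixed point", {
  s <- arm_reference_run()
  p <- attr(s, "params")
  gd <- p$gamma * p$dt
  expect_equal(mean(s$S_e), mean(attr(s, "A_e")) * gd, tolerance = 0.01)
  expect_equal(mean(s$S_i), mean(attr(s, "A_i")) * gd, tolerance = 0.01)
  # the long-run mean sits near the fixed point; the exponential link makes
  # the stationary mean sit slightly above it (fluctuation correction), so
  # compare with a tolerance of a few spikes rather than 3 SE
  fp <- fixed_point(p)
  expect_equal(mean(s$S_e), unname(fp[1]), tolerance = 0.12)
  expect_equal(mean(s$S_i), unname(fp[2]), tolerance = 0.12)
})

test_that("seed determinism gives identical count series", {
  p <- arm_params(n_exc = 1000L, n_inh = 250L)
  a <- simulate_arm(p, 1000, seed = 5)
  b <- simulate_arm(p, 1000, seed = 5)
  d <- simulate_arm(p, 1000, seed = 6)
  expect_identical(a$S_e, b$S_e)
  expect_false(identical(a$S_e, d$S_e))
})

test_that("mean-field right-hand side matches hand arithmetic at the printed constants", {
  p <- arm_params()
  r0 <- meanfield_rhs(0, 0, p)
  expect_equal(unname(r0[1]), exp(-0.046) * 10000 * 0.0325, tolerance = 1e-10)
  expect_equal(unname(r0[2]), exp(-0.046) * 2500 * 0.0325, tolerance = 1e-10)
  fp <- fixed_point(p)
  expect_equal(unname(meanfield_rhs(fp[1], fp[2], p)), c(0, 0),
               tolerance = 1e-8)
})

test_that("the linear special case has its closed-form equilibrium", {
  p <- arm_params(c1 = 0, c2 = 0)
  fp <- fixed_point(p)
  s_star <- 10000 * 0.0325 * exp(-0.046) / (exp(-0.046) + 8.105)
  expect_equal(unname(fp[1]), s_star, tolerance = 1e-9)
  expect_equal(unname(fp[1] / fp[2]), 4, tolerance = 1e-9)
})

test_that("fixed point equals an independent bisection on the reduced scalar equation", {
  p <- arm_params()
  f <- function(x) exp(-0.046 - 60 * x) * (0.0325 - x) - 8.105 * x
  lo <- 0; hi <- 0.0325
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(unname(fixed_point(p)[1]), 10000 * (lo + hi) / 2,
               tolerance = 1e-6)
})

test_that("mean-field integration converges monotonically to the fixed point", {
  p <- arm_params()
  fp <- fixed_point(p)
  # starting at the fixed point stays there
  tr0 <- integrate_meanfield(unname(fp), p, duration = 5)
  expect_lt(max(abs(tr0$S_e - fp[1])), 1e-8)
  # starting at the origin approaches it monotonically
  tr <- integrate_meanfield(c(0, 0), p, duration = 10)
  expect_equal(tr$S_e[nrow(tr)], unname(fp[1]), tolerance = 1e-6)
  expect_true(all(diff(tr$S_e) > -1e-12))
  # step halving changes the endpoint by less than 1e-6 (4th order)
  tr_h <- integrate_meanfield(c(0, 0), p, duration = 10, h = p$dt / 20)
  expect_lt(abs(tr_h$S_e[nrow(tr_h)] - tr$S_e[nrow(tr)]), 1e-6)
})

test_that("size normalization rescales the link coefficients as c1*Ne, c2*Ni", {
  p <- arm_params()
  np <- normalize_params(p)
  expect_equal(np$c1_prime, 320)
  expect_equal(np$c2_prime, -380)
  p1 <- arm_params(n_exc = 1L, n_inh = 1L, c1 = 0.01, c2 = -0.01,
                   beta = 5, gamma = 0.1)
  np1 <- normalize_params(p1)
  expect_equal(np1$c1_prime, p1$c1)
  expect_equal(np1$c2_prime, p1$c2)
})

test_that("normalized mean-field trajectories are invariant across network sizes", {
  sizes <- list(c(6000L, 1500L), c(10000L, 2500L), c(16000L, 4000L))
  trajs <- lapply(sizes, function(nn) {
    # rescale raw coefficients so c1', c2' stay fixed at (320, -380)
    p <- arm_params(c1 = 320 / nn[1], c2 = -380 / nn[2],
                    n_exc = nn[1], n_inh = nn[2])
    integrate_meanfield_normalized(c(0.001, 0.004), normalize_params(p),
                                   duration = 5)
  })
  for (k in 2:3) {
    expect_equal(trajs[[k]]$X_e, trajs[[1]]$X_e, tolerance = 1e-10)
    expect_equal(trajs[[k]]$X_i, trajs[[1]]$X_i, tolerance = 1e-10)
  }
  # and the raw fixed points sit at equal normalized activity
  p <- arm_params()
  fp <- fixed_point(p)
  expect_equal(unname(fp[1]) / p$n_exc, unname(fp[2]) / p$n_inh,
               tolerance = 1e-10)
})

test_that("derivative variance scales linearly with population size given the occupancy", {
  # the binomial noise component: Var(S' | A) = A * gamma*dt * (1 - gamma*dt),
  # so at matched normalized occupancy the E/I variance ratio is N_e/N_i
  s <- arm_reference_run()
  p <- attr(s, "params")
  gd <- p$gamma * p$dt
  v_e <- mean(attr(s, "A_e")) * gd * (1 - gd)
  v_i <- mean(attr(s, "A_i")) * gd * (1 - gd)
  expect_equal(v_e / v_i, p$n_exc / p$n_inh, tolerance = 0.02)
  # and the empirical state-conditioned ratio agrees
  fl <- reconstruct_flow(s)
  expect_equal(variance_ratio(fl), 4, tolerance = 0.15)
})
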