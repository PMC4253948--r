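test_that("flow assigns forward differences to the left state", {
  # deterministic alternation 3,5,3,5,... at dt = 0.1 ms
  S_e <- rep(c(3L, 5L), 50)
  cs <- count_series(S_e, rep(2L, 100), dt = 0.1)
  fl <- reconstruct_flow(cs, min_visits = 2)
  expect_equal(fl$mean_dSe[fl$S_e == 3], 20)   # +2 counts / 0.1 ms
  expect_equal(fl$mean_dSe[fl$S_e == 5], -20)
  expect_equal(fl$var_dSe, c(0, 0))
  expect_equal(fl$mean_dSi, c(0, 0))
})

test_that("a constant series yields zero flow and zero variance", {
  cs <- count_series(rep(4L, 50), rep(1L, 50), dt = 0.1)
  fl <- reconstruct_flow(cs, min_visits = 2)
  expect_equal(nrow(fl), 1L)
  expect_equal(unlist(fl[1, c("mean_dSe", "mean_dSi", "var_dSe", "var_dSi")]),
               c(mean_dSe = 0, mean_dSi = 0, var_dSe = 0, var_dSi = 0))
})

test_that("min_visits filters sparsely visited states", {
  set.seed(20)
  cs <- count_series(rpois(2000, 5), rpois(2000, 2), dt = 0.1)
  fl <- reconstruct_flow(cs, min_visits = 30)
  expect_true(all(fl$visits >= 30))
})

test_that("stationary series has no occupancy-weighted net drift", {
  s <- arm_reference_run()
  fl <- reconstruct_flow(s)
  drift_e <- sum(fl$visits * fl$mean_dSe) / sum(fl$visits)
  # net drift is a small fraction of the typical derivative magnitude
  # (exactly zero only before the min-visits filter, by telescoping)
  scale_e <- sum(fl$visits * abs(fl$mean_dSe)) / sum(fl$visits)
  expect_lt(abs(drift_e), 0.05 * scale_e)
})

test_that("ARM per-state mean derivatives track the mean-field at well-visited states", {
  s <- arm_reference_run()
  p <- attr(s, "params")
  fl <- reconstruct_flow(s, min_visits = 2000)
  rhs <- t(vapply(seq_len(nrow(fl)),
                  function(r) meanfield_rhs(fl$S_e[r], fl$S_i[r], p),
                  numeric(2)))
  se_e <- sqrt(fl$var_dSe / fl$visits)
  # allow a small systematic attenuation on top of Monte-Carlo error: the
  # latent occupancy is only partially determined by the observed counts
  z <- abs(fl$mean_dSe - rhs[, 1]) / pmax(se_e, 1e-9)
  expect_lt(median(z), 3)
  expect_gt(cor(fl$mean_dSe, rhs[, 1]), 0.97)
  expect_gt(cor(fl$mean_dSi, rhs[, 2]), 0.9)
})

test_that("derivative distributions are normalized point masses for deterministic input", {
  S_e <- rep(c(3L, 5L), 50)
  cs <- count_series(S_e, rep(2L, 100), dt = 0.1)
  d <- derivative_distribution(cs, c(3L, 2L), "exc", min_visits = 5)
  expect_equal(sum(d$mass), 1)
  expect_equal(nrow(d), 1L)
  expect_equal(d$derivative, 20)
  expect_error(derivative_distribution(cs, c(99L, 99L), "exc"), "visited")
})

test_that("a symmetric random walk gives a symmetric derivative distribution", {
  set.seed(21)
  n <- 60000
  step <- ifelse(rbinom(n, 1, 0.5) == 1L, 1L, -1L)
  x <- integer(n)
  x[1] <- 20L
  for (t in 2:n) {  # reflected at 15 and 25 so the center is visited often
    x[t] <- x[t - 1] + step[t]
    if (x[t] > 25L) x[t] <- 24L
    if (x[t] < 15L) x[t] <- 16L
  }
  cs <- count_series(x, rep(1L, n), dt = 1)
  d <- derivative_distribution(cs, c(20L, 1L), "exc", min_visits = 50)
  m1 <- sum(d$derivative * d$mass)
  expect_lt(abs(m1), 0.1)
  expect_setequal(round(d$derivative), c(-1, 1))
})

test_that("distribution overlap is min-mass arithmetic, symmetric, and bounded", {
  mk <- function(v, m) data.frame(derivative = v, mass = m)
  p <- mk(c(0, 1), c(0.5, 0.5))
  q <- mk(c(1, 2), c(0.5, 0.5))
  expect_equal(distribution_overlap(p, q), 0.5)
  expect_equal(distribution_overlap(q, p), 0.5)
  expect_equal(distribution_overlap(p, p), 1)
  expect_equal(distribution_overlap(p, mk(c(5, 6), c(0.5, 0.5))), 0)
  expect_error(distribution_overlap(p, mk(1, 0.7)), "normalized")
})

test_that("isoclines of an analytic mean-field surface match the root locus", {
  p <- arm_params()
  grid <- expand.grid(S_e = 0:60, S_i = 0:20)
  rhs <- t(vapply(seq_len(nrow(grid)),
                  function(r) meanfield_rhs(grid$S_e[r], grid$S_i[r], p),
                  numeric(2)))
  fl <- structure(data.frame(S_e = grid$S_e, S_i = grid$S_i,
                             visits = 100L, mean_dSe = rhs[, 1],
                             mean_dSi = rhs[, 2], var_dSe = 1, var_dSi = 1),
                  dt = 0.1, min_visits = 100L,
                  class = c("flow_field", "data.frame"))
  iso <- extract_isoclines(fl, "exc", levels = 0, smooth = FALSE)
  expect_gt(length(iso), 0)
  pts <- do.call(rbind, iso)
  # every contour vertex must satisfy the implicit equation within one cell
  resid <- vapply(seq_len(nrow(pts)),
                  function(r) meanfield_rhs(pts$S_e[r], pts$S_i[r], p)[1],
                  numeric(1))
  # local slope of the surface ~ hundreds per count unit; one-cell tolerance
  expect_lt(max(abs(resid)), 400)
  # the fixed point lies on the nullcline
  fp <- fixed_point(p)
  d_min <- min(sqrt((pts$S_e - fp[1])^2 + (pts$S_i - fp[2])^2))
  expect_lt(d_min, 1.5)
})

test_that("constant surfaces give full-range or empty isoclines", {
  fl <- structure(data.frame(S_e = rep(0:10, each = 11), S_i = rep(0:10, 11),
                             visits = 50L, mean_dSe = 5, mean_dSi = 0,
                             var_dSe = 1, var_dSi = 1),
                  dt = 0.1, min_visits = 50L,
                  class = c("flow_field", "data.frame"))
  expect_length(suppressWarnings(
    extract_isoclines(fl, "exc", levels = 99, smooth = FALSE)), 0)
})

test_that("variance ratio is exact on constructed variance maps", {
  fl <- structure(data.frame(S_e = 1:20, S_i = rep(1:4, 5), visits = 10L,
                             mean_dSe = 0, mean_dSi = 0,
                             var_dSe = 4 * (1:20), var_dSi = 1 * (1:20)),
                  dt = 0.1, min_visits = 10L,
                  class = c("flow_field", "data.frame"))
  expect_equal(variance_ratio(fl), 4)
  fl$var_dSe <- fl$var_dSi
  expect_equal(variance_ratio(fl), 1)
})
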