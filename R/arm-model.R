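#' Parameters of the Active-Refractory Markov (ARM) population model
#'
#' In the ARM model every neuron is in one of two states: active (membrane
#' potential close to threshold) or refractory (far from threshold). Three
#' rates govern the transitions: \eqn{\alpha} from refractory to active,
#' \eqn{\beta} from active to refractory without a spike (leak), and
#' \eqn{\gamma} from active to refractory through spike emission.
#' \eqn{\alpha} depends exponentially on the most recent joint spike counts,
#' \eqn{\alpha = \exp(c_0 + c_1 S_e + c_2 S_i)}, shared by both populations;
#' \eqn{\beta} and \eqn{\gamma} are constants. The defaults are the rates
#' estimated from a full-size balanced network simulation:
#' \eqn{c_0 = -0.046}, \eqn{c_1 = 0.032}, \eqn{c_2 = -0.152},
#' \eqn{\beta = 7.78} and \eqn{\gamma = 0.325} per ms, at a bin width of
#' 0.1 ms and population sizes 10000/2500.
#'
#' @param c0 log-rate offset of the exponential link (log ms^-1 scale).
#' @param c1 link coefficient per excitatory spike count.
#' @param c2 link coefficient per inhibitory spike count (negative:
#'   inhibition suppresses re-activation).
#' @param beta active-to-refractory leak rate (ms^-1).
#' @param gamma active-to-refractory spiking rate (ms^-1).
#' @param dt time step (ms); `(beta + gamma) * dt` must not exceed 1.
#' @param n_exc,n_inh population sizes.
#' @return An object of class `arm_params`.
#' @export
arm_params <- function(c0 = -0.046, c1 = 0.032, c2 = -0.152,
                       beta = 7.78, gamma = 0.325, dt = 0.1,
                       n_exc = 10000L, n_inh = 2500L) {
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be positive")
  if (dt <= 0) stop("dt must be positive")
  if ((beta + gamma) * dt > 1)
    stop("(beta + gamma) * dt exceeds 1; reduce dt")
  structure(list(c0 = c0, c1 = c1, c2 = c2, beta = beta, gamma = gamma,
                 dt = dt, n_exc = as.integer(n_exc), n_inh = as.integer(n_inh)),
            class = "arm_params")
}

#' @export
print.arm_params <- function(x, ...) {
  cat("ARM model parameters\n")
  cat(sprintf("  link: alpha = exp(%+.4g %+.4g * S_e %+.4g * S_i)  [ms^-1]\n",
              x$c0, x$c1, x$c2))
  cat(sprintf("  rates: beta = %.4g, gamma = %.4g ms^-1; dt = %g ms\n",
              x$beta, x$gamma, x$dt))
  cat(sprintf("  populations: N_e = %d, N_i = %d\n", x$n_exc, x$n_inh))
  invisible(x)
}

#' Refractory-to-active transition rate
#'
#' Evaluates the exponential link \eqn{\alpha = \exp(c_0 + c_1 S_e + c_2
#' S_i)} (ms^-1). As a per-step probability, \eqn{\alpha\,dt} is clipped to
#' \[0, 1\] by the simulator since the exponential is unbounded.
#'
#' @param s_e,s_i spike counts of the current bin.
#' @param params an [arm_params()] object.
#' @return Rate in ms^-1.
#' @export
alpha_rate <- function(s_e, s_i, params) {
  exp(params$c0 + params$c1 * s_e + params$c2 * s_i)
}

#' One stochastic ARM step (reference implementation)
#'
#' Advances the joint state by one bin. For each population independently:
#' the outflow \eqn{\Delta A^-} is Binomial\eqn{(A, (\beta+\gamma)dt)}; the
#' spike count is a Binomial\eqn{(\Delta A^-, \gamma/(\gamma+\beta))}
#' thinning of the outflow; the inflow \eqn{\Delta A^+} is
#' Binomial\eqn{(N - A, \alpha\,dt)} with \eqn{\alpha} evaluated from the
#' spike counts of the current step — those just drawn — and shared by both
#' populations. Evaluating \eqn{\alpha} on the current step's counts is what
#' couples the inflow to the instantaneous state, closing the feedback loop
#' of the mean-field equations. Draw order (excitatory outflow and spikes,
#' inhibitory outflow and spikes, then both inflows) matches the compiled
#' simulator, so iterating this function under the same seed reproduces
#' [simulate_arm()] exactly.
#'
#' @param state list with `A_e`, `A_i` (active-pool sizes) and `S_e`, `S_i`
#'   (current spike counts).
#' @param params an [arm_params()] object.
#' @return Updated state list.
#' @export
arm_step <- function(state, params) {
  p_out <- (params$beta + params$gamma) * params$dt
  p_spk <- params$gamma / (params$gamma + params$beta)
  dme <- stats::rbinom(1L, state$A_e, p_out)
  se <- stats::rbinom(1L, dme, p_spk)
  dmi <- stats::rbinom(1L, state$A_i, p_out)
  si <- stats::rbinom(1L, dmi, p_spk)
  p_in <- min(1, alpha_rate(se, si, params) * params$dt)
  dpe <- stats::rbinom(1L, params$n_exc - state$A_e, p_in)
  dpi <- stats::rbinom(1L, params$n_inh - state$A_i, p_in)
  list(A_e = state$A_e - dme + dpe, A_i = state$A_i - dmi + dpi,
       S_e = se, S_i = si,
       dA_minus_e = dme, dA_minus_i = dmi)
}

#' Simulate the stochastic ARM model
#'
#' Iterates the binomial two-pool dynamics for `n_steps` bins. By default the
#' run starts from the fixed-point occupancy \eqn{A^* = S^*/(\gamma dt)} and
#' the first `burn_in` steps are discarded, so the returned series is
#' stationary.
#'
#' @param params an [arm_params()] object.
#' @param n_steps number of retained steps.
#' @param init optional state list as in [arm_step()]; defaults to the
#'   mean-field fixed point.
#' @param seed integer seed (seed-deterministic output).
#' @param burn_in discarded initial steps (default 10000).
#' @return A [count_series()] with bin width `params$dt`; the latent
#'   active-pool traces are attached as attributes `A_e` and `A_i`.
#' @export
simulate_arm <- function(params, n_steps, init = NULL, seed = 1L,
                         burn_in = 10000L) {
  stopifnot(inherits(params, "arm_params"))
  if (n_steps < 1) stop("n_steps must be at least 1")
  if (is.null(init)) {
    fp <- fixed_point(params)
    a_e <- as.integer(round(fp[1] / (params$gamma * params$dt)))
    a_i <- as.integer(round(fp[2] / (params$gamma * params$dt)))
    init <- list(A_e = min(a_e, params$n_exc), A_i = min(a_i, params$n_inh),
                 S_e = as.integer(round(fp[1])), S_i = as.integer(round(fp[2])))
  }
  set.seed(seed)
  res <- arm_simulate_cpp(params$c0, params$c1, params$c2, params$beta,
                          params$gamma, params$dt, params$n_exc, params$n_inh,
                          as.integer(n_steps + burn_in),
                          init$A_e, init$A_i, init$S_e, init$S_i)
  keep <- (burn_in + 1L):(burn_in + n_steps)
  out <- count_series(res$S_e[keep], res$S_i[keep], params$dt)
  attr(out, "A_e") <- res$A_e[keep]
  attr(out, "A_i") <- res$A_i[keep]
  attr(out, "params") <- params
  out
}

#' Mean-field right-hand side of the ARM model
#'
#' The deterministic two-dimensional dynamics of the expected spike counts:
#' \deqn{\dot S = \exp(c_0 + c_1 S_e + c_2 S_i)\,(N \gamma dt - S) -
#'   (\beta + \gamma) S}
#' for each population with its own size \eqn{N}, sharing the same rates.
#'
#' @param s_e,s_i spike counts (continuum-valued).
#' @param params an [arm_params()] object.
#' @return Numeric pair `c(dS_e, dS_i)` in spikes/ms.
#' @export
meanfield_rhs <- function(s_e, s_i, params) {
  a <- alpha_rate(s_e, s_i, params)
  bg <- params$beta + params$gamma
  gd <- params$gamma * params$dt
  c(dS_e = a * (params$n_exc * gd - s_e) - bg * s_e,
    dS_i = a * (params$n_inh * gd - s_i) - bg * s_i)
}

#' Integrate the mean-field equations
#'
#' Classical fixed-step fourth-order Runge-Kutta integration of
#' [meanfield_rhs()] at step `dt/10`.
#'
#' @param init numeric pair `c(s_e, s_i)`.
#' @param params an [arm_params()] object.
#' @param duration integration time (ms).
#' @param h integration step (ms); defaults to `params$dt / 10`.
#' @return Data frame with columns `time_ms`, `S_e`, `S_i`.
#' @export
integrate_meanfield <- function(init, params, duration, h = params$dt / 10) {
  stopifnot(inherits(params, "arm_params"))
  if (duration <= 0) stop("duration must be positive")
  rhs <- function(t, y, p) list(meanfield_rhs(y[1], y[2], params))
  times <- seq(0, duration, by = h)
  sol <- deSolve::rk4(c(S_e = init[1], S_i = init[2]), times, rhs, NULL)
  if (any(!is.finite(sol[, 2:3]))) stop("mean-field integration diverged")
  out <- as.data.frame(sol)
  names(out) <- c("time_ms", "S_e", "S_i")
  out
}

#' Fixed point of the mean-field dynamics
#'
#' Since the two populations share identical transition rates, the fixed
#' point has equal normalized activity \eqn{X = S_e/N_e = S_i/N_i} and solves
#' the scalar equation
#' \eqn{\exp(c_0 + (c_1 N_e + c_2 N_i) X)(\gamma dt - X) = (\beta+\gamma) X}
#' on \eqn{(0, \gamma dt)}, found by bisection.
#'
#' @param params an [arm_params()] object.
#' @param tol convergence tolerance on `X`.
#' @return Numeric pair `c(s_e, s_i)` at which [meanfield_rhs()] vanishes.
#' @export
fixed_point <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "arm_params"))
  cp <- params$c1 * params$n_exc + params$c2 * params$n_inh
  gd <- params$gamma * params$dt
  bg <- params$beta + params$gamma
  f <- function(x) exp(params$c0 + cp * x) * (gd - x) - bg * x
  root <- stats::uniroot(f, c(0, gd), tol = tol)
  x <- root$root
  c(s_e = x * params$n_exc, s_i = x * params$n_inh)
}

#' Size-normalized ARM parameters
#'
#' Rescaling the counts by the population sizes, \eqn{X_e = S_e/N_e} and
#' \eqn{X_i = S_i/N_i}, turns the mean-field equations into a form that does
#' not depend on the network size:
#' \deqn{\dot X = \exp(c_0 + c_1' X_e + c_2' X_i)(\gamma dt - X) -
#'   (\beta+\gamma) X}
#' with \eqn{c_1' = c_1 N_e} and \eqn{c_2' = c_2 N_i}. Networks of different
#' size whose raw coefficients rescale to the same \eqn{c_1', c_2'} share
#' identical normalized trajectories (universality).
#'
#' @param params an [arm_params()] object.
#' @return An object of class `arm_params_normalized`: list with `c0`,
#'   `c1_prime`, `c2_prime`, `beta`, `gamma`, `dt`.
#' @export
normalize_params <- function(params) {
  stopifnot(inherits(params, "arm_params"))
  if (params$n_exc <= 0 || params$n_inh <= 0)
    stop("population sizes must be positive")
  structure(list(c0 = params$c0,
                 c1_prime = params$c1 * params$n_exc,
                 c2_prime = params$c2 * params$n_inh,
                 beta = params$beta, gamma = params$gamma, dt = params$dt),
            class = "arm_params_normalized")
}

#' @export
print.arm_params_normalized <- function(x, ...) {
  cat(sprintf("Normalized ARM parameters: c0 = %.4g, c1' = %.4g, c2' = %.4g, beta = %.4g, gamma = %.4g (dt = %g ms)\n",
              x$c0, x$c1_prime, x$c2_prime, x$beta, x$gamma, x$dt))
  invisible(x)
}

#' Integrate the size-normalized mean-field equations
#'
#' @param init numeric pair `c(x_e, x_i)` of normalized activities in
#'   \[0, 1\].
#' @param nparams a [normalize_params()] result.
#' @param duration integration time (ms).
#' @param h integration step (ms).
#' @return Data frame with columns `time_ms`, `X_e`, `X_i`.
#' @export
integrate_meanfield_normalized <- function(init, nparams, duration,
                                           h = nparams$dt / 10) {
  stopifnot(inherits(nparams, "arm_params_normalized"))
  gd <- nparams$gamma * nparams$dt
  bg <- nparams$beta + nparams$gamma
  rhs <- function(t, y, p) {
    a <- exp(nparams$c0 + nparams$c1_prime * y[1] + nparams$c2_prime * y[2])
    list(c(a * (gd - y[1]) - bg * y[1], a * (gd - y[2]) - bg * y[2]))
  }
  sol <- deSolve::rk4(c(X_e = init[1], X_i = init[2]),
                      seq(0, duration, by = h), rhs, NULL)
  out <- as.data.frame(sol)
  names(out) <- c("time_ms", "X_e", "X_i")
  out
}
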