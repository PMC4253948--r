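#' Drift and diffusion moments of the synaptic input
#'
#' For a LIF neuron bombarded by independent Poisson sources with rates
#' \eqn{r_k} (spikes/ms) and PSP amplitudes \eqn{J_k} (mV), the diffusion
#' approximation has drift \eqn{\mu = \tau \sum_k r_k J_k} and diffusion
#' \eqn{\sigma^2 = \tau \sum_k r_k J_k^2}.
#'
#' @param rates numeric vector of source rates (spikes/ms).
#' @param weights numeric vector of PSP amplitudes (mV), aligned with
#'   `rates`.
#' @param tau membrane time constant (ms).
#' @return An object of class `diffusion_moments`: list with `mu` (mV) and
#'   `sigma` (mV).
#' @export
input_moments <- function(rates, weights, tau) {
  if (!length(rates)) stop("empty input list")
  if (length(rates) != length(weights))
    stop("rates and weights must be aligned")
  if (tau <= 0) stop("tau must be positive")
  mu <- tau * sum(rates * weights)
  s2 <- tau * sum(rates * weights^2)
  if (s2 <= 0) stop("degenerate input: zero diffusion moment")
  structure(list(mu = mu, sigma = sqrt(s2), tau = tau),
            class = "diffusion_moments")
}

#' @export
print.diffusion_moments <- function(x, ...) {
  cat(sprintf("Diffusion moments: mu = %.4g mV, sigma = %.4g mV (tau = %g ms)\n",
              x$mu, x$sigma, x$tau))
  invisible(x)
}

#' Stationary membrane-potential density of the LIF neuron
#'
#' The stationary solution of the Fokker-Planck equation with absorbing
#' boundary at the threshold \eqn{\theta}, re-insertion at the reset, and
#' refractoriness excluded:
#' \deqn{p(v) \propto \frac{1}{\sigma} e^{-(v-\mu)^2/\sigma^2}
#'   \int_{\max(v, v_{reset})}^{\theta} e^{(x-\mu)^2/\sigma^2}\,dx .}
#' Below the reset this is a Gaussian branch times a constant (the integral
#' from \eqn{v_{reset}} to \eqn{\theta}); between reset and threshold the
#' integral shrinks, forcing \eqn{p(\theta) = 0}. The two branches are
#' continuous at the reset by construction and the overall constant is fixed
#' by unit mass (trapezoid quadrature on the grid).
#'
#' @param moments an [input_moments()] result.
#' @param theta spike threshold (mV).
#' @param v_reset reset potential (mV).
#' @param v_min lower edge of the voltage grid (mV); default
#'   `mu - 8 * sigma`.
#' @param n_grid number of grid points (default 2000).
#' @return An object of class `potential_density`: data frame with columns
#'   `v_mV`, `p` (1/mV) and `cdf`.
#' @export
stationary_density <- function(moments, theta, v_reset,
                               v_min = NULL, n_grid = 2000L) {
  stopifnot(inherits(moments, "diffusion_moments"))
  if (theta <= v_reset) stop("theta must exceed v_reset")
  mu <- moments$mu; sig <- moments$sigma
  if (is.null(v_min)) v_min <- mu - 8 * sig
  v_min <- min(v_min, v_reset - 4 * sig)
  v <- seq(v_min, theta, length.out = n_grid)
  # inner integral I(v) = int_{max(v, vr)}^{theta} exp((x-mu)^2/sigma^2) dx,
  # evaluated stably as exp(-(v-mu)^2/sigma^2) * I(v) via scaled erfi terms
  u <- (v - mu) / sig
  u_r <- (v_reset - mu) / sig
  u_th <- (theta - mu) / sig
  lo <- pmax(u, u_r)
  p_raw <- vapply(seq_along(v), function(k) {
    f <- function(x) exp(x^2 - u[k]^2)   # exp((x-mu)^2/s^2 - (v-mu)^2/s^2)
    sig * stats::integrate(f, lo[k], u_th, rel.tol = 1e-10)$value
  }, numeric(1))
  p_raw[p_raw < 0] <- 0
  dv <- diff(v)
  mass <- sum((p_raw[-1] + p_raw[-length(p_raw)]) / 2 * dv)
  p <- p_raw / mass
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * dv))
  # check the grid captured the support
  if (p[1] * (v[2] - v[1]) > 1e-3)
    stop("grid too narrow: appreciable mass below v_min")
  structure(data.frame(v_mV = v, p = p, cdf = cdf / cdf[length(cdf)]),
            mu = mu, sigma = sig, theta = theta, v_reset = v_reset,
            class = c("potential_density", "data.frame"))
}

#' @export
print.potential_density <- function(x, ...) {
  cat(sprintf("Stationary membrane-potential density on [%.3g, %.3g] mV (%d points)\n",
              min(x$v_mV), max(x$v_mV), nrow(x)))
  cat(sprintf("  mu = %.4g mV, sigma = %.4g mV, reset = %g mV, theta = %g mV\n",
              attr(x, "mu"), attr(x, "sigma"), attr(x, "v_reset"),
              attr(x, "theta")))
  invisible(x)
}

#' @export
plot.potential_density <- function(x, y = NULL, ...) {
  graphics::plot(x$v_mV, x$p, type = "l", xlab = "membrane potential (mV)",
                 ylab = "density (1/mV)", ...)
  graphics::abline(v = c(attr(x, "v_reset"), attr(x, "theta")),
                   lty = 2, col = "grey")
  invisible(x)
}

#' Exponential approximation of the potential CDF
#'
#' Least-squares fit of \eqn{\log F(v)} as a linear function of \eqn{v} over
#' a window \eqn{[v_{lo}, v_{hi}]} between reset and threshold. The quality
#' of this local exponential approximation of the cumulative distribution is
#' what motivates the exponential refractory-to-active link of the ARM model;
#' the fit degrades (sub-exponential behavior) as the window approaches the
#' threshold.
#'
#' @param density a [stationary_density()] result.
#' @param v_lo,v_hi fit window (mV), with
#'   \eqn{v_{reset} \le v_{lo} < v_{hi} < \theta}.
#' @return List with `slope` (1/mV), `offset` (log scale) and `max_rel_err`,
#'   the worst in-window relative deviation of the fitted exponential from
#'   the CDF.
#' @export
exponential_cdf_fit <- function(density, v_lo, v_hi) {
  stopifnot(inherits(density, "potential_density"))
  if (v_lo < attr(density, "v_reset") - 1e-9 ||
      v_hi >= attr(density, "theta") || v_lo >= v_hi)
    stop("fit window must satisfy v_reset <= v_lo < v_hi < theta")
  win <- density$v_mV >= v_lo & density$v_mV <= v_hi
  v <- density$v_mV[win]
  F <- density$cdf[win]
  if (any(F <= 0)) stop("CDF nonpositive inside the window")
  cf <- stats::lm.fit(cbind(1, v), log(F))$coefficients
  fit <- exp(cf[1] + cf[2] * v)
  list(slope = unname(cf[2]), offset = unname(cf[1]),
       max_rel_err = max(abs(fit - F) / F))
}
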