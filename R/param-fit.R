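#' Fit ARM transition rates to a reconstructed flow
#'
#' Estimates the five ARM parameters \eqn{(c_0, c_1, c_2, \beta, \gamma)} by
#' nonlinear least squares against the reconstructed mean derivatives: both
#' components of the mean-field equations share one parameter vector, and the
#' residuals of every state are weighted by its visit count (occupancy).
#' The optimization is two-staged: a coarse profile over \eqn{(\beta,
#' \gamma)} — for fixed rates, pointwise \eqn{\alpha} estimates give the link
#' coefficients by weighted log-linear regression — selects a starting point,
#' which Levenberg-Marquardt then refines jointly over all five parameters.
#'
#' @param flow a [reconstruct_flow()] result (needs at least 10 states).
#' @param n_exc,n_inh population sizes of the network that generated the
#'   counts.
#' @param dt bin width (ms) of the underlying series; defaults to the flow's.
#' @param weighting `"occupancy"` (default) weights each state's residuals by
#'   its visit count; `"none"` treats states equally.
#' @param beta_grid,gamma_grid coarse profile grids (ms^-1) for the
#'   multi-start stage.
#' @return An object of class `arm_fit`: list with elements `params` (an
#'   [arm_params()] object), `coefficients`, `std_errors`, `rss`,
#'   `converged`, `flow`, plus `fitted` and `residuals` matrices (columns
#'   `dS_e`, `dS_i`).
#' @seealso [pointwise_rates()], [fit_exponential_link()]
#' @export
fit_arm_global <- function(flow, n_exc, n_inh, dt = attr(flow, "dt"),
                           weighting = c("occupancy", "none"),
                           beta_grid = c(2, 5, 8, 12, 20),
                           gamma_grid = c(0.1, 0.2, 0.325, 0.5, 1)) {
  stopifnot(inherits(flow, "flow_field"))
  weighting <- match.arg(weighting)
  ok <- is.finite(flow$mean_dSe) & is.finite(flow$mean_dSi)
  flow <- flow[ok, ]
  if (nrow(flow) < 10) stop("need at least 10 states with finite derivatives")
  w <- if (weighting == "occupancy") flow$visits else rep(1, nrow(flow))
  sw <- sqrt(w)
  i <- flow$S_e; j <- flow$S_i
  de <- flow$mean_dSe; di <- flow$mean_dSi

  model_resid <- function(th) {
    # th = (c0, c1, c2, log beta, log gamma)
    beta <- exp(th[4]); gamma <- exp(th[5])
    a <- exp(th[1] + th[2] * i + th[3] * j)
    bg <- beta + gamma
    gd <- gamma * dt
    c(sw * (de - (a * (n_exc * gd - i) - bg * i)),
      sw * (di - (a * (n_inh * gd - j) - bg * j)))
  }

  # stage 1: profile the rates on a coarse grid; given (beta, gamma) the
  # pointwise alpha implied by the excitatory component is regressed
  # log-linearly on the counts
  best <- NULL
  for (beta in beta_grid) for (gamma in gamma_grid) {
    bg <- beta + gamma
    gd <- gamma * dt
    den_e <- n_exc * gd - i
    a_hat <- (de + bg * i) / den_e
    use <- is.finite(a_hat) & a_hat > 0 & abs(den_e) > 1e-8
    if (sum(use) < 5) next
    cf <- tryCatch(stats::lm.wfit(cbind(1, i[use], j[use]),
                                  log(a_hat[use]), w[use])$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    th <- c(cf, log(beta), log(gamma))
    rss <- sum(model_resid(th)^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss))
      best <- list(th = th, rss = rss)
  }
  if (is.null(best)) stop("no admissible starting point found")

  # stage 2: Levenberg-Marquardt refinement of all five parameters
  fit <- minpack.lm::nls.lm(par = best$th, fn = model_resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  th <- unname(fit$par)
  est <- c(c0 = th[1], c1 = th[2], c2 = th[3],
           beta = exp(th[4]), gamma = exp(th[5]))
  res <- model_resid(th)
  rss <- sum(res^2)
  dof <- max(length(res) - 5L, 1L)
  # delta-method standard errors on the natural scale
  se <- rep(NA_real_, 5)
  cv <- tryCatch(chol2inv(chol(fit$hessian)) * rss / dof,
                 error = function(e) NULL)
  if (!is.null(cv)) {
    se <- sqrt(pmax(diag(cv), 0))
    se[4] <- se[4] * est["beta"]
    se[5] <- se[5] * est["gamma"]
  }
  names(se) <- names(est)

  pars <- arm_params(c0 = unname(est["c0"]), c1 = unname(est["c1"]),
                     c2 = unname(est["c2"]), beta = unname(est["beta"]),
                     gamma = min(unname(est["gamma"]),
                                 (1 / dt) - unname(est["beta"])),
                     dt = dt, n_exc = n_exc, n_inh = n_inh)
  pred <- t(vapply(seq_len(nrow(flow)),
                   function(r) meanfield_rhs(i[r], j[r], pars),
                   numeric(2)))
  colnames(pred) <- c("dS_e", "dS_i")
  resid <- cbind(dS_e = de, dS_i = di) - pred
  structure(list(params = pars, coefficients = est, std_errors = se,
                 rss = rss, converged = fit$info %in% 1:4,
                 weighting = weighting, flow = flow,
                 fitted = pred, residuals = resid,
                 n_states = nrow(flow), dof = dof),
            class = "arm_fit")
}

#' @export
print.arm_fit <- function(x, ...) {
  cat("ARM mean-field fit (occupancy-weighted nonlinear least squares)\n")
  cat(sprintf("  %d states, RSS = %.4g, converged: %s\n",
              x$n_states, x$rss, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.arm_fit <- function(object, ...) {
  z <- object$coefficients / object$std_errors
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$std_errors,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, rss = object$rss,
              n_states = object$n_states, converged = object$converged)
  class(out) <- "summary.arm_fit"
  out
}

#' @export
print.summary.arm_fit <- function(x, ...) {
  cat("ARM mean-field fit\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nResidual sum of squares: %.4g over %d states (converged: %s)\n",
              x$rss, x$n_states, x$converged))
  invisible(x)
}

#' @export
coef.arm_fit <- function(object, ...) object$coefficients

#' @export
fitted.arm_fit <- function(object, ...) object$fitted

#' @export
residuals.arm_fit <- function(object, ...) object$residuals

#' Predict mean derivatives at new states
#'
#' @param object an `arm_fit`.
#' @param newdata data frame with columns `S_e`, `S_i`; defaults to the
#'   fitted states.
#' @param ... unused.
#' @return Matrix with columns `dS_e`, `dS_i` (spikes/ms).
#' @export
predict.arm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  pred <- t(vapply(seq_len(nrow(newdata)), function(r)
    meanfield_rhs(newdata$S_e[r], newdata$S_i[r], object$params), numeric(2)))
  colnames(pred) <- c("dS_e", "dS_i")
  pred
}

#' Simulate from a fitted ARM model
#'
#' @param object an `arm_fit`.
#' @param nsim number of steps to simulate.
#' @param seed integer seed.
#' @param ... passed to [simulate_arm()].
#' @return A [count_series()].
#' @export
simulate.arm_fit <- function(object, nsim = 100000L, seed = 1L, ...) {
  simulate_arm(object$params, n_steps = nsim, seed = seed, ...)
}

#' @export
plot.arm_fit <- function(x, y = NULL, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$flow$mean_dSe, x$fitted[, "dS_e"],
                 xlab = "observed dS_e/dt", ylab = "fitted", main = "excitatory", ...)
  graphics::abline(0, 1, col = "grey")
  graphics::plot(x$flow$mean_dSi, x$fitted[, "dS_i"],
                 xlab = "observed dS_i/dt", ylab = "fitted", main = "inhibitory", ...)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' Pointwise transition-rate estimates per state
#'
#' Given \eqn{\gamma} (from a global fit), each state \eqn{(i, j)} yields a
#' 2x2 linear system for \eqn{(\alpha, k)} with \eqn{k = \beta + \gamma}:
#' \deqn{\dot S_e = \alpha (N_e \gamma dt - i) - k i, \quad
#'       \dot S_i = \alpha (N_i \gamma dt - j) - k j.}
#' States whose system is ill-conditioned (condition number above `max_kappa`)
#' are skipped.
#'
#' @param flow a [reconstruct_flow()] result.
#' @param gamma spiking transition rate (ms^-1).
#' @param n_exc,n_inh population sizes.
#' @param dt bin width (ms).
#' @param max_kappa condition-number cutoff (default 1e8).
#' @return An object of class `pointwise_rates`: data frame with columns
#'   `S_e`, `S_i`, `visits`, `alpha`, `beta_plus_gamma`.
#' @export
pointwise_rates <- function(flow, gamma, n_exc, n_inh,
                            dt = attr(flow, "dt"), max_kappa = 1e8) {
  stopifnot(inherits(flow, "flow_field"))
  if (gamma <= 0) stop("gamma must be positive")
  gd <- gamma * dt
  res <- lapply(seq_len(nrow(flow)), function(r) {
    i <- flow$S_e[r]; j <- flow$S_i[r]
    A <- rbind(c(n_exc * gd - i, -i),
               c(n_inh * gd - j, -j))
    if (!all(is.finite(A)) || kappa(A, exact = TRUE) > max_kappa) return(NULL)
    sol <- solve(A, c(flow$mean_dSe[r], flow$mean_dSi[r]))
    data.frame(S_e = i, S_i = j, visits = flow$visits[r],
               alpha = sol[1], beta_plus_gamma = sol[2])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("all states are singular")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "gamma") <- gamma
  attr(out, "dt") <- dt
  class(out) <- c("pointwise_rates", "data.frame")
  out
}

#' @export
print.pointwise_rates <- function(x, ...) {
  cat(sprintf("Pointwise rate estimates at %d states; median alpha = %.4g, median beta+gamma = %.4g ms^-1\n",
              nrow(x), stats::median(x$alpha), stats::median(x$beta_plus_gamma)))
  invisible(x)
}

#' Fit the exponential link to pointwise rates
#'
#' Occupancy-weighted linear regression of \eqn{\log \alpha} on the state
#' counts, recovering the link coefficients \eqn{(c_0, c_1, c_2)}.
#'
#' @param rates a [pointwise_rates()] result.
#' @return Named numeric vector `c(c0, c1, c2)`.
#' @export
fit_exponential_link <- function(rates) {
  stopifnot(inherits(rates, "pointwise_rates"))
  use <- rates$alpha > 0 & is.finite(rates$alpha)
  r <- rates[use, ]
  if (nrow(r) < 3) stop("need at least 3 states with positive alpha")
  X <- cbind(1, r$S_e, r$S_i)
  if (qr(X)$rank < 3) stop("collinear design: states do not span the plane")
  cf <- stats::lm.wfit(X, log(r$alpha), r$visits)$coefficients
  stats::setNames(as.numeric(cf), c("c0", "c1", "c2"))
}
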