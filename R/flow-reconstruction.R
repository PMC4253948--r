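#' Reconstruct the state-space flow from a count series
#'
#' Treats each joint spike-count pair \eqn{(S_e, S_i)} as a state and assigns
#' to it the forward-difference derivative
#' \eqn{(S(t+dt) - S(t))/dt} observed whenever that state is visited. Per
#' state the function records the number of visits, the mean derivative of
#' each component (the reconstructed vector field) and the unbiased variance
#' of each component (the state-dependent, self-generated noise).
#'
#' @param series a [count_series()].
#' @param min_visits drop states visited fewer than this many times
#'   (default 20; below that the variance estimates are unusable).
#' @return An object of class `flow_field`: data frame with columns `S_e`,
#'   `S_i`, `visits`, `mean_dSe`, `mean_dSi`, `var_dSe`, `var_dSi`, attribute
#'   `dt`. Derivatives are in spikes/ms (change per bin divided by `dt`).
#' @export
reconstruct_flow <- function(series, min_visits = 20L) {
  stopifnot(inherits(series, "count_series"))
  n <- nrow(series)
  if (n < 2) stop("series must have at least two bins")
  dt <- attr(series, "dt")
  i <- series$S_e[-n]; j <- series$S_i[-n]
  de <- diff(series$S_e) / dt
  di <- diff(series$S_i) / dt
  m <- max(j) + 1L
  key <- i * m + j
  o <- order(key)
  key <- key[o]; de <- de[o]; di <- di[o]
  grp <- cumsum(c(TRUE, diff(key) != 0))
  visits <- tabulate(grp)
  sum_e <- rowsum(de, grp, reorder = FALSE)[, 1]
  sum_i <- rowsum(di, grp, reorder = FALSE)[, 1]
  sq_e <- rowsum(de^2, grp, reorder = FALSE)[, 1]
  sq_i <- rowsum(di^2, grp, reorder = FALSE)[, 1]
  ukey <- key[!duplicated(key)]
  mean_e <- sum_e / visits
  mean_i <- sum_i / visits
  var_e <- ifelse(visits > 1, (sq_e - visits * mean_e^2) / (visits - 1), 0)
  var_i <- ifelse(visits > 1, (sq_i - visits * mean_i^2) / (visits - 1), 0)
  keep <- visits >= min_visits
  out <- data.frame(S_e = as.integer(ukey %/% m), S_i = as.integer(ukey %% m),
                    visits = visits, mean_dSe = mean_e, mean_dSi = mean_i,
                    var_dSe = pmax(var_e, 0), var_dSi = pmax(var_i, 0))[keep, ]
  rownames(out) <- NULL
  attr(out, "dt") <- dt
  attr(out, "min_visits") <- min_visits
  class(out) <- c("flow_field", "data.frame")
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Reconstructed flow: %d states (>= %d visits), dt = %g ms\n",
              nrow(x), attr(x, "min_visits"), attr(x, "dt")))
  if (nrow(x))
    cat(sprintf("  S_e in [%d, %d], S_i in [%d, %d]\n",
                min(x$S_e), max(x$S_e), min(x$S_i), max(x$S_i)))
  invisible(x)
}

#' @param y unused.
#' @param thin plot every `thin`-th state to keep the arrow field readable.
#' @param scale arrow length per unit derivative.
#' @rdname reconstruct_flow
#' @export
plot.flow_field <- function(x, y = NULL, thin = 2L, scale = NULL, ...) {
  f <- x[seq(1, nrow(x), by = thin), ]
  if (is.null(scale))
    scale <- 0.05 * diff(range(x$S_e)) / max(abs(x$mean_dSe), 1e-9)
  graphics::plot(f$S_e, f$S_i, type = "n", xlab = "S_e (spikes/bin)",
                 ylab = "S_i (spikes/bin)", ...)
  graphics::arrows(f$S_e, f$S_i, f$S_e + scale * f$mean_dSe,
                   f$S_i + scale * f$mean_dSi, length = 0.03, col = "grey30")
  invisible(x)
}

#' State-dependent distribution of count derivatives
#'
#' Normalized histogram of the forward-difference derivatives observed from
#' one state, for one population, on the native derivative grid (multiples of
#' `1/dt`).
#'
#' @param series a [count_series()].
#' @param state integer pair `c(S_e, S_i)`.
#' @param population `"exc"` or `"inh"`.
#' @param min_visits minimum number of visits required.
#' @return An object of class `derivative_distribution`: data frame with
#'   columns `derivative` (spikes/ms) and `mass` summing to one.
#' @export
derivative_distribution <- function(series, state, population = c("exc", "inh"),
                                    min_visits = 20L) {
  stopifnot(inherits(series, "count_series"))
  population <- match.arg(population)
  n <- nrow(series)
  dt <- attr(series, "dt")
  at <- which(series$S_e[-n] == state[1] & series$S_i[-n] == state[2])
  if (length(at) < min_visits)
    stop(sprintf("state (%d, %d) visited only %d times (min %d)",
                 state[1], state[2], length(at), min_visits))
  x <- if (population == "exc") series$S_e else series$S_i
  incr <- x[at + 1L] - x[at]
  tab <- table(incr)
  structure(data.frame(derivative = as.integer(names(tab)) / dt,
                       mass = as.numeric(tab) / length(incr)),
            state = state, population = population, dt = dt,
            class = c("derivative_distribution", "data.frame"))
}

#' Overlap between two derivative distributions
#'
#' For every derivative value in the union of the supports, takes the minimum
#' of the two probability masses; the sum of the minima is 1 for identical
#' distributions and 0 for disjoint supports.
#'
#' @param p,q `derivative_distribution` objects (or data frames with columns
#'   `derivative` and `mass`).
#' @return Scalar in \[0, 1\].
#' @export
distribution_overlap <- function(p, q) {
  for (d in list(p, q))
    if (abs(sum(d$mass) - 1) > 1e-8) stop("distributions must be normalized")
  grid <- sort(unique(c(p$derivative, q$derivative)))
  pm <- p$mass[match(grid, p$derivative)]; pm[is.na(pm)] <- 0
  qm <- q$mass[match(grid, q$derivative)]; qm[is.na(qm)] <- 0
  sum(pmin(pm, qm))
}

# occupancy-weighted 3x3 box smoothing of a derivative surface on the state
# grid; weights are visit counts, unvisited cells contribute nothing
smooth_surface <- function(z, w) {
  nr <- nrow(z); nc <- ncol(z)
  zw <- z * w
  zw[is.na(zw)] <- 0
  w0 <- w
  acc_z <- matrix(0, nr, nc); acc_w <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    acc_z[rt, ct] <- acc_z[rt, ct] + zw[rs, cs]
    acc_w[rt, ct] <- acc_w[rt, ct] + w0[rs, cs]
  }
  out <- acc_z / acc_w
  out[acc_w == 0] <- NA
  out
}

#' Extract isoclines of the reconstructed flow
#'
#' Places the per-state mean derivatives of one component on the integer state
#' grid, smooths the surface with an occupancy-weighted 3x3 box filter, and
#' traces contour lines (marching squares) at the requested levels. Levels
#' outside the observed derivative range simply give no polyline. Typical
#' levels are `c(-200, 0, 200)` spikes/ms for the excitatory component and
#' `c(-50, 0, 50)` for the inhibitory one; the zero level is the nullcline.
#'
#' @param flow a [reconstruct_flow()] result.
#' @param component `"exc"` or `"inh"`.
#' @param levels numeric vector of derivative levels (spikes/ms).
#' @param smooth logical; apply the box filter before contouring.
#' @return An object of class `isocline_set`: list of polylines, each a data
#'   frame `S_e`, `S_i` with attribute `level`.
#' @export
extract_isoclines <- function(flow, component = c("exc", "inh"),
                              levels = NULL, smooth = TRUE) {
  stopifnot(inherits(flow, "flow_field"))
  component <- match.arg(component)
  if (is.null(levels))
    levels <- if (component == "exc") c(-200, 0, 200) else c(-50, 0, 50)
  xs <- seq(min(flow$S_e), max(flow$S_e))
  ys <- seq(min(flow$S_i), max(flow$S_i))
  z <- matrix(NA_real_, length(xs), length(ys))
  w <- matrix(0, length(xs), length(ys))
  ij <- cbind(flow$S_e - min(flow$S_e) + 1L, flow$S_i - min(flow$S_i) + 1L)
  z[ij] <- if (component == "exc") flow$mean_dSe else flow$mean_dSi
  w[ij] <- flow$visits
  if (smooth) z <- smooth_surface(z, w)
  # contourLines needs finite values; mask unvisited cells afterwards by
  # filling with a far-off constant so no spurious crossing is created
  fill <- if (all(is.na(z))) 0 else 2 * max(abs(z), na.rm = TRUE) + 1
  zf <- z; zf[is.na(zf)] <- fill
  cl <- grDevices::contourLines(xs, ys, zf, levels = levels)
  polys <- lapply(cl, function(p)
    structure(data.frame(S_e = p$x, S_i = p$y), level = p$level))
  # drop polylines that run along the filled (unvisited) border
  visited <- !is.na(z)
  keep <- vapply(polys, function(p) {
    ii <- pmin(pmax(round(p$S_e - min(xs) + 1), 1), length(xs))
    jj <- pmin(pmax(round(p$S_i - min(ys) + 1), 1), length(ys))
    mean(visited[cbind(ii, jj)]) > 0.5
  }, logical(1))
  structure(polys[keep], component = component, levels = levels,
            class = "isocline_set")
}

#' @export
print.isocline_set <- function(x, ...) {
  cat(sprintf("Isocline set (%s component): %d polylines at levels {%s}\n",
              attr(x, "component"), length(x),
              paste(attr(x, "levels"), collapse = ", ")))
  invisible(x)
}

#' @export
plot.isocline_set <- function(x, y = NULL, add = FALSE, col = "black", ...) {
  if (!length(x)) return(invisible(x))
  if (!add) {
    rx <- range(unlist(lapply(x, `[[`, "S_e")))
    ry <- range(unlist(lapply(x, `[[`, "S_i")))
    graphics::plot(NA, xlim = rx, ylim = ry, xlab = "S_e", ylab = "S_i", ...)
  }
  for (p in x) graphics::lines(p$S_e, p$S_i, col = col)
  invisible(x)
}

#' Occupancy-weighted excitatory/inhibitory variance ratio
#'
#' Averages the per-state ratio of excitatory to inhibitory derivative
#' variance over all states where both are defined, weighting by visit
#' counts. Under the binomial (independent-neuron) noise model the variance
#' scales linearly with population size, so the ratio approaches
#' \eqn{N_e / N_i}.
#'
#' @param flow a [reconstruct_flow()] result.
#' @return Scalar ratio.
#' @export
variance_ratio <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  ok <- flow$var_dSi > 0
  if (!all(ok))
    warning(sum(!ok), " states with zero inhibitory variance excluded")
  f <- flow[ok, ]
  if (!nrow(f)) stop("no states with positive inhibitory variance")
  sum(f$visits * f$var_dSe / f$var_dSi) / sum(f$visits)
}
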