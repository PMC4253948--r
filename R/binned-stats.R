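#' Construct a binned population count series
#'
#' @param S_e,S_i aligned integer vectors of excitatory / inhibitory spike
#'   counts per bin.
#' @param dt bin width (ms).
#' @param origin_ms time of the left edge of the first bin (ms).
#' @return A data frame of class `count_series` with columns `time_ms`, `S_e`,
#'   `S_i` and attributes `dt` and `origin_ms`.
#' @export
count_series <- function(S_e, S_i, dt, origin_ms = 0) {
  if (length(S_e) != length(S_i)) stop("S_e and S_i must have equal length")
  if (dt <= 0) stop("dt must be positive")
  if (length(S_e) && (min(S_e) < 0 || min(S_i) < 0))
    stop("counts must be nonnegative")
  x <- data.frame(time_ms = origin_ms + (seq_along(S_e) - 1) * dt,
                  S_e = as.integer(S_e), S_i = as.integer(S_i))
  attr(x, "dt") <- dt
  attr(x, "origin_ms") <- origin_ms
  class(x) <- c("count_series", "data.frame")
  x
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("Population count series: %d bins of %g ms (%.6g ms total)\n",
              nrow(x), attr(x, "dt"), nrow(x) * attr(x, "dt")))
  cat(sprintf("  mean counts per bin: S_e = %.3f, S_i = %.3f\n",
              mean(x$S_e), mean(x$S_i)))
  invisible(x)
}

#' @param y a `count_series`.
#' @param max_bins plot at most this many leading bins.
#' @rdname count_series
#' @export
plot.count_series <- function(x, max_bins = 2000L, y = NULL, ...) {
  n <- min(nrow(x), max_bins)
  graphics::plot(x$time_ms[1:n], x$S_e[1:n], type = "l", col = "steelblue",
                 xlab = "time (ms)", ylab = "spikes per bin", ...)
  graphics::lines(x$time_ms[1:n], x$S_i[1:n], col = "firebrick")
  graphics::legend("topright", c("excitatory", "inhibitory"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Bin a spike train set into population counts (PSTH)
#'
#' Counts spikes of each population in half-open bins
#' \eqn{[k\,dt, (k+1)\,dt)}. The bin width must be an integer multiple of the
#' time resolution of the spike set (when known), so that events on the grid
#' fall unambiguously into bins.
#'
#' @param spikes a `spike_train_set`.
#' @param dt bin width (ms).
#' @return A [count_series()].
#' @export
bin_counts <- function(spikes, dt) {
  stopifnot(inherits(spikes, "spike_train_set"))
  res <- attr(spikes, "dt_sim")
  if (!is.na(res) && abs(dt / res - round(dt / res)) > 1e-9)
    stop("dt must be an integer multiple of the source resolution ", res, " ms")
  duration <- attr(spikes, "duration_ms")
  n_bins <- as.integer(ceiling(duration / dt - 1e-9))
  n_exc <- attr(spikes, "n_exc")
  is_exc <- spikes$neuron <= n_exc
  if (!is.na(res)) {
    # snap event times to the simulation grid first, so that binning at any
    # multiple of the resolution is consistent under floating-point noise
    idx <- round(spikes$time_ms / res) %/% round(dt / res) + 1L
  } else {
    idx <- floor(spikes$time_ms / dt) + 1L
  }
  # guard against events exactly at `duration` landing past the last bin
  idx <- pmin(idx, n_bins)
  S_e <- tabulate(idx[is_exc], nbins = n_bins)
  S_i <- tabulate(idx[!is_exc], nbins = n_bins)
  count_series(S_e, S_i, dt)
}

#' Rebin a count series to a coarser resolution
#'
#' @param series a [count_series()].
#' @param dt new bin width (ms), an integer multiple of the current one.
#' @return A [count_series()] at resolution `dt`.
#' @export
rebin_counts <- function(series, dt) {
  stopifnot(inherits(series, "count_series"))
  dt0 <- attr(series, "dt")
  f <- dt / dt0
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("dt must be an integer multiple of the current bin width")
  f <- as.integer(round(f))
  n <- (nrow(series) %/% f) * f
  grp <- rep(seq_len(n %/% f), each = f)
  count_series(as.integer(rowsum(series$S_e[1:n], grp)),
               as.integer(rowsum(series$S_i[1:n], grp)),
               dt, origin_ms = attr(series, "origin_ms"))
}

#' Normalized autocorrelation of a count sequence
#'
#' Mean-subtracted, variance-normalized autocorrelation (biased estimator,
#' dividing by \eqn{n}, so the sequence is positive semidefinite and the value
#' at lag zero is exactly 1).
#'
#' @param x integer or numeric sequence.
#' @param max_lag maximum lag in bins.
#' @param dt bin width (ms), used only to label the lag grid.
#' @return An object of class `correlation_function`: a data frame with
#'   columns `lag_ms` and `value`.
#' @export
autocorrelation <- function(x, max_lag, dt = 1) {
  if (length(x) <= max_lag) stop("series must be longer than max_lag")
  if (stats::var(x) == 0) stop("autocorrelation undefined for a constant series")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE,
                  type = "correlation")
  structure(data.frame(lag_ms = (0:max_lag) * dt, value = as.numeric(a$acf)),
            dt = dt, kind = "acf",
            class = c("correlation_function", "data.frame"))
}

#' Normalized cross-correlation of two count sequences
#'
#' Mean-subtracted and normalized by the product of the standard deviations;
#' `value` at lag \eqn{\ell} estimates
#' \eqn{\mathrm{corr}(x_t, y_{t+\ell})}, so if `y` is a copy of `x` delayed by
#' `k` bins the peak sits at lag `k`.
#'
#' @param x,y equal-length sequences.
#' @param max_lag maximum |lag| in bins.
#' @param dt bin width (ms).
#' @return A `correlation_function` on the symmetric lag grid.
#' @export
crosscorrelation <- function(x, y, max_lag, dt = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("cross-correlation undefined for a constant series")
  # stats::ccf reports cor(x[t+k], y[t]); cor(x[t], y[t+l]) is its value at -l
  cc <- stats::ccf(x, y, lag.max = max_lag, plot = FALSE, demean = TRUE,
                   type = "correlation")
  v <- as.numeric(cc$acf)[order(-as.numeric(cc$lag))]
  structure(data.frame(lag_ms = (-max_lag:max_lag) * dt, value = v),
            dt = dt, kind = "ccf",
            class = c("correlation_function", "data.frame"))
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("%s on lags [%g, %g] ms (%d points), peak %.4f\n",
              if (identical(attr(x, "kind"), "ccf")) "Cross-correlation"
              else "Autocorrelation",
              min(x$lag_ms), max(x$lag_ms), nrow(x), max(x$value)))
  invisible(x)
}

#' @export
plot.correlation_function <- function(x, y = NULL, ...) {
  graphics::plot(x$lag_ms, x$value, type = "h", xlab = "lag (ms)",
                 ylab = "correlation", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' First zero crossing of a correlation function
#'
#' Scans the positive-lag range for the first sign change from positive and
#' returns the linearly interpolated crossing lag, the standard first estimate
#' of the intrinsic time scale of the binned population activity.
#'
#' @param corr a `correlation_function`.
#' @return Lag of the first zero crossing (ms).
#' @export
first_zero_crossing <- function(corr) {
  stopifnot(inherits(corr, "correlation_function"))
  pos <- corr[corr$lag_ms >= 0, ]
  v <- pos$value
  idx <- which(v[-length(v)] > 0 & v[-1] <= 0)
  if (!length(idx)) stop("no zero crossing within the lag range")
  i <- idx[1]
  l0 <- pos$lag_ms[i]; l1 <- pos$lag_ms[i + 1]
  v0 <- v[i]; v1 <- v[i + 1]
  l0 + (l1 - l0) * v0 / (v0 - v1)
}

#' Welch power spectral density of a count sequence
#'
#' Averaged modified periodogram: the demeaned series is split into
#' overlapping segments, each is Hann-windowed and Fourier transformed, and
#' the one-sided periodograms are averaged. With time in ms the frequency
#' axis is in kHz. The estimate is scaled so that the integral of the PSD
#' over frequency recovers the series variance (Parseval).
#'
#' @param x numeric sequence.
#' @param dt bin width (ms).
#' @param nseg segment length in bins (power of two recommended); default
#'   `2^14`, reduced to at most half the series length.
#' @param overlap fractional segment overlap, default 0.5.
#' @return An object of class `spectrum_estimate`: data frame with columns
#'   `freq_khz` and `power`, attributes `nseg`, `overlap`, `df_khz`.
#' @export
power_spectrum <- function(x, dt, nseg = 2^14, overlap = 0.5) {
  n <- length(x)
  nseg <- min(nseg, 2^floor(log2(n / 2)))
  if (n < 2 * nseg) stop("series shorter than two segments")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / nseg))   # Hann
  u <- sum(w^2)
  nfreq <- nseg %/% 2
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    pxx <- (Mod(ft)^2)[2:(nfreq + 1)]   # drop DC
    acc <- acc + pxx
  }
  # scale: two-sided |fft|^2 * dt / U; fold to one-sided
  pxx <- acc / length(starts) * dt / u
  pxx[-nfreq] <- 2 * pxx[-nfreq]        # all but Nyquist appear twice
  df <- 1 / (nseg * dt)
  structure(data.frame(freq_khz = (1:nfreq) * df, power = pxx),
            nseg = nseg, overlap = overlap, df_khz = df, dt = dt,
            class = c("spectrum_estimate", "data.frame"))
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("Welch PSD: %d frequencies up to %.4g kHz (nseg = %d, overlap = %g)\n",
              nrow(x), max(x$freq_khz), attr(x, "nseg"), attr(x, "overlap")))
  invisible(x)
}

#' @export
plot.spectrum_estimate <- function(x, y = NULL, ...) {
  graphics::plot(x$freq_khz, x$power, type = "l", log = "y",
                 xlab = "frequency (kHz)", ylab = "power density", ...)
  invisible(x)
}

#' Mean squared log-power distance between two spectra
#'
#' Quantifies the mismatch of two power spectral density estimates on a common
#' frequency grid as the mean of squared differences of natural-log power.
#' Zero if and only if the spectra are identical; doubling one spectrum gives
#' exactly \eqn{(\log 2)^2}.
#'
#' @param a,b `spectrum_estimate` objects on identical frequency grids.
#' @return Nonnegative scalar.
#' @export
spectrum_distance <- function(a, b) {
  stopifnot(inherits(a, "spectrum_estimate"), inherits(b, "spectrum_estimate"))
  if (nrow(a) != nrow(b) || max(abs(a$freq_khz - b$freq_khz)) > 1e-9)
    stop("spectra are not on the same frequency grid")
  mean((log(a$power) - log(b$power))^2)
}

#' Discrete-aware maximum-likelihood log-normal fit to spike counts
#'
#' Fits a log-normal distribution to integer spike counts, taking their
#' discreteness into account: the likelihood uses the bin-integrated masses
#' \eqn{P(k) = F(k + 1/2) - F(k - 1/2)} for \eqn{k \ge 1} and
#' \eqn{P(0) = F(1/2)}, where \eqn{F} is the log-normal CDF with parameters
#' `mu_log` and `sigma_log` (location and scale of the log counts).
#'
#' @param counts integer vector of per-bin spike counts; needs at least 100
#'   nonzero entries.
#' @return An object of class `lognormal_fit`: list with `mu_log`,
#'   `sigma_log`, `n`, `loglik`, `gof` (chi-square statistic over pooled count
#'   classes) and `degenerate` (TRUE when the counts are constant and the
#'   scale collapses to zero).
#' @export
fit_lognormal_counts <- function(counts) {
  counts <- as.integer(counts)
  if (!length(counts) || all(counts == 0)) stop("all counts are zero")
  if (sum(counts > 0) < 100) stop("need at least 100 nonzero counts")
  tab <- table(counts)
  k <- as.integer(names(tab))
  n_k <- as.numeric(tab)
  n <- sum(n_k)
  if (length(k) == 1L) {
    return(structure(list(mu_log = log(k), sigma_log = 0, n = n,
                          loglik = 0, gof = 0, degenerate = TRUE),
                     class = "lognormal_fit"))
  }
  mass <- function(mu, sig) {
    hi <- stats::plnorm(k + 0.5, mu, sig)
    lo <- ifelse(k >= 1L, stats::plnorm(k - 0.5, mu, sig), 0)
    pmax(hi - lo, 1e-300)
  }
  nll <- function(par) -sum(n_k * log(mass(par[1], exp(par[2]))))
  lk <- log(pmax(counts, 0.5))
  start <- c(mean(lk), log(max(stats::sd(lk), 1e-3)))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  mu <- opt$par[1]; sig <- exp(opt$par[2])
  p_hat <- mass(mu, sig)
  gof <- sum((n_k - n * p_hat)^2 / pmax(n * p_hat, 1e-12))
  structure(list(mu_log = mu, sigma_log = sig, n = n, loglik = -opt$value,
                 gof = gof, degenerate = FALSE),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Discrete log-normal fit: mu = %.4f, sigma = %.4f (n = %d%s)\n",
              x$mu_log, x$sigma_log, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
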