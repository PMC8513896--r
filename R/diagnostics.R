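#' Confidence-interval width ratio (CIWR) at the covariate boundaries
#'
#' The boundary-uncertainty diagnostic: the confidence-interval width at each
#' endpoint of the covariate grid divided by the mean width over the interior
#' region, where "interior" is covariate values between 0.05 and 0.95 of the
#' covariate range. Values near 1-2 indicate boundary uncertainty consistent
#' with the reduced sampling near a bound; much larger values indicate a loss
#' of statistical power (e.g. unmodified cardinal splines estimating a
#' boundary derivative), and values near 0 indicate under-stated uncertainty.
#'
#' Widths are measured on the exponentiated (intensity-modulation) scale by
#' default, matching plotted modulation curves; `scale = "log"` uses the
#' log-intensity widths (equivalently the standard-error ratio), which is
#' insensitive to the level of the estimate at the endpoint.
#'
#' @param curve An [intensity_curve()].
#' @param scale `"response"` (exponentiated, default) or `"log"`.
#' @param interior Fractions of the covariate range bounding the interior
#'   region (default `c(0.05, 0.95)`).
#' @return Object of class `ciwr_report`: list with `ciwr_start`,
#'   `ciwr_end`, `w_start`, `w_end`, `w_interior` (the mean interior width),
#'   `interior_range`, `n_interior`, `scale`.
#' @export
ciwr <- function(curve, scale = c("response", "log"),
                 interior = c(0.05, 0.95)) {
  stopifnot(inherits(curve, "intensity_curve"))
  scale <- match.arg(scale)
  g <- curve$grid
  n <- length(g)
  if (n < 12L) stop("curve grid must include endpoints and >= 10 interior points")
  w <- switch(scale,
    response = curve$upper - curve$lower,
    log = log(curve$upper) - log(curve$lower)
  )
  r <- range(g)
  lo <- r[1L] + interior[1L] * diff(r)
  hi <- r[1L] + interior[2L] * diff(r)
  inside <- g >= lo & g <= hi
  if (!any(inside)) stop("no interior grid points in the CIWR interior range")
  w_int <- mean(w[inside])
  i_start <- which.min(g)
  i_end <- which.max(g)
  structure(
    list(ciwr_start = w[i_start] / w_int, ciwr_end = w[i_end] / w_int,
         w_start = w[i_start], w_end = w[i_end], w_interior = w_int,
         interior_range = c(lo, hi), n_interior = sum(inside), scale = scale),
    class = "ciwr_report"
  )
}

#' @export
print.ciwr_report <- function(x, ...) {
  cat(sprintf(
    "<ciwr_report> (%s scale) CIWR start = %.3g, end = %.3g\n",
    x$scale, x$ciwr_start, x$ciwr_end))
  cat(sprintf("  endpoint widths %.3g / %.3g; mean interior width %.3g over %d point(s)\n",
              x$w_start, x$w_end, x$w_interior, x$n_interior))
  invisible(x)
}

#' Parameter correlation matrix from the inverse Fisher information
#'
#' \eqn{\rho_{ij} = \Sigma_{ij}/\sqrt{\Sigma_{ii}\Sigma_{jj}}} over the
#' (optionally block-restricted) coefficient covariance. Separated and
#' zero-variance columns are excluded with a message; locally supported bases
#' (indicator, spline) yield near-diagonal matrices, whereas globally
#' supported bases (raised cosines) do not.
#'
#' @param fit A [fit_ppglm()] result.
#' @param block Optional block name restricting to that block's columns.
#' @return Correlation matrix (unit diagonal) for the retained columns.
#' @export
param_correlation <- function(fit, block = NULL) {
  stopifnot(inherits(fit, "ppglm_fit"))
  idx <- if (is.null(block)) {
    seq_along(fit$coefficients)
  } else {
    if (!block %in% names(fit$design$blocks)) {
      stop(sprintf("no block named '%s'", block))
    }
    fit$design$blocks[[block]]$cols
  }
  S <- fit$vcov[idx, idx, drop = FALSE]
  keep <- !fit$separated[idx] & diag(S) > 0
  if (any(!keep)) {
    message(sprintf("param_correlation: excluding %d separated/zero-variance column(s)",
                    sum(!keep)))
  }
  S <- S[keep, keep, drop = FALSE]
  if (ncol(S) == 0L) stop("no usable columns for a correlation matrix")
  stats::cov2cor(S)
}

#' Occupancy-normalized spatial rate map
#'
#' Spikes per unit time spent in each spatial bin: for bin `j`,
#' (number of spikes emitted while the animal was in `j`) divided by (time
#' spent in `j`). Bins never occupied are reported as `NA`.
#'
#' @param positions Per-bin linearized positions aligned to the spike train.
#' @param train A [spike_train()].
#' @param breaks Spatial bin edges (numeric vector), or a single bin count
#'   over the observed position range.
#' @return Data frame with `mid`, `occupancy_s`, `spikes`, `rate`.
#' @export
occupancy_rate_map <- function(positions, train, breaks = 30) {
  stopifnot(inherits(train, "spike_train"))
  if (length(positions) != length(train$counts)) {
    stop("positions and spike train are not aligned")
  }
  if (length(breaks) == 1L) {
    breaks <- seq(min(positions), max(positions), length.out = breaks + 1L)
  }
  idx <- findInterval(positions, breaks, rightmost.closed = TRUE)
  valid <- idx >= 1L & idx <= length(breaks) - 1L
  nb <- length(breaks) - 1L
  occ <- tabulate(idx[valid], nb) * train$bin_width
  spk <- vapply(seq_len(nb), function(j) {
    sum(train$counts[valid & idx == j])
  }, numeric(1))
  if (all(occ == 0)) stop("no occupancy in any spatial bin")
  rate <- ifelse(occ > 0, spk / occ, NA_real_)
  data.frame(
    mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
    occupancy_s = occ, spikes = spk, rate = rate
  )
}

#' Spike-train autocorrelation
#'
#' Autocorrelation of the mean-centered binned spike train at lags
#' `1..max_lag` (in bins; 1 ms bins by default convention). A Poisson train
#' is flat near 0; refractoriness produces negative values at short lags and
#' theta-band firing produces positive values over tens of ms.
#'
#' @param train A [spike_train()].
#' @param max_lag Maximum lag in bins (default 200).
#' @return Numeric vector of autocorrelations at lags `1..max_lag`.
#' @export
spike_autocorrelation <- function(train, max_lag = 200) {
  stopifnot(inherits(train, "spike_train"))
  if (sum(train$counts) < 2L) stop("need at least 2 spikes")
  a <- stats::acf(train$counts, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)
  ac <- drop(a$acf)[-1L]
  names(ac) <- seq_len(max_lag)
  ac
}

#' Inter-spike interval histogram
#'
#' @param spike_times Spike times in seconds (>= 2 spikes).
#' @param bin_width ISI bin width in seconds (default 0.001).
#' @param max_isi Largest ISI retained (default 0.2 s).
#' @return Data frame with `isi_mid` (seconds) and `count`.
#' @export
isi_histogram <- function(spike_times, bin_width = 0.001, max_isi = 0.2) {
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) < 2L) stop("need at least 2 spikes for ISIs")
  isis <- diff(spike_times)
  isis <- isis[isis <= max_isi]
  breaks <- seq(0, max_isi, by = bin_width)
  if (breaks[length(breaks)] < max_isi) breaks <- c(breaks, max_isi)
  idx <- findInterval(isis, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, length(breaks) - 1L)
  data.frame(
    isi_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
    count = counts
  )
}
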