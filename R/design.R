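#' Bin spike times into a spike-count train
#'
#' Counts spikes in contiguous bins `[t0 + k*bin_width, t0 + (k+1)*bin_width)`
#' over `[t0, t1)`. Spikes outside the window are dropped with a message. At
#' the default 1 ms resolution counts are almost surely 0/1, so the Poisson
#' GLM on counts approximates the point-process likelihood.
#'
#' @param spike_times Numeric vector of spike times in seconds (sorted or not).
#' @param t0,t1 Window start and end (seconds), `t0 < t1`.
#' @param bin_width Bin width \eqn{\Delta} in seconds (default 0.001).
#' @return An object of class `spike_train`: list with integer `counts`,
#'   `bin_width`, `t0`.
#' @examples
#' bin_spikes(c(0.0005, 0.0015), 0, 0.003, 0.001)$counts  # 1 1 0
#' @export
bin_spikes <- function(spike_times, t0, t1, bin_width = 0.001) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  if (t0 >= t1) stop("need t0 < t1")
  spike_times <- sort(as.numeric(spike_times))
  n_bins <- as.integer(ceiling((t1 - t0) / bin_width - 1e-9))
  inside <- spike_times >= t0 & spike_times < t1
  if (any(!inside)) {
    message(sprintf("bin_spikes: dropped %d spike(s) outside [%g, %g)",
                    sum(!inside), t0, t1))
  }
  st <- spike_times[inside]
  # 1e-9-bin guard keeps binning invariant to a common time translation
  # despite floating-point noise at bin edges
  counts <- tabulate(pmin(floor((st - t0) / bin_width + 1e-9) + 1L, n_bins),
                     n_bins)
  spike_train(counts, bin_width, t0)
}

#' Construct a spike train from counts
#'
#' @param counts Non-negative integer vector of per-bin spike counts.
#' @param bin_width Bin width in seconds.
#' @param t0 Start time (seconds).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(counts, bin_width = 0.001, t0 = 0) {
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  structure(list(counts = counts, bin_width = bin_width, t0 = t0),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %d bins x %g ms, %d spike(s), t0 = %g s\n",
    length(x$counts), x$bin_width * 1000, sum(x$counts), x$t0))
  invisible(x)
}

#' Bin centers of a spike train
#' @param train A `spike_train`.
#' @return Numeric vector of bin-center times (seconds).
#' @export
bin_centers <- function(train) {
  train$t0 + (seq_along(train$counts) - 0.5) * train$bin_width
}

#' Resample a position trace to spike-train bins
#'
#' Nearest-time interpolation of a sampled position signal onto the bin
#' centers of a spike train, producing one linearized position per bin.
#'
#' @param times Sample times (seconds), sorted.
#' @param positions Linearized positions (cm), same length as `times`.
#' @param train A [spike_train()] defining the target bins.
#' @return Numeric vector of per-bin positions.
#' @export
resample_position <- function(times, positions, train) {
  stopifnot(length(times) == length(positions), length(times) >= 1)
  o <- order(times)
  times <- times[o]; positions <- positions[o]
  centers <- bin_centers(train)
  # nearest-neighbour: interval index, then pick the closer endpoint
  idx <- findInterval(centers, times, all.inside = TRUE)
  right <- idx < length(times) &
    (centers - times[idx]) > (times[idx + 1L] - centers)
  idx[right] <- idx[right] + 1L
  positions[idx]
}

#' Spike-history design block
#'
#' Convolves the spike train with each lag-basis function: column `j` at bin
#' `t` is \eqn{\sum_{\ell=1}^{L} B_{\ell j}\, \Delta N_{t-\ell}}, where the
#' lag basis `B` is the spec evaluated at lags `1..L` bins (expressed in ms).
#' Lag 0 is excluded — only strictly past spikes influence the present — and
#' bins before the session start contribute zero history ("cold start"). Set
#' `drop_cold_start = TRUE` downstream via [fit_ppglm()]'s `subset` if the
#' first `L` bins should be excluded instead.
#'
#' @param train A [spike_train()].
#' @param spec A basis specification evaluated on lag (ms): [knot_grid()],
#'   [raised_cosine_spec()] or [partition_spec()].
#' @param L Number of history lags in bins (default 200, i.e. 200 ms at 1 ms
#'   bins). Must be smaller than the number of bins.
#' @return A `design_block` with `name = "history"`; `lag_ms` records the lag
#'   grid the basis was evaluated on.
#' @export
history_block <- function(train, spec, L = 200) {
  stopifnot(inherits(train, "spike_train"))
  counts <- train$counts
  n <- length(counts)
  if (L >= n) stop("history length L must be smaller than the number of bins")
  lag_ms <- (seq_len(L)) * train$bin_width * 1000
  B <- eval_basis(spec, lag_ms)
  Bm <- B$matrix
  X <- matrix(0, nrow = n, ncol = ncol(Bm))
  spikes <- which(counts > 0L)
  for (s in spikes) {
    take <- seq_len(min(L, n - s))
    if (length(take)) {
      rows <- s + take
      X[rows, ] <- X[rows, ] + Bm[take, , drop = FALSE] * counts[s]
    }
  }
  colnames(X) <- colnames(Bm)
  design_block(X, "history", spec, lag_ms = lag_ms)
}

#' Spatial design block
#'
#' Evaluates a spatial basis at the per-bin animal position: row `t` of the
#' block is the basis row at `positions[t]`.
#'
#' @param positions Per-bin linearized positions (cm), aligned to the spike
#'   train bins.
#' @param spec Spatial basis specification ([knot_grid()],
#'   [raised_cosine_spec()] or [partition_spec()]).
#' @param clamp Passed to [spline_basis()] for spline specs: clamp positions
#'   slightly outside the knot span instead of erroring.
#' @return A `design_block` with `name = "spatial"`.
#' @export
spatial_block <- function(positions, spec, clamp = FALSE) {
  B <- if (inherits(spec, "knot_grid")) {
    spline_basis(positions, spec, clamp = clamp)
  } else {
    eval_basis(spec, positions)
  }
  design_block(B$matrix, "spatial", spec)
}

design_block <- function(X, name, spec, lag_ms = NULL) {
  if (any(!is.finite(X))) stop("design block contains non-finite entries")
  structure(list(matrix = X, name = name, spec = spec, lag_ms = lag_ms),
            class = "design_block")
}

#' @export
print.design_block <- function(x, ...) {
  cat(sprintf("<design_block> '%s': %d bins x %d column(s)\n",
              x$name, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# TRUE for basis families whose rows sum to 1 (span the constant function)
is_partition_of_unity <- function(spec) {
  inherits(spec, "knot_grid") || inherits(spec, "partition_spec")
}

#' Assemble a point-process GLM design matrix
#'
#' Horizontally concatenates design blocks, preserving per-column provenance
#' labels. By default no intercept is added: spline and indicator blocks are
#' partitions of unity, so they span the constant and the baseline rate is
#' absorbed into the control-point coefficients (each \eqn{e^{\hat\beta_i}}
#' is then the intensity at knot `i`). Requesting an intercept alongside such
#' a block triggers an exact-collinearity warning.
#'
#' @param ... One or more `design_block` objects (or a single list of them).
#' @param intercept Add a constant column (default `FALSE`).
#' @return An object of class `ppglm_design`: list with `X`, `blocks` (named
#'   list of specs plus column indices), `intercept`.
#' @export
assemble_design <- function(..., intercept = FALSE) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "design_block") &&
      is.list(blocks[[1L]])) {
    blocks <- blocks[[1L]]
  }
  if (length(blocks) == 0L) stop("no design blocks supplied")
  if (!all(vapply(blocks, inherits, logical(1), "design_block"))) {
    stop("all arguments must be design_block objects")
  }
  nr <- vapply(blocks, function(b) nrow(b$matrix), integer(1))
  if (length(unique(nr)) != 1L) {
    stop("design blocks have mismatched bin counts: ",
         paste(nr, collapse = ", "))
  }
  if (intercept && any(vapply(blocks, function(b) is_partition_of_unity(b$spec),
                              logical(1)))) {
    warning(paste("intercept is exactly collinear with a partition-of-unity",
                  "block (spline/indicator rows sum to 1)"))
  }
  mats <- lapply(blocks, function(b) {
    m <- b$matrix
    colnames(m) <- paste0(b$name, ":", colnames(m))
    m
  })
  X <- do.call(cbind, mats)
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  col_index <- list()
  offset <- if (intercept) 1L else 0L
  info <- list()
  for (b in blocks) {
    p <- ncol(b$matrix)
    idx <- offset + seq_len(p)
    offset <- offset + p
    info[[b$name]] <- list(spec = b$spec, cols = idx, lag_ms = b$lag_ms)
  }
  structure(list(X = X, blocks = info, intercept = intercept),
            class = "ppglm_design")
}

#' @export
print.ppglm_design <- function(x, ...) {
  cat(sprintf("<ppglm_design> %d bins x %d column(s)%s\n",
              nrow(x$X), ncol(x$X),
              if (x$intercept) " (incl. intercept)" else ""))
  for (nm in names(x$blocks)) {
    cat(sprintf("  %s: %d column(s)\n", nm, length(x$blocks[[nm]]$cols)))
  }
  invisible(x)
}
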