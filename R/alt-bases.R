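#' Raised-cosine basis specification
#'
#' A set of raised-cosine bumps on a logarithmically scaled axis,
#' \deqn{B_j(x) = \{1 + \cos(a \log(x + c) - \phi_j)\}/2}
#' for \eqn{a \log(x + c) \in [\phi_j - \pi, \phi_j + \pi]} and 0 elsewhere,
#' with peak phases \eqn{\phi_j} spaced \eqn{\pi/2} apart. The log scaling
#' gives fine resolution at short lags and broad coverage at long lags, which
#' is the conventional choice for spike-history filters.
#'
#' By default `a` and the first phase are solved so that the first and last
#' peaks fall at `peak_range[1]` and `peak_range[2]`.
#'
#' @param n_basis Number of basis functions (default 5).
#' @param peak_range Covariate locations of the first and last peaks
#'   (default `c(1, 100)`, i.e. lags in ms; with 5 bumps the final bump's
#'   support then extends well past 200 ms, so a 200 ms history window is
#'   covered while estimates at the longest lags integrate spiking over long
#'   log-stretched periods).
#' @param log_offset The shift `c` inside the logarithm (default 1); all
#'   evaluated values must satisfy `x + c > 0`.
#' @param a Optional explicit log-scaling rate; overrides the solved value.
#' @param phis Optional explicit peak phases (radians); must be evenly spaced
#'   at `pi/2`.
#' @return An object of class `raised_cosine_spec` with elements `a`,
#'   `log_offset`, `phis`, `peaks` (covariate locations of the peaks).
#' @export
raised_cosine_spec <- function(n_basis = 5, peak_range = c(1, 100),
                               log_offset = 1, a = NULL, phis = NULL) {
  stopifnot(n_basis >= 1, length(peak_range) == 2, peak_range[1] < peak_range[2])
  if (any(peak_range + log_offset <= 0)) {
    stop("peak_range + log_offset must be positive")
  }
  if (is.null(a)) {
    a <- if (n_basis == 1L) 1 else {
      (n_basis - 1) * (pi / 2) /
        (log(peak_range[2] + log_offset) - log(peak_range[1] + log_offset))
    }
  }
  if (is.null(phis)) {
    phis <- a * log(peak_range[1] + log_offset) + (seq_len(n_basis) - 1) * pi / 2
  } else {
    if (length(phis) >= 2 &&
        any(abs(diff(phis) - pi / 2) > 1e-8)) {
      stop("`phis` must be evenly spaced at pi/2")
    }
  }
  peaks <- exp(phis / a) - log_offset
  structure(
    list(a = a, log_offset = log_offset, phis = phis, peaks = peaks),
    class = "raised_cosine_spec"
  )
}

#' @export
print.raised_cosine_spec <- function(x, ...) {
  cat(sprintf("<raised_cosine_spec> %d bumps, a = %.4g, c = %g\n",
              length(x$phis), x$a, x$log_offset))
  cat("  peaks at:", paste(signif(x$peaks, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a raised-cosine basis matrix
#'
#' @param values Numeric covariate values; each must satisfy
#'   `value + log_offset > 0`.
#' @param spec A [raised_cosine_spec()].
#' @return A `basis_matrix` whose columns lie in \[0, 1\] with compact support
#'   in log-time. Rows do **not** in general sum to 1 (no partition of unity).
#' @export
raised_cosine_basis <- function(values, spec) {
  stopifnot(inherits(spec, "raised_cosine_spec"))
  values <- as.numeric(values)
  if (any(values + spec$log_offset <= 0)) {
    stop(sprintf("all values must exceed %g (log-offset domain)",
                 -spec$log_offset))
  }
  z <- spec$a * log(values + spec$log_offset)
  M <- sapply(spec$phis, function(phi) {
    d <- z - phi
    ifelse(abs(d) <= pi, (1 + cos(d)) / 2, 0)
  })
  M <- matrix(M, nrow = length(values))
  colnames(M) <- paste0("rc", signif(spec$peaks, 5))
  structure(list(matrix = M, values = values, spec = spec),
            class = "basis_matrix")
}

#' @export
eval_basis.raised_cosine_spec <- function(spec, values, ...) {
  raised_cosine_basis(values, spec)
}

#' Indicator (partition) basis specification
#'
#' Non-overlapping step functions: the covariate range is partitioned into
#' half-open intervals `[e_j, e_{j+1})` (the last interval closed), and each
#' basis function is the indicator of one interval. The default history
#' partition uses 4 ms bins over lags 0-200 ms (50 functions).
#'
#' @param edges Strictly increasing numeric vector of interval edges.
#' @return An object of class `partition_spec`.
#' @export
partition_spec <- function(edges = seq(0, 200, by = 4)) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    stop("`edges` must be strictly increasing with length >= 2")
  }
  structure(list(edges = edges), class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("<partition_spec> %d interval(s) on [%g, %g]\n",
              length(x$edges) - 1L, x$edges[1L], x$edges[length(x$edges)]))
  invisible(x)
}

#' Evaluate an indicator basis matrix
#'
#' @param values Numeric covariate values within `[min(edges), max(edges)]`.
#' @param spec A [partition_spec()] (or a bare numeric vector of edges).
#' @return A `basis_matrix` with exactly one 1 per row (exact one-hot).
#' @export
indicator_basis <- function(values, spec) {
  if (is.numeric(spec)) spec <- partition_spec(spec)
  stopifnot(inherits(spec, "partition_spec"))
  e <- spec$edges
  values <- as.numeric(values)
  if (any(values < e[1L] | values > e[length(e)])) {
    bad <- values[values < e[1L] | values > e[length(e)]][1L]
    stop(sprintf("value %g outside partition range [%g, %g]",
                 bad, e[1L], e[length(e)]))
  }
  idx <- findInterval(values, e)
  idx[idx >= length(e)] <- length(e) - 1L  # last interval closed
  M <- matrix(0, nrow = length(values), ncol = length(e) - 1L)
  M[cbind(seq_along(values), idx)] <- 1
  colnames(M) <- paste0("bin", signif(e[-length(e)], 6), "_",
                        signif(e[-1L], 6))
  structure(list(matrix = M, values = values, spec = spec),
            class = "basis_matrix")
}

#' @export
eval_basis.partition_spec <- function(spec, values, ...) {
  indicator_basis(values, spec)
}
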