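#' Fit a point-process GLM by iteratively re-weighted least squares
#'
#' Maximizes the Poisson log-likelihood
#' \deqn{\ell(\theta) = \sum_t [y_t (x_t'\theta + o_t) - e^{x_t'\theta + o_t}
#' - \log y_t!]}{l(theta) = sum_t y_t (x_t'theta + o_t) - exp(x_t'theta + o_t) - log(y_t!)}
#' over binned spike counts with a log link, using Newton scoring (the
#' canonical-link IRLS) with step-halving, which guarantees a monotone
#' deviance path. The default offset is \eqn{\log\Delta}, placing
#' coefficients on the per-second intensity scale: at a spline knot,
#' \eqn{e^{\hat\beta_i}} is the conditional intensity (spikes/s) at that knot.
#'
#' The observed Fisher information \eqn{I_{\hat\theta} = X'WX} with
#' \eqn{W = \mathrm{diag}(\mu_t)} is computed at the optimum and inverted for
#' the coefficient covariance. Columns exhibiting complete separation (no
#' spikes anywhere on the column's support, or a diverging coefficient) are
#' flagged rather than causing failure, mirroring the "perfect prediction"
#' behaviour of such fits.
#'
#' @param design A [assemble_design()] object, a single `design_block`, or a
#'   bare numeric matrix.
#' @param train A [spike_train()] (or bare count vector when `design` is a
#'   matrix and `offset` is given).
#' @param offset Per-bin log-exposure; scalar or vector. Default
#'   `log(bin_width)`.
#' @param tol_step Convergence tolerance on the max absolute coefficient
#'   update (default 1e-8).
#' @param tol_loglik Convergence tolerance on the relative log-likelihood
#'   change (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @param init Optional starting coefficients (default 0, with any intercept
#'   column started at the log mean rate).
#' @return An object of class `ppglm_fit` with elements `coefficients`,
#'   `fisher`, `vcov`, `loglik`, `deviance`, `aic`, `iterations`,
#'   `converged`, `separated` (per-column flags), `fitted` (per-bin expected
#'   counts \eqn{\mu_t}), `design`, `train`, `offset`.
#' @export
fit_ppglm <- function(design, train, offset = NULL, tol_step = 1e-8,
                      tol_loglik = 1e-10, max_iter = 100, init = NULL) {
  if (inherits(design, "design_block")) design <- assemble_design(design)
  if (inherits(design, "ppglm_design")) {
    X <- design$X
  } else if (is.matrix(design)) {
    X <- design
    design <- structure(list(X = X, blocks = list(), intercept = FALSE),
                        class = "ppglm_design")
  } else {
    stop("`design` must be a ppglm_design, design_block, or matrix")
  }
  if (any(!is.finite(X))) stop("design matrix contains non-finite entries")
  if (inherits(train, "spike_train")) {
    y <- train$counts
    if (is.null(offset)) offset <- log(train$bin_width)
  } else {
    y <- as.numeric(train)
    train <- NULL
    if (is.null(offset)) stop("supply `offset` when `train` is a bare vector")
  }
  if (length(y) != nrow(X)) stop("counts and design have different lengths")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  off <- rep_len(offset, length(y))

  p <- ncol(X)
  theta <- numeric(p)
  if (!is.null(init)) {
    theta <- rep_len(init, p)
  } else if ("(Intercept)" %in% colnames(X) && mean(y) > 0) {
    theta[match("(Intercept)", colnames(X))] <- log(mean(y)) - mean(off)
  }

  loglik_at <- function(eta) sum(y * eta - exp(eta)) - sum(lgamma(y + 1))
  eta <- drop(X %*% theta) + off
  ll <- loglik_at(eta)
  converged <- FALSE
  ridge_used <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- exp(eta)
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X, X * mu)
    step <- tryCatch(
      solve(H, grad),
      error = function(e) {
        ridge_used <<- TRUE
        lam <- 1e-8 * mean(diag(H))
        if (!is.finite(lam) || lam <= 0) lam <- 1e-8
        solve(H + diag(lam, p), grad)
      }
    )
    # step-halving keeps the log-likelihood monotone (deviance never increases)
    halve <- 0L
    repeat {
      theta_new <- theta + step
      eta_new <- drop(X %*% theta_new) + off
      ll_new <- loglik_at(eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12 * max(1, abs(ll))) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 50L) break
    }
    d_ll <- abs(ll_new - ll) / max(1, abs(ll_new))
    theta <- theta_new; eta <- eta_new; ll <- ll_new
    if (max(abs(step)) < tol_step || d_ll < tol_loglik) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("IRLS did not converge in %d iterations", max_iter))
  }
  if (ridge_used) {
    message("fit_ppglm: rank-deficient IRLS step; ridge jitter 1e-8 applied")
  }

  mu <- exp(eta)
  fisher <- crossprod(X, X * mu)
  Sigma <- tryCatch(
    chol2inv(chol(fisher)),
    error = function(e) {
      message("fit_ppglm: Fisher information singular; ridge-regularized inverse")
      lam <- 1e-8 * mean(diag(fisher))
      if (!is.finite(lam) || lam <= 0) lam <- 1e-8
      solve(fisher + diag(lam, p))
    }
  )
  dimnames(fisher) <- dimnames(Sigma) <- list(colnames(X), colnames(X))
  names(theta) <- colnames(X)

  separated <- detect_separation(X, y, theta = theta)

  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  aic <- -2 * ll + 2 * p

  structure(
    list(coefficients = theta, fisher = fisher, vcov = Sigma,
         loglik = ll, deviance = dev, aic = aic, iterations = iter,
         converged = converged, separated = separated, fitted = mu,
         design = design, train = train, offset = off,
         ridge_used = ridge_used),
    class = "ppglm_fit"
  )
}

#' @export
print.ppglm_fit <- function(x, ...) {
  cat(sprintf(
    "<ppglm_fit> %d column(s), %d bin(s); logLik = %.2f, AIC = %.2f\n",
    length(x$coefficients), length(x$fitted), x$loglik, x$aic))
  cat(sprintf("  %d iteration(s), converged: %s, separated columns: %d\n",
              x$iterations, x$converged, sum(x$separated)))
  invisible(x)
}

#' @export
logLik.ppglm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
coef.ppglm_fit <- function(object, ...) object$coefficients

#' @export
vcov.ppglm_fit <- function(object, ...) object$vcov

#' Detect complete separation (perfect prediction)
#'
#' A design column is flagged when its support — the rows where the column is
#' materially nonzero — contains no spikes, or when the fitted coefficient
#' has diverged beyond `theta_bound` in absolute value (rate factor below
#' ~3e-7 at the default bound of 15). Such columns have maximum-likelihood
#' estimates at \eqn{-\infty} and effectively infinite interval widths.
#'
#' @param design Design matrix, `ppglm_design`, or `ppglm_fit`.
#' @param counts Spike counts (omit when `design` is a `ppglm_fit`).
#' @param theta Optional coefficient vector for the divergence check.
#' @param theta_bound Divergence bound on the log scale (default 15).
#' @param support_tol Relative threshold defining "materially nonzero"
#'   (default 1e-8 of the column max absolute value).
#' @return Logical vector, one flag per design column.
#' @export
detect_separation <- function(design, counts = NULL, theta = NULL,
                              theta_bound = 15, support_tol = 1e-8) {
  if (inherits(design, "ppglm_fit")) {
    if (is.null(counts)) counts <- design$train$counts
    if (is.null(theta)) theta <- design$coefficients
    design <- design$design
  }
  X <- if (inherits(design, "ppglm_design")) design$X else design
  y <- as.numeric(counts)
  flags <- vapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    thr <- support_tol * max(abs(col))
    support <- abs(col) > thr
    !any(support & y > 0)
  }, logical(1))
  if (!is.null(theta)) flags <- flags | abs(theta) > theta_bound
  names(flags) <- colnames(X)
  flags
}

#' Wald confidence intervals for model coefficients
#'
#' Intervals \eqn{\hat\theta_i \pm z \sqrt{\Sigma_{ii}}} from the inverse
#' observed Fisher information, reported on both the log-intensity and the
#' exponentiated (rate/modulation) scales. Separated columns receive
#' infinite-width intervals rather than an error.
#'
#' @param fit A [fit_ppglm()] result.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `term`, `estimate`, `se`, `lower`,
#'   `upper`, `rate`, `rate_lower`, `rate_upper`, `separated`.
#' @export
param_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ppglm_fit"), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients
  se <- sqrt(pmax(diag(fit$vcov), 0))
  se[fit$separated] <- Inf
  lower <- est - z * se
  upper <- est + z * se
  data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    lower = unname(lower), upper = unname(upper),
    rate = unname(exp(est)), rate_lower = unname(exp(lower)),
    rate_upper = unname(exp(upper)),
    separated = unname(fit$separated),
    row.names = NULL
  )
}

#' Intensity / modulation curve with confidence bounds for one block
#'
#' Evaluates one design block's contribution to the conditional intensity on
#' a covariate grid: at grid point with basis row \eqn{x},
#' \eqn{\exp(x'\hat\theta_b)} with Wald bounds
#' \eqn{\exp(x'\hat\theta_b \pm z\sqrt{x'\Sigma_b x})} using the block's full
#' sub-covariance (so between-knot uncertainty incorporates the estimated
#' parameter covariance). Other blocks contribute nothing, i.e. the curve is
#' the block's multiplicative modulation (for the spatial block with the
#' default offset convention this is the place field in spikes/s, assuming
#' unit history modulation).
#'
#' @param fit A [fit_ppglm()] result whose design has named blocks.
#' @param block Block name, e.g. `"spatial"` or `"history"`.
#' @param grid Covariate grid; defaults to 201 points spanning the block
#'   basis range (for history blocks, the evaluated lag grid in ms).
#' @param level Confidence level (default 0.95).
#' @return Object of class `intensity_curve`: data-frame-like list with
#'   `grid`, `estimate`, `lower`, `upper`, plus `log_estimate`, `log_se`,
#'   `level`, `block`.
#' @export
intensity_curve <- function(fit, block = "spatial", grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ppglm_fit"))
  if (!block %in% names(fit$design$blocks)) {
    stop(sprintf("design has no block named '%s' (available: %s)", block,
                 paste(names(fit$design$blocks), collapse = ", ")))
  }
  b <- fit$design$blocks[[block]]
  if (is.null(grid)) {
    grid <- if (!is.null(b$lag_ms)) {
      b$lag_ms
    } else if (inherits(b$spec, "knot_grid")) {
      r <- knot_range(b$spec)
      seq(r[1L], r[2L], length.out = 201L)
    } else if (inherits(b$spec, "partition_spec")) {
      e <- b$spec$edges
      (e[-1L] + e[-length(e)]) / 2
    } else {
      stop("supply `grid` for this basis family")
    }
  }
  B <- eval_basis(b$spec, grid)  # errors if grid outside basis range
  Xg <- B$matrix
  th <- fit$coefficients[b$cols]
  Sg <- fit$vcov[b$cols, b$cols, drop = FALSE]
  lin <- drop(Xg %*% th)
  se <- sqrt(pmax(rowSums((Xg %*% Sg) * Xg), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(grid = grid, estimate = exp(lin), lower = exp(lin - z * se),
         upper = exp(lin + z * se), log_estimate = lin, log_se = se,
         level = level, block = block),
    class = "intensity_curve"
  )
}

#' @export
print.intensity_curve <- function(x, ...) {
  cat(sprintf(
    "<intensity_curve> block '%s', %d grid point(s), %g%% bounds\n",
    x$block, length(x$grid), 100 * x$level))
  invisible(x)
}

#' @export
as.data.frame.intensity_curve <- function(x, ...) {
  data.frame(grid = x$grid, estimate = x$estimate,
             lower = x$lower, upper = x$upper)
}

#' Time-rescaling goodness-of-fit (Kolmogorov-Smirnov)
#'
#' Rescales inter-spike intervals by the fitted cumulative intensity:
#' \eqn{z_k = \sum \mu_t} over the bins between consecutive spikes. Under a
#' correct model the \eqn{z_k} are unit-rate exponential, so
#' \eqn{u_k = 1 - e^{-z_k}} is Uniform(0,1). Returns the KS distance of the
#' \eqn{u_k} from uniformity and the approximate 95% band
#' \eqn{1.36/\sqrt{n}}.
#'
#' @param fit A [fit_ppglm()] result (fitted per-bin intensities available).
#' @param counts Optional count vector; defaults to the training counts.
#' @return List with `statistic`, `band`, `n_isi`, `within_band`, `rescaled`.
#' @export
time_rescaling_ks <- function(fit, counts = NULL) {
  stopifnot(inherits(fit, "ppglm_fit"))
  if (is.null(counts)) counts <- fit$train$counts
  if (is.null(counts)) stop("no counts available")
  spikes <- rep(seq_along(counts), counts)
  if (length(spikes) < 2L) stop("need at least 2 spikes for rescaled ISIs")
  cs <- c(0, cumsum(fit$fitted))
  z <- diff(cs[spikes + 1L])  # integrated intensity between successive spikes
  u <- 1 - exp(-z)
  n <- length(u)
  us <- sort(u)
  d_plus <- max(seq_len(n) / n - us)
  d_minus <- max(us - (seq_len(n) - 1L) / n)
  D <- max(d_plus, d_minus)
  band <- 1.36 / sqrt(n)
  list(statistic = D, band = band, n_isi = n,
       within_band = D < band, rescaled = u)
}
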