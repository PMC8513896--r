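# Independent oracles used across the suite. These never call the code paths
# they check.

# Solve the cubic S(u) = c0 + c1 u + c2 u^2 + c3 u^3 from endpoint conditions
# (values and u-derivatives at u = 0, 1), then return the weight each control
# point receives at u. `cond` maps a unit control vector to the 4 conditions
# (S0, S1, D0, D1).
oracle_cubic_weights <- function(u, n_points, cond) {
  A <- rbind(
    c(1, 0, 0, 0),  # S(0)
    c(1, 1, 1, 1),  # S(1)
    c(0, 1, 0, 0),  # S'(0)
    c(0, 1, 2, 3)   # S'(1)
  )
  vapply(seq_len(n_points), function(k) {
    p <- numeric(n_points)
    p[k] <- 1
    cc <- solve(A, cond(p))
    sum(cc * u^(0:3))
  }, numeric(1))
}

# Oracle weights for each segment kind, from the stated endpoint conditions.
oracle_interior <- function(u, s, l1, l2) {
  oracle_cubic_weights(u, 4L, function(p) {
    c(p[2], p[3], s * l1 * (p[3] - p[1]), s * l2 * (p[4] - p[2]))
  })
}
oracle_first <- function(u, s, lb) {
  oracle_cubic_weights(u, 3L, function(p) {
    c(p[1], p[2], 0, s * lb * (p[3] - p[1]))
  })
}
oracle_last <- function(u, s, le) {
  oracle_cubic_weights(u, 3L, function(p) {
    c(p[2], p[3], s * le * (p[3] - p[1]), 0)
  })
}
oracle_single <- function(u) {
  oracle_cubic_weights(u, 2L, function(p) c(p[1], p[2], 0, 0))
}

# Richardson-extrapolated one-sided finite difference of f at x (step h):
# cancels the O(h) term, leaving O(h^2) error.
fd_onesided <- function(f, x, h, sign = 1) {
  d1 <- (f(x + sign * h) - f(x)) / (sign * h)
  d2 <- (f(x + sign * 2 * h) - f(x)) / (sign * 2 * h)
  2 * d1 - d2
}

# Poisson log-likelihood and gradient for the optimizer oracle.
pois_loglik <- function(theta, X, y, off) {
  eta <- drop(X %*% theta) + off
  sum(y * eta - exp(eta))
}
pois_grad <- function(theta, X, y, off) {
  eta <- drop(X %*% theta) + off
  drop(crossprod(X, y - exp(eta)))
}

# Generic maximizer of the same likelihood (BFGS), independent of the IRLS
# implementation under test.
oracle_poisson_mle <- function(X, y, off, start = NULL) {
  if (is.null(start)) start <- numeric(ncol(X))
  fit <- stats::optim(start, fn = pois_loglik, gr = pois_grad,
                      X = X, y = y, off = off,
                      method = "BFGS",
                      control = list(fnscale = -1, maxit = 1000,
                                     reltol = 1e-14))
  fit$par
}

# Small standard session used by several test files (cheap: 60 s).
tiny_session <- function(seed = 123, duration = 60, ...) {
  simulate_session(sim_config(duration = duration, seed = seed, ...))
}
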