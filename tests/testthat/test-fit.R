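test_that("intercept-only fit recovers the closed-form Poisson MLE", {
  set.seed(21)
  n <- 20000L
  dt <- 0.001
  counts <- rbinom(n, 1, 8 * dt)  # ~8 Hz
  tr <- spike_train(counts, dt)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_ppglm(X, tr)
  m <- sum(counts)
  expect_equal(unname(coef(fit)), log(m / (n * dt)), tolerance = 1e-10)
  expect_true(fit$converged)
  # Fisher information for the intercept is the total expected count
  expect_equal(unname(fit$fisher[1, 1]), m, tolerance = 1e-6)
})

test_that("IRLS agrees with a generic likelihood maximizer", {
  s <- tiny_session(seed = 31, duration = 60)
  fs <- fit_session(s, "modified")
  fit <- fs$fit
  X <- fit$design$X
  y <- s$train$counts
  off <- log(s$train$bin_width)
  theta_oracle <- oracle_poisson_mle(X, y, rep(off, length(y)),
                                     start = coef(fit) * 0)
  expect_equal(unname(coef(fit)), unname(theta_oracle), tolerance = 1e-5)
  # concavity: refit from a random start lands on the same optimum
  set.seed(99)
  fit2 <- fit_ppglm(fit$design, s$train, init = rnorm(ncol(X), 0, 0.3))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
  # log-likelihood is no worse than at the zero start
  ll0 <- pois_loglik(numeric(ncol(X)), X, y, off) - sum(lgamma(y + 1))
  expect_gte(fit$loglik, ll0)
})

test_that("Sigma inverts the observed Fisher information", {
  s <- tiny_session(seed = 32, duration = 30)
  fit <- fit_session(s, "modified")$fit
  p <- length(coef(fit))
  expect_equal(unname(fit$vcov %*% fit$fisher), diag(p), tolerance = 1e-8)
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * p)
})

test_that("offset convention makes per-second intensity bin-size invariant", {
  s <- tiny_session(seed = 33, duration = 120)
  g <- sim_config(seed = 1)$spatial_knots
  grid_sp <- knot_grid(g)
  fit1 <- fit_ppglm(assemble_design(spatial_block(s$position, grid_sp,
                                                  clamp = TRUE)), s$train)
  # rebin at 2 ms
  tr2 <- bin_spikes(s$spike_times, 0, s$config$duration, 0.002)
  pos2 <- resample_position(s$trace$times, s$position, tr2)
  fit2 <- fit_ppglm(assemble_design(spatial_block(pos2, grid_sp,
                                                  clamp = TRUE)), tr2)
  # same per-second scale: compare field profiles at the knots
  expect_equal(coef(fit1), coef(fit2), tolerance = 0.1)
})

test_that("param_ci: Wald intervals, zero-variance, separated columns", {
  s <- tiny_session(seed = 34, duration = 30)
  fit <- fit_session(s, "modified")$fit
  ci <- param_ci(fit, level = 0.95)
  z <- qnorm(0.975)
  expect_equal(ci$lower, ci$estimate - z * ci$se)
  expect_equal(ci$rate_upper, exp(ci$upper))
  # hand-constructed fit: theta = 0, Sigma = I -> (-1.96, 1.96)
  fake <- fit
  fake$coefficients[] <- 0
  fake$vcov <- diag(length(coef(fit)))
  fake$separated[] <- FALSE
  ci0 <- param_ci(fake)
  expect_equal(ci0$lower, rep(-z, nrow(ci0)))
  expect_equal(ci0$upper, rep(z, nrow(ci0)))
  fake$vcov <- diag(0, length(coef(fit)))
  ci1 <- param_ci(fake)
  expect_equal(ci1$lower, ci1$estimate)  # zero-width at Sigma_ii = 0
  fake$separated[2] <- TRUE
  expect_equal(param_ci(fake)$upper[2], Inf)
})

test_that("intensity curve: one-hot rows, covariance use, MC delta oracle", {
  s <- tiny_session(seed = 35, duration = 60)
  fit <- fit_session(s, "modified")$fit
  hcols <- fit$design$blocks$history$cols
  knots <- s$config$history_knots
  cv <- intensity_curve(fit, "history", grid = knots)
  # at a knot the row is one-hot: estimate exp(theta_k), width from Sigma_kk
  th <- coef(fit)[hcols]
  Sg <- fit$vcov[hcols, hcols]
  z <- qnorm(0.975)
  expect_equal(cv$estimate, unname(exp(th)), tolerance = 1e-10)
  expect_equal(cv$upper, unname(exp(th + z * sqrt(diag(Sg)))),
               tolerance = 1e-10)
  expect_true(all(cv$lower <= cv$estimate & cv$estimate <= cv$upper))
  # between knots the delta-method SE matches Monte-Carlo sampling of theta
  grid <- c(5, 25, 70, 150)
  cv2 <- intensity_curve(fit, "history", grid = grid)
  set.seed(77)
  R <- chol(Sg)
  draws <- matrix(rnorm(1e5 * length(th)), ncol = length(th)) %*% R
  draws <- sweep(draws, 2, th, "+")
  Xg <- spline_basis(grid, knot_grid(knots))$matrix
  mc_sd <- apply(draws %*% t(Xg), 2, sd)
  expect_equal(cv2$log_se, mc_sd, tolerance = 0.02)
  # all-zero covariance -> upper = lower = estimate
  fake <- fit
  fake$vcov[] <- 0
  cv3 <- intensity_curve(fake, "history", grid = grid)
  expect_equal(cv3$lower, cv3$estimate)
  expect_equal(cv3$upper, cv3$estimate)
  expect_error(intensity_curve(fit, "history", grid = c(250)), "outside")
  expect_error(intensity_curve(fit, "nope"), "no block")
})

test_that("separation is detected column-wise and handled, not fatal", {
  set.seed(36)
  n <- 5000L
  pos <- runif(n, 0, 100)
  counts <- integer(n)
  # spikes only where position < 50: columns supported above 50 are separated
  eligible <- pos < 50
  counts[eligible] <- rbinom(sum(eligible), 1, 0.05)
  tr <- spike_train(counts, 0.001)
  spec <- partition_spec(seq(0, 100, by = 25))
  d <- assemble_design(spatial_block(pos, spec))
  fit <- suppressWarnings(fit_ppglm(d, tr))
  expect_equal(unname(fit$separated), c(FALSE, FALSE, TRUE, TRUE))
  ci <- param_ci(fit)
  expect_true(all(is.infinite(ci$upper[3:4])))
  expect_true(all(is.finite(ci$upper[1:2])))
  # all columns flagged when there are no spikes at all
  flags <- detect_separation(d$X, integer(n))
  expect_true(all(flags))
})

test_that("time-rescaling KS behaves for matched and mismatched models", {
  set.seed(37)
  n <- 60000L
  dt <- 0.001
  rate <- 12
  counts <- as.integer(runif(n) < 1 - exp(-rate * dt))
  tr <- spike_train(counts, dt)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_ppglm(X, tr)
  ks <- time_rescaling_ks(fit)
  expect_true(ks$within_band)
  expect_equal(ks$n_isi, sum(counts) - 1L)
  # deliberate 5x mis-specification over a sub-interval is flagged
  bad <- fit
  bad$fitted <- fit$fitted
  bad$fitted[1:20000] <- bad$fitted[1:20000] / 5
  ks_bad <- time_rescaling_ks(bad)
  expect_false(ks_bad$within_band)
  suppressWarnings(fit0 <- fit_ppglm(X, spike_train(integer(n), dt)))
  expect_error(time_rescaling_ks(fit0), "2 spikes")
})
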