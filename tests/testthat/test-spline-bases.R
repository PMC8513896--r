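test_that("Hermite components match closed form at reference points", {
  expect_equal(drop(hermite_components(0)), c(h00 = 1, h10 = 0, h01 = 0, h11 = 0))
  expect_equal(drop(hermite_components(1)), c(h00 = 0, h10 = 0, h01 = 1, h11 = 0))
  expect_equal(drop(hermite_components(0.5)),
               c(h00 = 0.5, h10 = 0.125, h01 = 0.5, h11 = -0.125))
  expect_error(hermite_components(1.01), "\\[0, 1\\]")
  expect_error(hermite_components(NA_real_), "finite")
})

test_that("segment weights match frozen hand-evaluated examples", {
  expect_equal(unname(drop(interior_weights(0, 0.7, 1.3, 2.9))),
               c(0, 1, 0, 0))
  expect_equal(unname(drop(interior_weights(0.5, 0.5, 2, 2))),
               c(-0.125, 0.625, 0.625, -0.125))
  expect_equal(unname(drop(boundary_weights_first(0, 0.5, 2))), c(1, 0, 0))
  expect_equal(unname(drop(boundary_weights_first(1, 0.5, 2))), c(0, 1, 0))
  expect_equal(unname(drop(boundary_weights_first(0.5, 0.5, 2))),
               c(0.625, 0.5, -0.125))
  expect_equal(unname(drop(boundary_weights_last(1, 0.5, 2))), c(0, 0, 1))
  expect_equal(unname(drop(boundary_weights_last(0, 0.5, 2))), c(0, 1, 0))
  expect_equal(unname(drop(boundary_weights_last(0.5, 0.5, 2))),
               c(-0.125, 0.5, 0.625))
  expect_equal(unname(drop(single_segment_weights(0))), c(1, 0))
  expect_equal(unname(drop(single_segment_weights(0.5))), c(0.5, 0.5))
  expect_equal(unname(drop(single_segment_weights(1))), c(0, 1))
  expect_error(interior_weights(0.5, Inf, 2, 2), "finite")
})

test_that("closed-form weights equal the endpoint-condition linear solve", {
  set.seed(41)
  for (i in 1:50) {
    u <- runif(1)
    s <- runif(1, 0.1, 2)
    l1 <- runif(1, 1.1, 4); l2 <- runif(1, 1.1, 4)
    expect_equal(unname(drop(interior_weights(u, s, l1, l2))),
                 oracle_interior(u, s, l1, l2), tolerance = 1e-12)
    expect_equal(unname(drop(boundary_weights_first(u, s, l1))),
                 oracle_first(u, s, l1), tolerance = 1e-12)
    expect_equal(unname(drop(boundary_weights_last(u, s, l1))),
                 oracle_last(u, s, l1), tolerance = 1e-12)
    expect_equal(unname(drop(single_segment_weights(u))),
                 oracle_single(u), tolerance = 1e-12)
  }
})

test_that("knot_grid validates and auto-places ghost knots", {
  g <- knot_grid(c(1, 10, 40, 100, 200), variant = "cardinal")
  expect_equal(g$locations, c(-8, 1, 10, 40, 100, 200, 300))
  expect_equal(g$user_knots, c(1, 10, 40, 100, 200))
  g2 <- knot_grid(c(0, 10), variant = "cardinal", ghosts = c(-5, 15))
  expect_equal(g2$locations, c(-5, 0, 10, 15))
  expect_error(knot_grid(c(1, 1, 2)), "strictly increasing")
  expect_error(knot_grid(c(1, 2), tension = 0), "positive")
  expect_error(knot_grid(1), "at least 2")
  expect_error(knot_grid(c(1, 10), variant = "cardinal", ghosts = c(2, 20)),
               "outside")
})

test_that("same knots give n columns modified, n + 2 cardinal", {
  knots <- c(1, 10, 40, 100, 200)
  Bm <- spline_basis(seq(1, 200, by = 1), knot_grid(knots))
  Bc <- spline_basis(seq(1, 200, by = 1),
                     knot_grid(knots, variant = "cardinal"))
  expect_identical(ncol(Bm$matrix), 5L)
  expect_identical(ncol(Bc$matrix), 7L)
})

test_that("partition of unity holds for all variants over random grids", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(2:9, 1)
    knots <- sort(runif(n, -10, 10))
    while (min(diff(knots)) < 1e-3) knots <- sort(runif(n, -10, 10))
    s <- runif(1, 0.05, 3)
    gm <- knot_grid(knots, tension = s)
    vals <- runif(25, knots[1], knots[n])
    expect_equal(rowSums(spline_basis(vals, gm)$matrix), rep(1, 25),
                 tolerance = 1e-12)
    if (n >= 2) {
      gc <- knot_grid(knots, tension = s, variant = "cardinal")
      r <- knot_range(gc <- gc)
      vals_c <- runif(25, r[1], r[2])
      expect_equal(rowSums(spline_basis(vals_c, gc)$matrix), rep(1, 25),
                   tolerance = 1e-12)
    }
  }
})

test_that("spline interpolates: one-hot rows at knots", {
  knots <- c(0, 3, 7.5, 20, 31)
  gm <- knot_grid(knots, tension = 0.8)
  B <- spline_basis(knots, gm)$matrix
  expect_equal(unname(B), diag(5), tolerance = 1e-12)
  # cardinal variant: interior (user) knots are one-hot in their columns
  gc <- knot_grid(knots, tension = 0.8, variant = "cardinal")
  Bc <- spline_basis(knots, gc)$matrix
  expect_equal(unname(Bc), cbind(0, diag(5), 0), tolerance = 1e-12)
})

test_that("C0/C1 continuity at interior knots (uniform spacing)", {
  # The printed per-segment spacing-ratio convention is C1 only for equal
  # adjacent spacings; see the methods vignette. The left-limit at a shared
  # knot is recovered exactly by fitting the left segment's cubic through
  # four of its evaluated points (the basis is piecewise cubic by
  # construction), then evaluating value and slope at the knot.
  left_limit <- function(f, xl, xr) {
    u <- c(0.15, 0.35, 0.6, 0.85)
    V <- outer(u, 0:3, "^")
    cc <- solve(V, vapply(xl + u * (xr - xl), f, numeric(1)))
    c(value = sum(cc), slope = sum(cc[2:4] * (1:3)) / (xr - xl))
  }
  set.seed(11)
  for (i in 1:20) {
    d <- runif(1, 0.5, 20)
    x0 <- runif(1, -5, 5)
    n <- sample(4:8, 1)
    knots <- x0 + d * (0:(n - 1))
    s <- runif(1, 0.1, 2)
    for (variant in c("modified", "cardinal")) {
      g <- knot_grid(knots, tension = s, variant = variant)
      r <- knot_range(g)
      interior <- knots[knots > r[1] & knots < r[2]]
      p <- rnorm(length(g$locations))
      f <- function(x) drop(spline_basis(x, g)$matrix %*% p)
      for (xk in interior) {
        lim <- left_limit(f, xk - d, xk)
        expect_equal(unname(lim["value"]), f(xk),
                     tolerance = 1e-10)
        dr <- drop(spikespline:::spline_basis_deriv(xk, g)$matrix %*% p)
        expect_equal(unname(lim["slope"]), dr,
                     tolerance = 1e-10 * max(1, abs(dr)))
      }
    }
  }
})

test_that("modified variant has flat derivative at both boundary knots", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:7, 1)
    knots <- sort(runif(n, 0, 50))
    while (min(diff(knots)) < 0.5) knots <- sort(runif(n, 0, 50))
    g <- knot_grid(knots, tension = runif(1, 0.1, 2))
    p <- rnorm(n)
    f <- function(x) drop(spline_basis(x, g)$matrix %*% p)
    sp <- min(diff(knots))
    h <- 1e-6 * sp
    scale <- max(abs(p)) / sp
    expect_lt(abs(fd_onesided(f, knots[1], h, sign = 1)), 1e-8 * scale)
    expect_lt(abs(fd_onesided(f, knots[n], h, sign = -1)), 1e-8 * scale)
    # analytic derivative is exactly zero
    expect_equal(
      drop(spikespline:::spline_basis_deriv(c(knots[1], knots[n]), g)$matrix %*% p),
      c(0, 0))
  }
})

test_that("out-of-range values error by default and clamp on request", {
  g <- knot_grid(c(0, 10, 20))
  expect_error(spline_basis(c(5, 21), g), "21.*\\[0, 20\\]")
  expect_message(B <- spline_basis(c(-1, 5, 25), g, clamp = TRUE),
                 "clamped 2")
  expect_equal(unname(B$matrix[1, 1]), 1)
  expect_equal(unname(B$matrix[3, 3]), 1)
  # cardinal variant excludes ghost segments from the evaluable range
  gc <- knot_grid(c(0, 10, 20), variant = "cardinal")
  expect_error(spline_basis(-5, gc), "outside evaluable range")
})

test_that("two-knot grid reproduces the single-segment solution", {
  g <- knot_grid(c(2, 6))
  B <- spline_basis(c(2, 4, 6), g)$matrix
  expect_equal(unname(B), rbind(c(1, 0), c(0.5, 0.5), c(0, 1)),
               tolerance = 1e-12)
})
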