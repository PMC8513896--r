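#' Cubic Hermite polynomial components
#'
#' Evaluates the four cubic Hermite blending polynomials
#' \eqn{h_{00}(u) = 2u^3 - 3u^2 + 1}, \eqn{h_{10}(u) = u^3 - 2u^2 + u},
#' \eqn{h_{01}(u) = -2u^3 + 3u^2}, \eqn{h_{11}(u) = u^3 - u^2} that express a
#' cubic segment in terms of its endpoint values and endpoint derivatives
#' (in local-coordinate units).
#'
#' @param u Numeric vector of local coordinates, each in \[0, 1\].
#' @return A numeric matrix with `length(u)` rows and columns
#'   `h00`, `h10`, `h01`, `h11`.
#' @examples
#' hermite_components(c(0, 0.5, 1))
#' @export
hermite_components <- function(u) {
  if (!is.numeric(u) || anyNA(u) || any(!is.finite(u))) {
    stop("`u` must be finite numeric")
  }
  if (any(u < 0 | u > 1)) {
    stop("`u` must lie in [0, 1]; got value outside range")
  }
  u2 <- u * u
  u3 <- u2 * u
  cbind(
    h00 = 2 * u3 - 3 * u2 + 1,
    h10 = u3 - 2 * u2 + u,
    h01 = -2 * u3 + 3 * u2,
    h11 = u3 - u2
  )
}

# du-derivatives of the Hermite components (used for analytic slope checks)
hermite_components_deriv <- function(u) {
  u2 <- u * u
  cbind(
    h00 = 6 * u2 - 6 * u,
    h10 = 3 * u2 - 4 * u + 1,
    h01 = -6 * u2 + 6 * u,
    h11 = 3 * u2 - 2 * u
  )
}

#' Interior cardinal-spline segment weights
#'
#' Weights attached to the four nearest control points
#' \eqn{(p_{i-1}, p_i, p_{i+1}, p_{i+2})} for a point with local coordinate
#' `u` on the segment \eqn{[x_i, x_{i+1}]}. The segment interpolates
#' \eqn{S(0) = p_i}, \eqn{S(1) = p_{i+1}} with endpoint derivatives (in `u`
#' units) \eqn{S'(0) = s\,l_1 (p_{i+1} - p_{i-1})} and
#' \eqn{S'(1) = s\,l_2 (p_{i+2} - p_i)}, where `s` is the tension parameter
#' and `l1`, `l2` are spacing ratios (both equal 2 on a uniform knot grid).
#'
#' @param u Numeric vector in \[0, 1\].
#' @param s Tension parameter (scalar, > 0).
#' @param l1,l2 Spacing ratios: span of the two knots bracketing the segment's
#'   left (resp. right) derivative stencil divided by the segment width.
#' @return Matrix with `length(u)` rows and 4 columns; each row sums to 1.
#' @export
interior_weights <- function(u, s, l1, l2) {
  if (!all(is.finite(c(s, l1, l2)))) stop("`s`, `l1`, `l2` must be finite")
  h <- hermite_components(u)
  w <- cbind(
    -s * l1 * h[, "h10"],
    h[, "h00"] - s * l2 * h[, "h11"],
    h[, "h01"] + s * l1 * h[, "h10"],
    s * l2 * h[, "h11"]
  )
  colnames(w) <- c("p[i-1]", "p[i]", "p[i+1]", "p[i+2]")
  w
}

interior_weights_deriv <- function(u, s, l1, l2) {
  h <- hermite_components_deriv(u)
  cbind(
    -s * l1 * h[, "h10"],
    h[, "h00"] - s * l2 * h[, "h11"],
    h[, "h01"] + s * l1 * h[, "h10"],
    s * l2 * h[, "h11"]
  )
}

#' Modified-spline boundary segment weights (first segment)
#'
#' Weights on \eqn{(p_1, p_2, p_3)} for the initial segment of the modified
#' cardinal spline, which imposes a flat derivative at the first knot:
#' \eqn{S(0) = p_1}, \eqn{S(1) = p_2}, \eqn{S'(0) = 0},
#' \eqn{S'(1) = s\,l_b (p_3 - p_1)}.
#'
#' @param u Numeric vector in \[0, 1\].
#' @param s Tension parameter.
#' @param lb Spacing ratio \eqn{(x_3 - x_1)/(x_2 - x_1)}.
#' @return Matrix with 3 columns; rows sum to 1.
#' @export
boundary_weights_first <- function(u, s, lb) {
  if (!all(is.finite(c(s, lb)))) stop("`s`, `lb` must be finite")
  u <- hermite_check(u)
  u2 <- u * u
  u3 <- u2 * u
  w <- cbind(
    (2 - s * lb) * u3 + (s * lb - 3) * u2 + 1,
    -2 * u3 + 3 * u2,
    s * lb * (u3 - u2)
  )
  colnames(w) <- c("p1", "p2", "p3")
  w
}

boundary_weights_first_deriv <- function(u, s, lb) {
  u2 <- u * u
  cbind(
    3 * (2 - s * lb) * u2 + 2 * (s * lb - 3) * u,
    -6 * u2 + 6 * u,
    s * lb * (3 * u2 - 2 * u)
  )
}

#' Modified-spline boundary segment weights (last segment)
#'
#' Weights on \eqn{(p_{n-2}, p_{n-1}, p_n)} for the final segment of the
#' modified cardinal spline, which imposes a flat derivative at the last knot:
#' \eqn{S(0) = p_{n-1}}, \eqn{S(1) = p_n},
#' \eqn{S'(0) = s\,l_e (p_n - p_{n-2})}, \eqn{S'(1) = 0}.
#'
#' @param u Numeric vector in \[0, 1\].
#' @param s Tension parameter.
#' @param le Spacing ratio \eqn{(x_n - x_{n-2})/(x_n - x_{n-1})}.
#' @return Matrix with 3 columns; rows sum to 1.
#' @export
boundary_weights_last <- function(u, s, le) {
  if (!all(is.finite(c(s, le)))) stop("`s`, `le` must be finite")
  u <- hermite_check(u)
  u2 <- u * u
  u3 <- u2 * u
  w <- cbind(
    -s * le * (u3 - 2 * u2 + u),
    2 * u3 - 3 * u2 + 1,
    (s * le - 2) * u3 + (3 - 2 * s * le) * u2 + s * le * u
  )
  colnames(w) <- c("p[n-2]", "p[n-1]", "p[n]")
  w
}

boundary_weights_last_deriv <- function(u, s, le) {
  u2 <- u * u
  cbind(
    -s * le * (3 * u2 - 4 * u + 1),
    6 * u2 - 6 * u,
    3 * (s * le - 2) * u2 + 2 * (3 - 2 * s * le) * u + s * le
  )
}

#' Two-knot modified-spline segment weights
#'
#' The degenerate modified spline with exactly two control points: a single
#' cubic segment with zero derivative at both ends, i.e.
#' \eqn{S(u) = (2u^3 - 3u^2 + 1) p_1 + (-2u^3 + 3u^2) p_2}.
#'
#' @param u Numeric vector in \[0, 1\].
#' @return Matrix with 2 columns; rows sum to 1.
#' @export
single_segment_weights <- function(u) {
  u <- hermite_check(u)
  u2 <- u * u
  u3 <- u2 * u
  w <- cbind(2 * u3 - 3 * u2 + 1, -2 * u3 + 3 * u2)
  colnames(w) <- c("p1", "p2")
  w
}

hermite_check <- function(u) {
  if (!is.numeric(u) || anyNA(u) || any(!is.finite(u))) {
    stop("`u` must be finite numeric")
  }
  if (any(u < 0 | u > 1)) stop("`u` must lie in [0, 1]")
  u
}

#' Construct a spline knot grid
#'
#' Defines the control-point locations and tension for a cardinal or modified
#' cardinal spline basis. For `variant = "cardinal"` the standard construction
#' requires two extra "ghost" knots beyond the covariate range, used only to
#' set the boundary derivatives; if not supplied they are placed one adjacent
#' knot spacing beyond the first and last user knots. For
#' `variant = "modified"` no ghost knots exist: the derivative is assumed flat
#' at the first and last knot, so the basis has two fewer dimensions for the
#' same interior knots.
#'
#' @param locations Strictly increasing numeric vector of knot locations, in
#'   covariate units (cm for position, ms for spike-history lag).
#' @param tension Tension parameter `s` (> 0); default 0.5.
#' @param variant `"modified"` (flat boundary derivative) or `"cardinal"`.
#' @param ghosts For `variant = "cardinal"`, optional length-2 numeric vector
#'   `c(lower, upper)` of ghost-knot locations; defaults to
#'   `c(x1 - (x2 - x1), xn + (xn - x[n-1]))`.
#' @return An object of class `knot_grid` with elements `locations` (all
#'   knots, including ghosts for the cardinal variant), `tension`, `variant`,
#'   and `user_knots`.
#' @examples
#' knot_grid(c(1, 10, 40, 100, 200))                      # 5 basis functions
#' knot_grid(c(1, 10, 40, 100, 200), variant = "cardinal") # 7 (2 ghosts)
#' @export
knot_grid <- function(locations, tension = 0.5,
                      variant = c("modified", "cardinal"), ghosts = NULL) {
  variant <- match.arg(variant)
  locations <- as.numeric(locations)
  if (anyNA(locations) || any(!is.finite(locations))) {
    stop("knot locations must be finite")
  }
  if (is.unsorted(locations, strictly = TRUE)) {
    stop("knot locations must be strictly increasing")
  }
  if (!is.numeric(tension) || length(tension) != 1L || tension <= 0) {
    stop("`tension` must be a positive scalar")
  }
  user <- locations
  if (variant == "modified") {
    if (length(locations) < 2L) stop("modified variant needs at least 2 knots")
    if (!is.null(ghosts)) stop("ghost knots apply only to variant = 'cardinal'")
  } else {
    if (length(user) < 2L) stop("cardinal variant needs at least 2 user knots")
    if (is.null(ghosts)) {
      n <- length(user)
      ghosts <- c(user[1L] - (user[2L] - user[1L]),
                  user[n] + (user[n] - user[n - 1L]))
    }
    if (length(ghosts) != 2L || ghosts[1L] >= user[1L] ||
        ghosts[2L] <= user[length(user)]) {
      stop("`ghosts` must be c(lower, upper) strictly outside the user knots")
    }
    locations <- c(ghosts[1L], user, ghosts[2L])
    if (length(locations) < 4L) stop("cardinal variant needs >= 4 knots total")
  }
  structure(
    list(locations = locations, tension = tension, variant = variant,
         user_knots = user),
    class = "knot_grid"
  )
}

#' @export
print.knot_grid <- function(x, ...) {
  cat(sprintf("<knot_grid> %s, s = %g, %d basis function(s)\n",
              x$variant, x$tension, length(x$locations)))
  cat("  knots:", paste(signif(x$locations, 6), collapse = ", "), "\n")
  invisible(x)
}

# Evaluable covariate range for a knot grid: the modified variant covers the
# full knot span; the cardinal variant excludes the ghost segments.
knot_range <- function(grid) {
  x <- grid$locations
  n <- length(x)
  if (grid$variant == "modified") c(x[1L], x[n]) else c(x[2L], x[n - 1L])
}

# Segment index for each value: half-open [x_i, x_{i+1}), maximum value
# assigned to the last evaluable segment.
segment_index <- function(values, grid) {
  x <- grid$locations
  n <- length(x)
  idx <- findInterval(values, x)
  if (grid$variant == "modified") {
    idx[idx >= n] <- n - 1L
  } else {
    idx[idx >= n - 1L] <- n - 2L
  }
  idx
}

#' Evaluate a spline basis matrix
#'
#' Builds the samples-by-control-points weight matrix for a cardinal or
#' modified cardinal spline: row `t` holds the weights such that the spline
#' value at `values[t]` is the row's inner product with the control-point
#' parameter vector. Rows sum to 1 (partition of unity), and a row evaluated
#' exactly at an interior knot is one-hot for that knot's column.
#'
#' Segment membership is half-open (`[x_i, x_{i+1})`), with the maximum of the
#' evaluable range assigned to the final segment. For the cardinal variant the
#' evaluable range excludes the ghost segments.
#'
#' @param values Numeric vector of covariate values.
#' @param grid A [knot_grid()].
#' @param clamp If `TRUE`, out-of-range values are mapped to the nearest end
#'   of the evaluable range (a message reports how many); if `FALSE`
#'   (default), out-of-range values are an error.
#' @return An object of class `basis_matrix`: list with `matrix` (rows =
#'   evaluation points, columns = control points, labelled by knot location),
#'   `values`, and `spec` (the grid).
#' @export
spline_basis <- function(values, grid, clamp = FALSE) {
  stopifnot(inherits(grid, "knot_grid"))
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) stop("`values` must be finite")
  rng <- knot_range(grid)
  out <- values < rng[1L] | values > rng[2L]
  if (any(out)) {
    if (clamp) {
      message(sprintf("spline_basis: clamped %d value(s) to [%g, %g]",
                      sum(out), rng[1L], rng[2L]))
      values <- pmin(pmax(values, rng[1L]), rng[2L])
    } else {
      bad <- values[out][1L]
      stop(sprintf(
        "value %g outside evaluable range [%g, %g] (use clamp = TRUE to clamp)",
        bad, rng[1L], rng[2L]))
    }
  }
  basis_from_segments(values, grid, deriv = FALSE)
}

# Shared evaluation engine for basis values and (analytic) x-derivatives.
basis_from_segments <- function(values, grid, deriv = FALSE) {
  x <- grid$locations
  n <- length(x)
  s <- grid$tension
  idx <- segment_index(values, grid)
  M <- matrix(0, nrow = length(values), ncol = n)
  colnames(M) <- paste0("k", signif(x, 8))

  for (i in sort(unique(idx))) {
    rows <- which(idx == i)
    h <- x[i + 1L] - x[i]
    u <- (values[rows] - x[i]) / h
    two_knot <- grid$variant == "modified" && n == 2L
    if (two_knot) {
      w <- if (deriv) {
        u2 <- u * u
        cbind(6 * u2 - 6 * u, -6 * u2 + 6 * u)
      } else {
        single_segment_weights(u)
      }
      cols <- c(1L, 2L)
    } else if (grid$variant == "modified" && i == 1L) {
      lb <- (x[3L] - x[1L]) / (x[2L] - x[1L])
      w <- if (deriv) boundary_weights_first_deriv(u, s, lb)
           else boundary_weights_first(u, s, lb)
      cols <- 1:3
    } else if (grid$variant == "modified" && i == n - 1L) {
      le <- (x[n] - x[n - 2L]) / (x[n] - x[n - 1L])
      w <- if (deriv) boundary_weights_last_deriv(u, s, le)
           else boundary_weights_last(u, s, le)
      cols <- (n - 2L):n
    } else {
      l1 <- (x[i + 1L] - x[i - 1L]) / h
      l2 <- (x[i + 2L] - x[i]) / h
      w <- if (deriv) interior_weights_deriv(u, s, l1, l2)
           else interior_weights(u, s, l1, l2)
      cols <- (i - 1L):(i + 2L)
    }
    if (deriv) w <- w / h  # du -> dx
    M[rows, cols] <- w
  }
  structure(
    list(matrix = M, values = values, spec = grid),
    class = "basis_matrix"
  )
}

# Analytic x-derivative of the spline basis (one-sided at shared knots,
# following the same half-open segment convention as spline_basis).
spline_basis_deriv <- function(values, grid) {
  stopifnot(inherits(grid, "knot_grid"))
  rng <- knot_range(grid)
  if (any(values < rng[1L] | values > rng[2L])) {
    stop("values outside evaluable range")
  }
  basis_from_segments(values, grid, deriv = TRUE)
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("<basis_matrix> %d evaluation point(s) x %d basis function(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.basis_matrix <- function(x) dim(x$matrix)

#' Evaluate a basis specification on covariate values
#'
#' Generic dispatcher turning a basis specification ([knot_grid()],
#' [raised_cosine_spec()], or [partition_spec()]) plus covariate values into a
#' `basis_matrix`.
#'
#' @param spec A basis specification object.
#' @param values Numeric covariate values.
#' @param ... Passed to the specific method (e.g. `clamp` for splines).
#' @return A `basis_matrix`.
#' @export
eval_basis <- function(spec, values, ...) UseMethod("eval_basis")

#' @export
eval_basis.knot_grid <- function(spec, values, ...) {
  spline_basis(values, spec, ...)
}
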