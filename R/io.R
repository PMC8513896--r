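#' Read spike times from delimited text
#'
#' Expects a comma-separated file with a header row and a single column of
#' spike times in seconds (column name free; first column used). Malformed
#' rows are reported with their line number.
#'
#' @param path File path.
#' @return Numeric vector of spike times (seconds), sorted.
#' @export
read_spike_times <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 1L || nrow(df) == 0L) stop("spike file has no data rows")
  raw <- df[[1L]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("spike file %s: non-numeric value '%s' at line %d",
                 path, raw[bad], bad + 1L))  # +1 for the header row
  }
  sort(vals)
}

#' Read a position trace from delimited text
#'
#' Expects a comma-separated file with a header row and two columns:
#' time (s) and linearized position (cm).
#'
#' @param path File path.
#' @return Data frame with columns `time_s`, `position_cm`.
#' @export
read_position <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    stop("position file needs two columns (time_s, position_cm)")
  }
  t <- suppressWarnings(as.numeric(df[[1L]]))
  p <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(t) || anyNA(p)) {
    bad <- which(is.na(t) | is.na(p))[1L]
    stop(sprintf("position file %s: non-numeric value at line %d",
                 path, bad + 1L))
  }
  data.frame(time_s = t, position_cm = p)
}

#' Write a simulated session to delimited text files
#'
#' Writes `spikes.csv` (single column `time_s`), `position.csv`
#' (`time_s, position_cm`) and `truth.json` (ground-truth configuration,
#' spatial control values and history kernel) into `dir`. The text files are
#' in the exact formats [read_spike_times()] and [read_position()] consume.
#'
#' @param session A [simulate_session()] result.
#' @param dir Output directory (created if needed).
#' @param position_every Write every k-th position sample (default 33,
#'   ~30 Hz from 1 ms bins, emulating a tracking camera).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir, position_every = 33L) {
  stopifnot(inherits(session, "sim_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spike_path <- file.path(dir, "spikes.csv")
  pos_path <- file.path(dir, "position.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(data.frame(time_s = session$spike_times), spike_path,
                   row.names = FALSE)
  keep <- seq(1L, length(session$trace$times), by = position_every)
  utils::write.csv(
    data.frame(time_s = session$trace$times[keep],
               position_cm = session$position[keep]),
    pos_path, row.names = FALSE)
  truth <- list(
    config = unclass(session$config),
    spatial_theta = session$spatial_theta,
    history_kernel = session$history_kernel
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(spikes = spike_path, position = pos_path, truth = truth_path))
}

#' Export a fitted model to JSON
#'
#' Serializes coefficients, covariance, labels, block structure, convergence
#' metadata and separation flags. Round-trips through [read_model_json()].
#'
#' @param fit A [fit_ppglm()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "ppglm_fit"))
  blocks <- lapply(fit$design$blocks, function(b) {
    list(cols = b$cols, lag_ms = b$lag_ms, spec = serialize_spec(b$spec))
  })
  obj <- list(
    package = "spikespline",
    coefficients = as.list(fit$coefficients),
    vcov = unname(apply(fit$vcov, 1L, as.list)),
    labels = names(fit$coefficients),
    loglik = fit$loglik, deviance = fit$deviance, aic = fit$aic,
    iterations = fit$iterations, converged = fit$converged,
    separated = as.list(fit$separated),
    bin_width = if (!is.null(fit$train)) fit$train$bin_width else NULL,
    blocks = blocks
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

serialize_spec <- function(spec) {
  if (inherits(spec, "knot_grid")) {
    list(type = "knot_grid", locations = spec$user_knots,
         tension = spec$tension, variant = spec$variant)
  } else if (inherits(spec, "raised_cosine_spec")) {
    list(type = "raised_cosine", a = spec$a, log_offset = spec$log_offset,
         phis = spec$phis)
  } else if (inherits(spec, "partition_spec")) {
    list(type = "partition", edges = spec$edges)
  } else {
    list(type = "unknown")
  }
}

deserialize_spec <- function(s) {
  switch(s$type,
    knot_grid = knot_grid(unlist(s$locations), s$tension, s$variant),
    raised_cosine = raised_cosine_spec(a = s$a, log_offset = s$log_offset,
                                       phis = unlist(s$phis)),
    partition = partition_spec(unlist(s$edges)),
    stop("unknown basis spec type in model JSON")
  )
}

#' Read a model JSON written by [write_model_json()]
#'
#' Reconstructs a light-weight `ppglm_fit`-like object: coefficients,
#' covariance, block specs, convergence metadata. Per-bin fitted values are
#' not stored, so goodness-of-fit requires refitting against data; intensity
#' curves and CIWR work directly.
#'
#' @param path JSON path.
#' @return An object of class `ppglm_fit` (without `fitted`/`train`).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  labels <- unlist(obj$labels)
  theta <- stats::setNames(unlist(obj$coefficients), labels)
  V <- do.call(rbind, lapply(obj$vcov, unlist))
  dimnames(V) <- list(labels, labels)
  blocks <- lapply(obj$blocks, function(b) {
    list(spec = deserialize_spec(b$spec), cols = unlist(b$cols),
         lag_ms = if (is.null(b$lag_ms)) NULL else unlist(b$lag_ms))
  })
  structure(
    list(coefficients = theta, fisher = NULL, vcov = V,
         loglik = obj$loglik, deviance = obj$deviance, aic = obj$aic,
         iterations = obj$iterations, converged = obj$converged,
         separated = stats::setNames(unlist(obj$separated), labels),
         fitted = NULL,
         design = structure(list(X = NULL, blocks = blocks,
                                 intercept = FALSE),
                            class = "ppglm_design"),
         train = NULL, offset = NULL),
    class = "ppglm_fit"
  )
}

#' Export an intensity curve as delimited text
#'
#' @param curve An [intensity_curve()].
#' @param path Output path (CSV with columns grid, estimate, lower, upper).
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
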