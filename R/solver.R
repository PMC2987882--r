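#' ODE solver settings
#'
#' Tolerances for the adaptive integrator used throughout the package
#' (deSolve's `lsoda`). Densities computed by the method of characteristics
#' are exact up to the accuracy of the ODE solver, so these tolerances are the
#' only approximation knob of the core method. The defaults are deliberately
#' tight; loosen them for quick exploration of expensive grids.
#'
#' @param rel_tol,abs_tol Positive relative and absolute tolerances.
#' @param max_step Optional maximum step size passed to the integrator.
#' @param chunk_size Number of independent characteristics stacked into one
#'   integrator call in batch operations; a performance knob only, results do
#'   not depend on it.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_step = NULL,
                            chunk_size = 1000L) {
  stopifnot(is.numeric(rel_tol), rel_tol > 0, is.numeric(abs_tol), abs_tol > 0,
            is.null(max_step) || (is.numeric(max_step) && max_step > 0),
            chunk_size >= 1)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 chunk_size = as.integer(chunk_size)),
            class = "solver_settings")
}

#' @export
print.solver_settings <- function(x, ...) {
  cat("<solver_settings> rel_tol:", x$rel_tol, " abs_tol:", x$abs_tol,
      if (!is.null(x$max_step)) paste(" max_step:", x$max_step), "\n")
  invisible(x)
}

# Low-level wrapper around deSolve::ode. `deriv` maps a state vector to its
# derivative. Returns the solution matrix (rows = times, first column time)
# or signals a classed solver error carrying the last reached time.
ode_solve <- function(y0, times, deriv, settings) {
  fn <- function(t, y, parms) list(deriv(y))
  args <- list(y = y0, times = times, func = fn, parms = NULL,
               method = "lsoda", rtol = settings$rel_tol,
               atol = settings$abs_tol)
  if (!is.null(settings$max_step)) args$hmax <- settings$max_step
  out <- withCallingHandlers(
    try(do.call(deSolve::ode, args), silent = TRUE),
    warning = function(w) invokeRestart("muffleWarning")
  )
  ok <- !inherits(out, "try-error") && is.matrix(out) &&
    nrow(out) == length(times) && all(is.finite(out[nrow(out), -1]))
  if (!ok) {
    last_t <- if (is.matrix(out) && nrow(out) >= 1) out[nrow(out), 1] else times[1]
    abort(sprintf("ODE integration failed; last time reached: %g.", last_t),
          class = "liouville_solver_error", last_time = last_t)
  }
  out
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1 || times[1] != 0 ||
      (length(times) > 1 && any(diff(times) <= 0))) {
    abort("`times` must start at 0 and be strictly increasing.")
  }
  as.numeric(times)
}

# Flow map for a set of points: integrate dx/dt = direction * F(x) from 0 to
# `time` for every row of `pts` (n x d). Independent points are stacked into
# one integrator call in chunks; on a chunk failure each point is retried
# alone so a single stiff trajectory cannot take down the batch.
# Returns list(states = n x d matrix (NA rows on failure),
#              ok = logical, last_time = numeric).
flow_points <- function(field, pts, time, settings, direction = 1) {
  n <- nrow(pts); d <- field$dim
  states <- matrix(NA_real_, n, d)
  ok <- rep(FALSE, n)
  last_time <- rep(NA_real_, n)
  if (time == 0) {
    return(list(states = pts, ok = rep(TRUE, n), last_time = rep(0, n)))
  }
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / settings$chunk_size))
  for (idx in idx_chunks) {
    X0 <- t(pts[idx, , drop = FALSE])            # d x k
    k <- length(idx)
    deriv <- function(y) {
      X <- matrix(y, nrow = d)
      as.vector(rhs_at(field, X)) * direction
    }
    res <- try(ode_solve(as.vector(X0), c(0, time), deriv, settings),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      states[idx, ] <- t(matrix(res[2, -1], nrow = d))
      ok[idx] <- TRUE
      last_time[idx] <- time
    } else if (k == 1L) {
      last_time[idx] <- attr(attr(res, "condition"), "last_time") %||% 0
    } else {
      for (i in idx) {                            # per-point fallback
        one <- flow_points(field, pts[i, , drop = FALSE], time, settings,
                           direction)
        states[i, ] <- one$states
        ok[i] <- one$ok
        last_time[i] <- one$last_time
      }
    }
  }
  list(states = states, ok = ok, last_time = last_time)
}

# Joint flow of points and their log-densities: integrates
#   dx/dt = F(x),  d(log rho)/dt = -div F(x)
# forward from (pts, log_rho0) and returns states and log_rho at `time`.
flow_with_density <- function(field, pts, log_rho0, time, settings) {
  n <- nrow(pts); d <- field$dim
  states <- matrix(NA_real_, n, d)
  log_rho <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  if (time == 0) {
    return(list(states = pts, log_rho = log_rho0, ok = rep(TRUE, n)))
  }
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / settings$chunk_size))
  for (idx in idx_chunks) {
    k <- length(idx)
    y0 <- c(as.vector(t(pts[idx, , drop = FALSE])), rep(0, k))
    deriv <- function(y) {
      X <- matrix(y[seq_len(d * k)], nrow = d)
      c(as.vector(rhs_at(field, X)), -div_at(field, X))
    }
    res <- try(ode_solve(y0, c(0, time), deriv, settings), silent = TRUE)
    if (!inherits(res, "try-error")) {
      yT <- res[2, -1]
      states[idx, ] <- t(matrix(yT[seq_len(d * k)], nrow = d))
      log_rho[idx] <- log_rho0[idx] + yT[d * k + seq_len(k)]
      ok[idx] <- TRUE
    } else if (k > 1L) {
      for (i in idx) {
        one <- flow_with_density(field, pts[i, , drop = FALSE], log_rho0[i],
                                 time, settings)
        states[i, ] <- one$states
        log_rho[i] <- one$log_rho
        ok[i] <- one$ok
      }
    }
  }
  list(states = states, log_rho = log_rho, ok = ok)
}
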