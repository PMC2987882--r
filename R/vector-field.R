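#' Define an autonomous ODE vector field
#'
#' A vector field is the right-hand side \eqn{F} of an autonomous ODE
#' \eqn{\dot x = F(x)} on \eqn{R^d}, optionally with an analytic divergence
#' \eqn{\mathrm{div}\,F = \sum_i \partial F_i/\partial x_i} (the trace of the
#' Jacobian) and per-coordinate domain bounds. The divergence is the local
#' exponential rate at which probability density changes along trajectories,
#' so supplying it analytically improves both speed and accuracy of density
#' propagation; when absent, a central finite-difference approximation of the
#' Jacobian trace is used.
#'
#' Only autonomous fields are supported: `rhs` must be a function of the state
#' alone (one argument). Time-dependent right-hand sides are rejected.
#'
#' @param rhs Function of a numeric state vector of length `dim`, returning
#'   the derivative vector of the same length. When the formula is built from
#'   elementwise operations it may also accept a `dim` x n matrix (one column
#'   per point) and return a matrix of the same shape; declare that via
#'   `vectorized = TRUE` to enable batched integration.
#' @param dim Positive integer, the state dimension \eqn{d}.
#' @param divergence Optional function of the state returning the scalar
#'   \eqn{\mathrm{div}\,F(x)}. If `vectorized = TRUE` it must likewise accept
#'   a matrix of column points and return one value per column.
#' @param lower,upper Optional numeric vectors of length `dim` giving the
#'   domain on which `rhs` is valid (default unbounded). Concentration models
#'   typically declare `lower = 0`.
#' @param vectorized Logical; `TRUE` asserts that `rhs` (and `divergence`, if
#'   given) operate columnwise on matrices of points.
#' @param state_names Optional character vector of coordinate names (default
#'   `x1`, ..., `xd`).
#' @param name Optional model label used in printed output and metadata.
#'
#' @return An object of class `vector_field`.
#' @seealso [eval_rhs()], [field_divergence()], [autoregulation_model()],
#'   [toggle_switch_model()]
#' @examples
#' rot <- vector_field(function(x) c(-x[2], x[1]), dim = 2,
#'                     divergence = function(x) 0)
#' eval_rhs(rot, c(1, 0))
#' field_divergence(rot, c(1, 0))
#' @export
vector_field <- function(rhs, dim, divergence = NULL, lower = NULL,
                         upper = NULL, vectorized = FALSE,
                         state_names = NULL, name = NULL) {
  stopifnot(is.function(rhs), is.numeric(dim), length(dim) == 1, dim >= 1,
            dim == as.integer(dim))
  dim <- as.integer(dim)
  if (length(formals(rhs)) != 1L) {
    abort("`rhs` must be a function of the state alone (autonomous field); time-dependent right-hand sides are not supported.")
  }
  if (!is.null(divergence) && !is.function(divergence)) {
    abort("`divergence` must be a function of the state or NULL.")
  }
  lower <- check_bound(lower, dim, -Inf, "lower")
  upper <- check_bound(upper, dim, Inf, "upper")
  if (any(lower >= upper)) abort("`lower` bounds must be strictly below `upper` bounds.")
  state_names <- state_names %||% paste0("x", seq_len(dim))
  stopifnot(length(state_names) == dim)
  structure(
    list(rhs = rhs, dim = dim, divergence = divergence,
         lower = lower, upper = upper, vectorized = isTRUE(vectorized),
         state_names = state_names, name = name),
    class = "vector_field"
  )
}

check_bound <- function(b, dim, default, what) {
  if (is.null(b)) return(rep(default, dim))
  if (length(b) == 1) b <- rep(b, dim)
  if (length(b) != length(seq_len(dim)) || !is.numeric(b)) {
    abort(sprintf("`%s` must be numeric of length 1 or %d.", what, dim))
  }
  as.numeric(b)
}

#' @export
print.vector_field <- function(x, ...) {
  cat("<vector_field>", if (!is.null(x$name)) paste0(" ", x$name), "\n", sep = "")
  cat("  dim:", x$dim, paste0("(", paste(x$state_names, collapse = ", "), ")"), "\n")
  cat("  divergence:", if (is.null(x$divergence)) "finite-difference" else "analytic", "\n")
  if (any(is.finite(x$lower)) || any(is.finite(x$upper))) {
    cat("  domain: [", paste(x$lower, collapse = ", "), "] to [",
        paste(x$upper, collapse = ", "), "]\n")
  }
  invisible(x)
}

check_state <- function(field, x) {
  if (!is.numeric(x) || length(x) != field$dim) {
    abort(sprintf("state has length %d but the field has dim %d.",
                  length(x), field$dim))
  }
  bad <- which(x < field$lower | x > field$upper)
  if (length(bad)) {
    abort(sprintf("state coordinate %s (%s = %g) is outside the field's domain [%g, %g].",
                  bad[1], field$state_names[bad[1]], x[bad[1]],
                  field$lower[bad[1]], field$upper[bad[1]]),
          class = "liouville_domain_error")
  }
  invisible(x)
}

#' Evaluate a vector field's right-hand side
#'
#' @param field A [vector_field()].
#' @param x Numeric state vector of length `field$dim`, inside the field's
#'   domain.
#' @return The derivative vector \eqn{F(x)}.
#' @examples
#' eval_rhs(autoregulation_model(), 2)
#' @export
eval_rhs <- function(field, x) {
  stopifnot(inherits(field, "vector_field"))
  check_state(field, x)
  fx <- as.numeric(field$rhs(x))
  if (length(fx) != field$dim) {
    abort(sprintf("rhs returned length %d, expected %d.", length(fx), field$dim))
  }
  fx
}

#' Divergence (Jacobian trace) of a vector field
#'
#' Returns the analytic divergence when the field declares one, otherwise a
#' central finite-difference approximation of the Jacobian trace with
#' per-coordinate step \eqn{h_i = \sqrt{\epsilon}\,\max(1, |x_i|)} where
#' \eqn{\epsilon} is the machine epsilon.
#'
#' @inheritParams eval_rhs
#' @return Scalar \eqn{\mathrm{div}\,F(x)}.
#' @examples
#' field_divergence(autoregulation_model(), 2)
#' @export
field_divergence <- function(field, x) {
  stopifnot(inherits(field, "vector_field"))
  check_state(field, x)
  if (!is.null(field$divergence)) {
    d <- as.numeric(field$divergence(x))
  } else {
    d <- fd_divergence(field$rhs, x)
  }
  if (!is.finite(d)) {
    abort(sprintf("divergence is non-finite (%g) at (%s).", d,
                  paste(signif(x, 6), collapse = ", ")),
          class = "liouville_numeric_error")
  }
  d
}

fd_divergence <- function(rhs, x) {
  h <- sqrt(.Machine$double.eps) * pmax(1, abs(x))
  s <- 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    s <- s + (rhs(xp)[i] - rhs(xm)[i]) / (xp[i] - xm[i])
  }
  s
}

# divergence for a matrix of column points -> numeric vector
div_at <- function(field, X) {
  if (!is.null(field$divergence)) {
    if (field$vectorized) return(as.numeric(field$divergence(X)))
    return(vapply(seq_len(ncol(X)), function(j) as.numeric(field$divergence(X[, j])),
                  numeric(1)))
  }
  vapply(seq_len(ncol(X)), function(j) fd_divergence(field$rhs, X[, j]), numeric(1))
}

# rhs for a matrix of column points -> matrix of column derivatives
rhs_at <- function(field, X) {
  if (field$vectorized) {
    out <- field$rhs(X)
    dim(out) <- dim(X)
    return(out)
  }
  out <- vapply(seq_len(ncol(X)), function(j) as.numeric(field$rhs(X[, j])),
                numeric(field$dim))
  matrix(out, nrow = field$dim)
}
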