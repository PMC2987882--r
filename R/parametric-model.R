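#' Define a parametric ODE model
#'
#' A parametric model is a family of vector fields \eqn{\dot z = f(z \mid p)}
#' on an \eqn{n}-dimensional state space indexed by \eqn{m} parameters.
#' Parameter uncertainty is handled by [extend_state()], which embeds the
#' model in the joint state-parameter space where parameters evolve with zero
#' derivative; from there every density-propagation tool applies unchanged.
#'
#' @param rhs Function `(z, p)` returning the length-`state_dim` derivative of
#'   the state `z` given the parameter vector `p`.
#' @param state_dim Positive integer \eqn{n}.
#' @param param_names Character vector naming the \eqn{m} parameters
#'   (`param_dim` is its length; it may be empty).
#' @param divergence Optional function `(z, p)` returning the divergence of
#'   \eqn{f(\cdot \mid p)} with respect to the state alone.
#' @param vectorized Logical; `TRUE` asserts that `rhs` (and `divergence`)
#'   accept matrices `Z` (`state_dim` x k) and `P` (`param_dim` x k) and
#'   operate columnwise.
#' @param state_names Optional coordinate names for the state.
#' @param name Optional model label.
#' @return An object of class `parametric_model`.
#' @seealso [extend_state()], [build_parametric()]
#' @examples
#' m <- parametric_model(
#'   function(z, p) -p[1] * z, state_dim = 1, param_names = "k",
#'   divergence = function(z, p) -p[1])
#' f <- extend_state(m)
#' eval_rhs(f, c(2, 0.5))  # decay at rate 0.5; parameter derivative is 0
#' @export
parametric_model <- function(rhs, state_dim, param_names = character(),
                             divergence = NULL, vectorized = FALSE,
                             state_names = NULL, name = NULL) {
  stopifnot(is.function(rhs), state_dim >= 1, state_dim == as.integer(state_dim),
            is.character(param_names))
  if (length(formals(rhs)) != 2L) {
    abort("`rhs` must be a function (z, p) of state and parameters.")
  }
  structure(
    list(rhs = rhs, state_dim = as.integer(state_dim),
         param_dim = length(param_names), param_names = param_names,
         divergence = divergence, vectorized = isTRUE(vectorized),
         state_names = state_names %||% paste0("x", seq_len(state_dim)),
         name = name),
    class = "parametric_model"
  )
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model>", if (!is.null(x$name)) paste0(" ", x$name), "\n", sep = "")
  cat("  state dim:", x$state_dim, " parameters:",
      if (x$param_dim) paste(x$param_names, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Extend a parametric model to the joint state-parameter space
#'
#' Builds the autonomous vector field on \eqn{R^{n+m}} whose first \eqn{n}
#' components are \eqn{f(z \mid p)} and whose last \eqn{m} components are
#' identically zero (parameters are constant in time). Its divergence equals
#' the divergence of \eqn{f} with respect to the state alone, since the
#' parameter block contributes nothing to the Jacobian trace. This reduction
#' turns parameter uncertainty into initial-condition uncertainty on the
#' extended space.
#'
#' @param model A [parametric_model()].
#' @return A [vector_field()] with `dim = state_dim + param_dim`.
#' @examples
#' f <- extend_state(build_parametric("autoregulation", free = "V_max"))
#' eval_rhs(f, c(2, 1))  # c(dx/dt, 0)
#' @export
extend_state <- function(model) {
  stopifnot(inherits(model, "parametric_model"))
  n <- model$state_dim
  m <- model$param_dim
  zeros <- rep(0, m)
  rhs_ext <- if (m == 0L) {
    function(x) {
      if (is.matrix(x)) model$rhs(x, matrix(0, 0, ncol(x)))
      else model$rhs(x, numeric(0))
    }
  } else if (model$vectorized) {
    function(x) {
      if (is.matrix(x)) {
        rbind(model$rhs(x[seq_len(n), , drop = FALSE],
                        x[n + seq_len(m), , drop = FALSE]),
              matrix(0, m, ncol(x)))
      } else {
        c(model$rhs(x[seq_len(n)], x[n + seq_len(m)]), zeros)
      }
    }
  } else {
    function(x) c(model$rhs(x[seq_len(n)], x[n + seq_len(m)]), zeros)
  }
  div_ext <- if (is.null(model$divergence)) NULL else if (model$vectorized) {
    function(x) {
      if (is.matrix(x)) {
        model$divergence(x[seq_len(n), , drop = FALSE],
                         x[n + seq_len(m), , drop = FALSE])
      } else {
        model$divergence(x[seq_len(n)], x[n + seq_len(m)])
      }
    }
  } else {
    function(x) model$divergence(x[seq_len(n)], x[n + seq_len(m)])
  }
  vector_field(rhs_ext, dim = n + m, divergence = div_ext,
               vectorized = model$vectorized,
               state_names = c(model$state_names, model$param_names),
               name = if (!is.null(model$name)) paste0(model$name, " (extended)"))
}
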