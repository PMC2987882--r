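#' Autoregulatory gene-expression model
#'
#' One-dimensional model of a protein activating its own expression by
#' cooperative promoter binding, with first-order dilution:
#' \deqn{\dot x = V_{max} \frac{x^\beta}{K^\beta + x^\beta} - k_d\, x.}
#' `V_max` is the maximal expression rate (mol/volume/time), `K` the
#' concentration of half-maximal expression (mol/volume), `beta` the
#' dimensionless promoter cooperativity, and `k_d` the dilution rate constant
#' (1/time). The positive feedback makes the field bistable for suitable
#' parameters: trajectories starting below the unstable threshold collapse
#' toward 0 while the bulk grows toward the high steady state, leaving a
#' heavy low-concentration tail in the propagated density. The analytic
#' divergence is
#' \deqn{V_{max}\,\beta K^\beta x^{\beta-1} / (K^\beta + x^\beta)^2 - k_d.}
#'
#' @param V_max,K,k_d,beta Positive parameters (defaults: 1, 2, 0.01, 4).
#' @return A [vector_field()] on `x >= 0` with analytic, vectorized rhs and
#'   divergence.
#' @examples
#' f <- autoregulation_model()
#' eval_rhs(f, 2)          # 0.48
#' field_divergence(f, 2)  # 0.49
#' @export
autoregulation_model <- function(V_max = 1, K = 2, k_d = 0.01, beta = 4) {
  check_positive(c(V_max = V_max, K = K, k_d = k_d, beta = beta))
  Kb <- K^beta
  rhs <- function(x) V_max * x^beta / (Kb + x^beta) - k_d * x
  div <- function(x) V_max * beta * Kb * x^(beta - 1) / (Kb + x^beta)^2 - k_d
  vector_field(rhs, dim = 1, divergence = div, lower = 0, vectorized = TRUE,
               state_names = "x", name = "autoregulation")
}

#' Genetic toggle switch model
#'
#' Two proteins mutually repressing each other's expression:
#' \deqn{\dot x_1 = \frac{\alpha_1}{1 + (x_2/q_1)^{\beta_1}} - k_d x_1,
#'       \qquad
#'       \dot x_2 = \frac{\alpha_2}{1 + (x_1/q_2)^{\beta_2}} - k_d x_2.}
#' `alpha1`/`alpha2` are effective expression rates, `beta1`/`beta2`
#' repression cooperativities, `q1`/`q2` the repressor concentrations of
#' half-maximal repression, and `k_d` the common dilution rate. Each
#' equation's own state enters only through dilution, so the divergence is
#' constant: \eqn{-2 k_d}. With the default symmetric parameters an initially
#' round density contracts rapidly onto the slow manifold of the field,
#' developing a steep, strongly non-normal ridge.
#'
#' @param alpha1,alpha2,beta1,beta2,q1,q2,k_d Positive parameters (defaults
#'   5, 5, 2, 2, 1, 1, 1).
#' @return A [vector_field()] on the non-negative quadrant with analytic,
#'   vectorized rhs and divergence.
#' @examples
#' f <- toggle_switch_model()
#' eval_rhs(f, c(3, 3))          # c(-2.5, -2.5)
#' field_divergence(f, c(3, 3))  # -2
#' @export
toggle_switch_model <- function(alpha1 = 5, alpha2 = 5, beta1 = 2, beta2 = 2,
                                q1 = 1, q2 = 1, k_d = 1) {
  check_positive(c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
                   beta2 = beta2, q1 = q1, q2 = q2, k_d = k_d))
  rhs <- function(x) {
    if (is.matrix(x)) {
      rbind(alpha1 / (1 + (x[2, ] / q1)^beta1) - k_d * x[1, ],
            alpha2 / (1 + (x[1, ] / q2)^beta2) - k_d * x[2, ])
    } else {
      c(alpha1 / (1 + (x[2] / q1)^beta1) - k_d * x[1],
        alpha2 / (1 + (x[1] / q2)^beta2) - k_d * x[2])
    }
  }
  div <- function(x) {
    if (is.matrix(x)) rep(-2 * k_d, ncol(x)) else -2 * k_d
  }
  vector_field(rhs, dim = 2, divergence = div, lower = c(0, 0),
               vectorized = TRUE, state_names = c("x1", "x2"),
               name = "toggle_switch")
}

check_positive <- function(p) {
  bad <- !is.finite(p) | p <= 0
  if (any(bad)) {
    abort(sprintf("parameter(s) %s must be positive.",
                  paste(names(p)[bad], collapse = ", ")))
  }
  invisible(p)
}

model_defaults <- list(
  autoregulation = c(V_max = 1, K = 2, k_d = 0.01, beta = 4),
  toggle_switch = c(alpha1 = 5, alpha2 = 5, beta1 = 2, beta2 = 2,
                    q1 = 1, q2 = 1, k_d = 1)
)

#' Built-in model registry
#'
#' `model_names()` lists the built-in models; `build_model()` instantiates
#' one by name with (a subset of) its parameters overridden;
#' `build_parametric()` instead leaves the named parameters free, returning a
#' [parametric_model()] ready for [extend_state()] and likelihood profiling.
#'
#' @param name `"autoregulation"` or `"toggle_switch"`.
#' @param params Named list/vector of parameter overrides.
#' @param free Character vector of parameter names left free (for
#'   `build_parametric()`).
#' @return `build_model()` a [vector_field()]; `build_parametric()` a
#'   [parametric_model()].
#' @examples
#' build_model("autoregulation", list(V_max = 1.2))
#' build_parametric("autoregulation", free = "V_max")
#' @export
build_model <- function(name, params = list()) {
  pars <- resolve_params(name, params)
  switch(name,
         autoregulation = do.call(autoregulation_model, as.list(pars)),
         toggle_switch = do.call(toggle_switch_model, as.list(pars)))
}

#' @rdname build_model
#' @export
build_parametric <- function(name, free, params = list()) {
  fixed <- resolve_params(name, params)
  if (!all(free %in% names(fixed))) {
    abort(sprintf("unknown free parameter(s) %s for model '%s'.",
                  paste(setdiff(free, names(fixed)), collapse = ", "), name))
  }
  check_positive(fixed[setdiff(names(fixed), free)])
  state_dim <- if (name == "autoregulation") 1L else 2L
  state_names <- if (name == "autoregulation") "x" else c("x1", "x2")

  # free parameters are NOT constrained to be positive here: likelihood
  # profiles legitimately evaluate boundary values such as V_max = 0
  plist <- function(p) {
    pl <- as.list(fixed)
    if (is.matrix(p)) {
      for (i in seq_along(free)) pl[[free[i]]] <- p[i, ]
    } else {
      pl[free] <- as.list(p)
    }
    pl
  }
  rhs <- function(z, p) {
    if (is.matrix(z)) eval_builtin_rhs(name, z, plist(p))
    else as.numeric(eval_builtin_rhs(name, matrix(z), plist(p)))
  }
  div <- function(z, p) {
    if (is.matrix(z)) eval_builtin_div(name, z, plist(p))
    else as.numeric(eval_builtin_div(name, matrix(z), plist(p)))
  }
  parametric_model(rhs, state_dim = state_dim, param_names = free,
                   divergence = div, vectorized = TRUE,
                   state_names = state_names, name = name)
}

#' @rdname build_model
#' @export
model_names <- function() names(model_defaults)

resolve_params <- function(name, params) {
  if (!name %in% names(model_defaults)) {
    abort(sprintf("unknown model '%s'; built-ins: %s.", name,
                  paste(model_names(), collapse = ", ")))
  }
  pars <- model_defaults[[name]]
  params <- unlist(params)
  if (length(params)) {
    unknown <- setdiff(names(params), names(pars))
    if (length(unknown)) {
      abort(sprintf("unknown parameter(s) %s for model '%s'.",
                    paste(unknown, collapse = ", "), name))
    }
    pars[names(params)] <- params
  }
  pars
}

# vectorized builtin formulas over matrices of column points with parameters
# given as scalars or per-column vectors
eval_builtin_rhs <- function(name, Z, pl) {
  if (name == "autoregulation") {
    x <- Z[1, ]
    Kb <- pl$K^pl$beta
    matrix(pl$V_max * x^pl$beta / (Kb + x^pl$beta) - pl$k_d * x, nrow = 1)
  } else {
    rbind(pl$alpha1 / (1 + (Z[2, ] / pl$q1)^pl$beta1) - pl$k_d * Z[1, ],
          pl$alpha2 / (1 + (Z[1, ] / pl$q2)^pl$beta2) - pl$k_d * Z[2, ])
  }
}

eval_builtin_div <- function(name, Z, pl) {
  if (name == "autoregulation") {
    x <- Z[1, ]
    Kb <- pl$K^pl$beta
    pl$V_max * pl$beta * Kb * x^(pl$beta - 1) / (Kb + x^pl$beta)^2 - pl$k_d
  } else {
    rep(-2 * pl$k_d, ncol(Z))
  }
}
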