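#' Observed data at a common time
#'
#' A set of full-state observations \eqn{D = \{\xi_1(T), ..., \xi_N(T)\}}
#' made at time `T`, assumed to be independent draws from the model's output
#' distribution \eqn{u(T, \cdot)} (e.g. single-cell measurements across a
#' population).
#'
#' @param time Observation time (scalar, `>= 0`).
#' @param values Numeric vector (one-dimensional observed state) or
#'   matrix/data frame with one observation per row.
#' @return An object of class `observation_set`.
#' @examples
#' observation_set(20, 5)
#' @export
observation_set <- function(time, values) {
  stopifnot(is.numeric(time), length(time) == 1, time >= 0)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1) abort("at least one observation is required.")
  if (!all(is.finite(values))) abort("observations must be finite.")
  structure(list(time = time, points = values, n = nrow(values)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set>", x$n, "observation(s) at time", x$time, "\n")
  invisible(x)
}

#' Likelihood of an ODE model for observed data
#'
#' The likelihood of a model with random initial state is the product of its
#' output density at the data points,
#' \eqn{L = \prod_i u(T, \xi_i(T))}, evaluated here exactly by the
#' backward-forward characteristics procedure and accumulated in log space
#' (an N-point product of densities underflows quickly). A data point with
#' zero output density makes the log-likelihood `-Inf`; a point whose solve
#' fails makes it undefined (an error, since the likelihood is then unknown
#' rather than zero).
#'
#' @param field A [vector_field()] (observations are full-state).
#' @param u0 An [initial_density] encoding prior knowledge of the initial
#'   state (and parameters on an extended space).
#' @param obs An [observation_set()] with dimension equal to `field$dim`.
#' @param settings A [solver_settings()].
#' @return An object of class `likelihood_eval`: a list with `points` (a
#'   `density_field` at the data) and `log_likelihood`.
#' @examples
#' ll <- likelihood_of_data(autoregulation_model(), normal_density(2, 0.2),
#'                          observation_set(20, 5))
#' ll$log_likelihood
#' @export
likelihood_of_data <- function(field, u0, obs, settings = solver_settings()) {
  stopifnot(inherits(obs, "observation_set"))
  if (ncol(obs$points) != field$dim) {
    abort(sprintf("observations have dimension %d but the field has dim %d (full-state observation is required).",
                  ncol(obs$points), field$dim))
  }
  f <- density_at_points(field, u0, obs$points, obs$time, settings)
  if (any(f$status == "solver_error")) {
    abort(sprintf("%d of %d data points failed to solve; the likelihood is undefined.",
                  sum(f$status == "solver_error"), nrow(f)))
  }
  structure(list(points = f, log_likelihood = sum(f$log_density),
                 time = obs$time, n = obs$n),
            class = "likelihood_eval")
}

#' @export
print.likelihood_eval <- function(x, ...) {
  cat("<likelihood_eval>", x$n, "data point(s) at time", x$time,
      " log-likelihood:", x$log_likelihood, "\n")
  invisible(x)
}

#' @export
tidy.likelihood_eval <- function(x, ...) tibble::as_tibble(x$points)

#' @export
glance.likelihood_eval <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood, n = x$n, time = x$time)
}

#' Profile the likelihood over a parameter grid
#'
#' For each candidate value \eqn{v_i} of the profiled parameter(s), the model
#' is extended by those parameters (constant in time), each data point
#' \eqn{\xi(T)} paired with \eqn{v_i} is integrated backward to its pre-image
#' \eqn{(\xi(0), v_i)}, the joint prior \eqn{u_0} is evaluated there, and the
#' extended system is integrated forward to yield the likelihood value
#' \eqn{u(T, (\xi(T), v_i))}. Per-value log-likelihoods sum over data points.
#' The maximizer is recorded with ties broken toward the smallest parameter
#' value; values whose solves fail are flagged missing and skipped in the
#' maximization.
#'
#' @param model A [parametric_model()] whose free parameters are the ones
#'   profiled (see [build_parametric()]).
#' @param u0_joint An [initial_density] on the joint (state, free-parameter)
#'   space, in that coordinate order.
#' @param obs An [observation_set()] of state-only data.
#' @param values Candidate parameter values: a numeric vector (one free
#'   parameter; see [profile_points()] for node-inclusive grids) or a
#'   matrix/data frame with one column per free parameter.
#' @param settings A [solver_settings()].
#' @return A tibble of class `likelihood_profile` with one row per candidate
#'   value: parameter column(s), `log_likelihood`, `ok`; attributes carry the
#'   maximizer and its gap to the runner-up. Use [mle_from_profile()],
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' m <- build_parametric("autoregulation", free = "V_max")
#' prior <- normal_density(mean = c(2, 1), cov = c(0.2, 0.01))
#' pr <- profile_parameter(m, prior, observation_set(20, 5),
#'                         values = profile_points(0, 2, 0.25))
#' mle_from_profile(pr)
#' @export
profile_parameter <- function(model, u0_joint, obs, values,
                              settings = solver_settings()) {
  stopifnot(inherits(model, "parametric_model"),
            inherits(u0_joint, "initial_density"),
            inherits(obs, "observation_set"))
  m <- model$param_dim
  if (m < 1) abort("the model has no free parameters to profile.")
  if (is.null(dim(values))) {
    if (m != 1) abort(sprintf("`values` must have %d columns (one per free parameter).", m))
    V <- matrix(as.numeric(values), ncol = 1)
  } else {
    V <- as.matrix(values)
    storage.mode(V) <- "double"
  }
  if (ncol(V) != m) {
    abort(sprintf("`values` has %d columns but the model has %d free parameters.",
                  ncol(V), m))
  }
  if (ncol(obs$points) != model$state_dim) {
    abort("observations must have the model's state dimension.")
  }
  if (u0_joint$dim != model$state_dim + m) {
    abort(sprintf("joint prior has dim %d, expected state_dim + param_dim = %d.",
                  u0_joint$dim, model$state_dim + m))
  }
  field <- extend_state(model)
  nv <- nrow(V); nd <- obs$n
  # all (datum, value) pairs in one batched backward-forward computation
  pairs <- cbind(obs$points[rep(seq_len(nd), times = nv), , drop = FALSE],
                 V[rep(seq_len(nv), each = nd), , drop = FALSE])
  f <- density_at_points(field, u0_joint, pairs, obs$time, settings)
  ld <- matrix(f$log_density, nrow = nd, ncol = nv)
  failed <- matrix(f$status == "solver_error", nrow = nd, ncol = nv)
  ll <- colSums(ld)
  ok <- colSums(failed) == 0
  ll[!ok] <- NA_real_

  prof <- tibble::as_tibble(as.data.frame(V, optional = TRUE),
                            .name_repair = "minimal")
  names(prof) <- model$param_names
  prof$log_likelihood <- ll
  prof$ok <- ok
  prof <- structure(prof,
                    class = c("likelihood_profile", class(tibble::tibble())),
                    param_names = model$param_names, time = obs$time,
                    n_obs = nd, model_name = model$name)
  finite <- ok & is.finite(ll)
  if (any(finite)) {
    if (diff(range(ll[finite])) < 1e-8 && sum(finite) > 1) {
      warn("the likelihood profile is flat over the candidate values; the maximizer is not informative.",
           class = "liouville_flat_profile_warning")
    }
    attr(prof, "maximizer") <- find_maximizer(V, ll, finite,
                                              model$param_names)
  }
  prof
}

find_maximizer <- function(V, ll, finite, param_names) {
  ord <- do.call(order, c(lapply(seq_len(ncol(V)), function(j) V[, j])))
  ordf <- ord[finite[ord]]
  best <- ordf[which.max(ll[ordf])]    # first (= smallest value) on ties
  gap <- if (length(ordf) > 1) {
    sorted <- sort(ll[ordf], decreasing = TRUE)
    sorted[1] - sorted[2]
  } else NA_real_
  list(value = setNames(as.numeric(V[best, ]), param_names),
       log_likelihood = ll[best], gap = gap)
}

#' Refine a likelihood profile around its maximizer
#'
#' Optional second pass for a single-parameter profile: re-profiles on a
#' finer node-inclusive grid spanning one coarse grid step on either side of
#' the current maximizer (clipped to the original range). Off by default in
#' the sense that [profile_parameter()] never refines on its own - grid
#' profiling at the declared spacing is the primary procedure.
#'
#' @param model,u0_joint,obs,settings As in [profile_parameter()].
#' @param profile The coarse `likelihood_profile` to refine.
#' @param factor Grid-step reduction factor (default 10).
#' @return A new, finer `likelihood_profile`.
#' @export
refine_profile <- function(model, u0_joint, obs, profile, factor = 10,
                           settings = solver_settings()) {
  stopifnot(inherits(profile, "likelihood_profile"), factor > 1)
  nm <- attr(profile, "param_names")
  if (length(nm) != 1) abort("refinement supports a single profiled parameter.")
  mx <- attr(profile, "maximizer")
  if (is.null(mx)) abort("the profile has no finite maximizer to refine around.",
                         class = "liouville_estimation_error")
  v <- sort(profile[[nm]])
  h <- stats::median(diff(v))
  lo <- max(min(v), mx$value[[nm]] - h)
  hi <- min(max(v), mx$value[[nm]] + h)
  steps <- max(2L, round((hi - lo) / (h / factor)))
  profile_parameter(model, u0_joint, obs,
                    profile_points(lo, hi, (hi - lo) / steps), settings)
}

#' Extract the maximum-likelihood estimate from a profile
#'
#' Returns the grid value attaining the maximal finite log-likelihood, ties
#' broken toward the smallest parameter value, together with the
#' log-likelihood gap to the runner-up grid point (attributes `gap` and
#' `log_likelihood`).
#'
#' @param profile A `likelihood_profile` from [profile_parameter()].
#' @return Named numeric vector of the maximizing parameter value(s).
#' @export
mle_from_profile <- function(profile) {
  stopifnot(inherits(profile, "likelihood_profile"))
  mx <- attr(profile, "maximizer")
  if (is.null(mx)) {
    abort("no finite log-likelihood in the profile; cannot estimate.",
          class = "liouville_estimation_error")
  }
  structure(mx$value, gap = mx$gap, log_likelihood = mx$log_likelihood)
}

#' @export
print.likelihood_profile <- function(x, ...) {
  mx <- attr(x, "maximizer")
  cat("<likelihood_profile> over", paste(attr(x, "param_names"), collapse = ", "),
      "-", nrow(x), "values,", attr(x, "n_obs"), "data point(s) at time",
      attr(x, "time"), "\n")
  if (!is.null(mx)) {
    cat("  maximizer:", paste(sprintf("%s = %g", names(mx$value), mx$value),
                              collapse = ", "),
        sprintf("(log L = %.6g, gap to runner-up %.3g)\n",
                mx$log_likelihood, mx$gap))
  }
  NextMethod()
}

#' @export
tidy.likelihood_profile <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.likelihood_profile <- function(x, ...) {
  mx <- attr(x, "maximizer")
  out <- tibble::tibble(n_values = nrow(x), n_missing = sum(!x$ok),
                        n_obs = attr(x, "n_obs"), time = attr(x, "time"))
  if (!is.null(mx)) {
    for (nm in names(mx$value)) out[[paste0("mle_", nm)]] <- mx$value[[nm]]
    out$max_log_likelihood <- mx$log_likelihood
    out$gap <- mx$gap
  }
  out
}

#' Plot a likelihood profile
#'
#' @param object A `likelihood_profile` (single profiled parameter).
#' @param likelihood Plot the likelihood (`TRUE`, default) or the
#'   log-likelihood.
#' @param ... Unused.
#' @return A ggplot with the maximizer marked.
#' @export
autoplot.likelihood_profile <- function(object, likelihood = TRUE, ...) {
  nm <- attr(object, "param_names")[1]
  mx <- attr(object, "maximizer")
  y <- if (likelihood) exp(object$log_likelihood) else object$log_likelihood
  df <- tibble::tibble(x = object[[nm]], y = y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = nm, y = if (likelihood) "likelihood" else "log-likelihood")
  if (!is.null(mx)) {
    p <- p + ggplot2::geom_vline(xintercept = mx$value[[nm]], linetype = 2)
  }
  p
}

#' Write a likelihood profile to CSV plus JSON summary
#'
#' @param profile A `likelihood_profile`.
#' @param file CSV path (parameter value, log_likelihood, ok); the JSON
#'   summary (maximizer, gap, counts) is written to `<file>.json` unless
#'   `summary_file` is given.
#' @param summary_file Optional explicit JSON path.
#' @param metadata Extra fields merged into the summary.
#' @return `file`, invisibly.
#' @export
write_profile <- function(profile, file, summary_file = NULL, metadata = list()) {
  stopifnot(inherits(profile, "likelihood_profile"))
  readr::write_csv(tibble::as_tibble(profile), file)
  mx <- attr(profile, "maximizer")
  meta <- c(list(
    parameters = attr(profile, "param_names"),
    n_values = nrow(profile), n_obs = attr(profile, "n_obs"),
    time = attr(profile, "time"),
    maximizer = if (!is.null(mx)) as.list(mx$value),
    max_log_likelihood = if (!is.null(mx)) mx$log_likelihood,
    gap = if (!is.null(mx)) mx$gap), metadata)
  jsonlite::write_json(meta, summary_file %||% paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
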