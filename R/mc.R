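#' Monte Carlo trajectory ensemble
#'
#' The classical sampling alternative to characteristics, kept as a
#' reference: (i) draw `n` iid samples from the initial density, (ii) solve
#' the original ODE for each sample up to `time`, (iii) estimate the density
#' from the propagated cloud ([histogram_density()]). The whole ensemble is
#' reproducible from `(seed, n, settings)` since trajectory integration is
#' deterministic. Samples whose integration fails are excluded, with a
#' warning when more than 0.1% fail.
#'
#' @param field A [vector_field()].
#' @param u0 An [initial_density] that supports sampling.
#' @param n Number of samples.
#' @param time Final time.
#' @param seed Integer seed for the initial draw.
#' @param settings A [solver_settings()].
#' @return An object of class `mc_ensemble`: list with `points` (propagated
#'   states, one row per surviving sample), `initial` (the draws), `time`,
#'   `n`, `n_failed`, `seed`.
#' @examples
#' ens <- monte_carlo_ensemble(autoregulation_model(), normal_density(2, 0.2),
#'                             n = 200, time = 10, seed = 1)
#' @export
monte_carlo_ensemble <- function(field, u0, n, time, seed = NULL,
                                 settings = solver_settings()) {
  stopifnot(inherits(field, "vector_field"), inherits(u0, "initial_density"),
            n >= 1, time >= 0)
  x0 <- draw_samples(u0, n, seed = seed)
  res <- flow_points(field, x0, time, settings, direction = 1)
  n_failed <- sum(!res$ok)
  if (n_failed > 0.001 * n) {
    warn(sprintf("%d of %d sample trajectories failed to integrate and were excluded.",
                 n_failed, n))
  }
  structure(list(points = res$states[res$ok, , drop = FALSE],
                 initial = x0[res$ok, , drop = FALSE],
                 time = time, n = as.integer(n), n_failed = n_failed,
                 seed = seed, state_names = field$state_names),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat("<mc_ensemble>", nrow(x$points), "of", x$n, "samples at time", x$time,
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' @export
tidy.mc_ensemble <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(x$points, optional = TRUE),
                          .name_repair = "minimal")
  names(df) <- x$state_names
  dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(df))), df)
}

#' @export
glance.mc_ensemble <- function(x, ...) {
  tibble::tibble(n = x$n, n_failed = x$n_failed, time = x$time,
                 seed = x$seed %||% NA_integer_)
}

#' Histogram density estimate from a Monte Carlo ensemble
#'
#' Step (iii) of the Monte Carlo route: the density in each cell of a uniform
#' grid is the relative frequency of propagated points divided by the cell
#' volume, with binomial standard errors
#' \eqn{\sqrt{\hat p (1 - \hat p)/N} / \mathrm{vol}}. The estimate's accuracy
#' at a point depends on the total sample size, which is what makes
#' low-probability regions expensive for sampling methods: covering a region
#' holding 0.1% of the mass with ~100 points requires ~100 000 samples.
#' Points outside the grid are counted into an overflow tally reported as an
#' attribute (and a message). The result is flagged as an estimate and is not
#' quadrature-eligible.
#'
#' @param ensemble An `mc_ensemble`.
#' @param grid A [uniform_grid()] over the ensemble's space.
#' @return A `density_field` with extra columns `count` and `std_error`,
#'   attribute `overflow` (number of out-of-grid points) and
#'   `estimate = TRUE`.
#' @export
histogram_density <- function(ensemble, grid) {
  stopifnot(inherits(ensemble, "mc_ensemble"), inherits(grid, "uniform_grid"))
  pts <- ensemble$points
  if (ncol(pts) != grid$dim) {
    abort(sprintf("ensemble has dimension %d but the grid has %d.",
                  ncol(pts), grid$dim))
  }
  N <- nrow(pts)
  # per-axis cell index, NA when outside; linear index in the grid's
  # row-major order (first axis slowest)
  idx <- matrix(NA_integer_, N, grid$dim)
  for (a in seq_len(grid$dim)) {
    i <- floor((pts[, a] - grid$lo[a]) / grid$h[a]) + 1
    i[pts[, a] == grid$hi[a]] <- grid$n[a]   # right-boundary points included
    i[i < 1 | i > grid$n[a]] <- NA_integer_
    idx[, a] <- as.integer(i)
  }
  inside <- stats::complete.cases(idx)
  lin <- rep(1L, sum(inside))
  for (a in seq_len(grid$dim)) {
    lin <- (lin - 1L) * grid$n[a] + idx[inside, a]
  }
  counts <- tabulate(lin, nbins = prod(grid$n))
  overflow <- N - sum(inside)
  if (overflow > 0) {
    message(sprintf("%d of %d points fall outside the grid (overflow bin).",
                    overflow, N))
  }
  vol <- cell_volume(grid)
  phat <- counts / N
  dens <- phat / vol
  se <- sqrt(phat * (1 - phat) / N) / vol
  out <- new_density_field(as.matrix(grid_points(grid)), log(dens),
                           time = ensemble$time, grid = grid,
                           state_names = grid$names, estimate = TRUE,
                           extra = tibble::tibble(count = counts,
                                                  std_error = se))
  attr(out, "overflow") <- overflow
  out
}

#' Compare characteristics densities with a Monte Carlo histogram
#'
#' Convenience cross-validation: evaluates the exact backward-forward density
#' on the cell centers of `grid` and the histogram estimate from an ensemble
#' of `n` samples, returning per-cell z-scores
#' `(characteristics - estimate) / std_error`.
#'
#' @inheritParams monte_carlo_ensemble
#' @param grid A [uniform_grid()] at the final time.
#' @return A tibble: cell centers, `density_char`, `density_mc`, `count`,
#'   `std_error`, `z`.
#' @export
mc_compare <- function(field, u0, grid, n, time, seed = NULL,
                       settings = solver_settings()) {
  char <- density_at_points(field, u0, grid, time, settings)
  ens <- monte_carlo_ensemble(field, u0, n, time, seed, settings)
  hist <- histogram_density(ens, grid)
  nm <- attr(char, "state_names")
  out <- tibble::as_tibble(char)[nm]
  out$density_char <- char$density
  out$density_mc <- hist$density
  out$count <- hist$count
  out$std_error <- hist$std_error
  out$z <- (char$density - hist$density) / hist$std_error
  out
}
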