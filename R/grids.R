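#' Cell-centered uniform grid over a box
#'
#' Discretizes a box into cells of side `h` per axis and represents it by the
#' cell centers `lo + h/2, lo + 3h/2, ...`, which lie strictly inside
#' `[lo, hi]`. Cell-centering matches the midpoint quadrature rule used for
#' marginalization and region masses, and guarantees that grid points never
#' hit the support boundary of a uniform or exponential initial density.
#'
#' @param lo,hi Numeric vectors of per-axis bounds (`lo < hi`); scalars for a
#'   one-dimensional grid.
#' @param h Per-axis step(s); `(hi - lo)` must be an integer multiple of `h`
#'   (within 1e-9).
#' @param names Optional axis names.
#' @return An object of class `uniform_grid`.
#' @examples
#' uniform_grid(0, 1, h = 0.5)              # centers 0.25, 0.75
#' uniform_grid(c(0, 0), c(1, 2), h = 0.5)  # 2 x 4 product grid
#' @export
uniform_grid <- function(lo, hi, h, names = NULL) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  d <- max(length(lo), length(hi), length(h))
  lo <- rep_len(lo, d); hi <- rep_len(hi, d); h <- rep_len(as.numeric(h), d)
  if (any(lo >= hi)) abort("`lo` must be strictly below `hi` on every axis.")
  if (any(h <= 0)) abort("`h` must be positive.")
  n <- round((hi - lo) / h)
  off <- abs((hi - lo) - n * h)
  if (any(off > 1e-9)) {
    a <- which(off > 1e-9)[1]
    abort(sprintf("axis %d: (hi - lo) = %g is not an integer multiple of h = %g.",
                  a, hi[a] - lo[a], h[a]))
  }
  names <- names %||% paste0("x", seq_len(d))
  centers <- lapply(seq_len(d), function(a) lo[a] + h[a] * (seq_len(n[a]) - 0.5))
  structure(list(lo = lo, hi = hi, h = h, n = as.integer(n), dim = d,
                 centers = setNames(centers, names), names = names),
            class = "uniform_grid")
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat("<uniform_grid> dim:", x$dim, " cells:", paste(x$n, collapse = " x "),
      "\n")
  for (a in seq_len(x$dim)) {
    cat(sprintf("  %s: [%g, %g] h = %g\n", x$names[a], x$lo[a], x$hi[a], x$h[a]))
  }
  invisible(x)
}

grid_metadata <- function(g) {
  list(lo = g$lo, hi = g$hi, h = g$h, n = g$n, names = g$names)
}

#' Cell centers of a uniform grid
#'
#' The flattened order is row-major over axes in declaration order (the first
#' axis varies slowest), fixed so serialized outputs are reproducible
#' bit-for-bit.
#'
#' @param grid A [uniform_grid()].
#' @return A tibble with one coordinate column per axis, one row per cell.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "uniform_grid"))
  do.call(tidyr::expand_grid, grid$centers)
}

#' @rdname grid_points
#' @export
cell_volume <- function(grid) prod(grid$h)

#' Node-inclusive profile grid
#'
#' Equally spaced values including both endpoints, as used for profiling a
#' likelihood over a parameter interval (e.g. 41 values on `[0, 2]` at spacing
#' 0.05). Distinct from the cell-centered [uniform_grid()] used for
#' quadrature.
#'
#' @param lo,hi Scalar interval bounds.
#' @param h Spacing; `(hi - lo)` must be an integer multiple.
#' @return Numeric vector `lo, lo + h, ..., hi`.
#' @examples
#' length(profile_points(0, 2, 0.05))  # 41
#' @export
profile_points <- function(lo, hi, h) {
  stopifnot(lo < hi, h > 0)
  n <- round((hi - lo) / h)
  if (abs((hi - lo) - n * h) > 1e-9) {
    abort(sprintf("(hi - lo) = %g is not an integer multiple of h = %g.",
                  hi - lo, h))
  }
  lo + h * (0:n)
}

#' Attach explicit density values to a uniform grid
#'
#' Builds a grid-attached `density_field` from values given in the grid's
#' flattened cell order, mainly for testing quadrature and marginalization
#' against closed forms.
#'
#' @param grid A [uniform_grid()].
#' @param density Non-negative values, one per cell (recycled if scalar).
#' @param time Time stamp for the field (default 0).
#' @return A `density_field`.
#' @examples
#' midpoint_integrate(as_density_field(uniform_grid(0, 1, 0.1), 1))  # 1
#' @export
as_density_field <- function(grid, density, time = 0) {
  stopifnot(inherits(grid, "uniform_grid"))
  n <- prod(grid$n)
  density <- rep_len(as.numeric(density), n)
  if (any(density < 0, na.rm = TRUE)) abort("`density` must be non-negative.")
  new_density_field(as.matrix(grid_points(grid)), log(density), time = time,
                    grid = grid, state_names = grid$names)
}

#' Midpoint-rule integral of a grid-attached density field
#'
#' Computes \eqn{\sum_i v(\xi_i) \prod_a h_a} over the cell centers. Exact
#' summation order is fixed by the grid's flattened order. Histogram
#' estimates are refused: quadrature is only meaningful for exact
#' characteristics values on a backward-forward grid.
#'
#' @param field A `density_field` with an attached [uniform_grid()].
#' @param values Column to integrate (default `"density"`).
#' @return The integral (scalar).
#' @examples
#' g <- uniform_grid(-8, 8, h = 0.01)
#' f <- density_at_points(vector_field(function(x) 0 * x, 1,
#'                                     divergence = function(x) 0),
#'                        normal_density(0, 1), g, time = 0)
#' midpoint_integrate(f)  # ~1
#' @export
midpoint_integrate <- function(field, values = "density") {
  stopifnot(inherits(field, "density_field"))
  g <- attr(field, "grid")
  if (is.null(g)) {
    abort("this density field has no attached grid; midpoint quadrature needs cell-centered values.",
          class = "liouville_capability_error")
  }
  if (isTRUE(attr(field, "estimate"))) {
    abort("this density field is a histogram estimate, not exact characteristics values; refusing quadrature.",
          class = "liouville_capability_error")
  }
  v <- field[[values]]
  if (anyNA(v)) abort("density field contains failed points (NA); resolve them before integrating.")
  sum(v) * cell_volume(g)
}

#' Marginalize a grid-attached density field
#'
#' Integrates out the dropped axes by the midpoint rule, e.g.
#' \eqn{u(x) = \int u(x, \beta)\, d\beta}, leaving a density field on the
#' sub-grid of kept axes. By associativity of the sum, integrating the
#' marginal over the kept axes reproduces the full integral exactly.
#'
#' @param field A grid-attached `density_field`.
#' @param keep Axes to keep: integer indices or axis names (a strict,
#'   non-empty subset).
#' @return A `density_field` on the sub-grid of the kept axes.
#' @export
marginalize <- function(field, keep) {
  stopifnot(inherits(field, "density_field"))
  g <- attr(field, "grid")
  if (is.null(g)) {
    abort("marginalization needs a grid-attached density field.",
          class = "liouville_capability_error")
  }
  if (is.character(keep)) keep <- match(keep, g$names)
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0) abort("`keep` must name at least one axis.")
  if (anyNA(keep) || any(keep < 1 | keep > g$dim)) abort("`keep` contains unknown axes.")
  if (length(keep) == g$dim) abort("`keep` must be a strict subset of the axes.")
  drop_vol <- prod(g$h[-keep])
  nm <- g$names[keep]
  out <- field |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(nm))) |>
    dplyr::summarise(density = sum(.data$density) * drop_vol, .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(nm)))
  sub <- uniform_grid(g$lo[keep], g$hi[keep], g$h[keep], names = nm)
  new_density_field(as.matrix(out[nm]), log(out$density),
                    time = attr(field, "time"), grid = sub, state_names = nm)
}

#' Probability mass of a region at a final time
#'
#' Runs the backward-forward procedure on the cell centers of `region` at
#' time `time` and integrates the resulting exact density values by the
#' midpoint rule. Because the density arrives exactly at the chosen points,
#' low-probability regions (such as the heavy tail left behind by a positive
#' feedback switch) are resolved with a handful of trajectories where a Monte
#' Carlo ensemble would need the reciprocal of the mass times the desired
#' point count.
#'
#' @param field A [vector_field()].
#' @param u0 An [initial_density].
#' @param region A [uniform_grid()] over the field's space.
#' @param time Final time.
#' @param settings A [solver_settings()].
#' @param max_fail_frac Abort if more than this fraction of cells fails.
#' @return The probability mass (scalar).
#' @examples
#' mass <- region_mass(autoregulation_model(), normal_density(2, 0.2),
#'                     uniform_grid(0, 10, h = 0.5), time = 10)
#' @export
region_mass <- function(field, u0, region, time, settings = solver_settings(),
                        max_fail_frac = 0.01) {
  stopifnot(inherits(region, "uniform_grid"))
  f <- density_at_points(field, u0, region, time, settings)
  failed <- f$status == "solver_error"
  if (mean(failed) > max_fail_frac) {
    abort(sprintf("%d of %d cells failed to solve (> %g%%); refusing to integrate. First failures at rows: %s",
                  sum(failed), nrow(f), 100 * max_fail_frac,
                  paste(head(which(failed), 5), collapse = ", ")))
  }
  if (any(failed)) {
    warn(sprintf("%d of %d cells failed; their density is treated as missing and excluded.",
                 sum(failed), nrow(f)))
    f$density[failed] <- 0
    f$log_density[failed] <- -Inf
  }
  sum(f$density) * cell_volume(region)
}

#' @rdname region_mass
#' @param halvings Number of times `h` is halved for the convergence check.
#' @return `region_mass_convergence()` returns a tibble with one row per
#'   resolution (`h`, `mass`, and `rel_change` against the previous row):
#'   the midpoint rule is second order, so on smooth densities the change
#'   should shrink ~4x per halving. Use it when the adequacy of a grid
#'   resolution is in doubt (e.g. coarse grids over wide parameter boxes).
#' @export
region_mass_convergence <- function(field, u0, region, time,
                                    settings = solver_settings(),
                                    halvings = 2) {
  hs <- region$h[1] / 2^(0:halvings)
  masses <- vapply(hs, function(h) {
    region_mass(field, u0,
                uniform_grid(region$lo, region$hi, region$h * h / region$h[1]),
                time, settings)
  }, numeric(1))
  tibble::tibble(h = hs, mass = masses,
                 rel_change = c(NA, abs(diff(masses)) / masses[-1]))
}

#' @rdname region_mass
#' @return `region_density()` returns the underlying grid-attached
#'   `density_field` instead of the integrated mass.
#' @export
region_density <- function(field, u0, region, time, settings = solver_settings()) {
  stopifnot(inherits(region, "uniform_grid"))
  density_at_points(field, u0, region, time, settings)
}
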