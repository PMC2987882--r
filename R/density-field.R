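# Density fields: a set of points at a common time with attached density
# values, optionally on a uniform grid (which makes them quadrature-eligible).

new_density_field <- function(points, log_values, time, status = NULL,
                              grid = NULL, state_names = NULL,
                              estimate = FALSE, extra = NULL) {
  d <- ncol(points)
  state_names <- state_names %||% colnames(points) %||% paste0("x", seq_len(d))
  df <- tibble::as_tibble(as.data.frame(points, optional = TRUE),
                          .name_repair = "minimal")
  names(df) <- state_names
  df$log_density <- log_values
  df$density <- exp(log_values)
  if (!is.null(status)) df$status <- status
  if (!is.null(extra)) df <- dplyr::bind_cols(df, extra)
  structure(df,
            class = c("density_field", class(tibble::tibble())),
            time = time, grid = grid, estimate = estimate,
            state_names = state_names)
}

#' Test and access density-field metadata
#'
#' A density field is a tibble of points at a common time with `log_density`
#' and `density` columns, carrying its evaluation time and (optionally) the
#' [uniform_grid()] its points are the cell centers of. Only grid-attached
#' fields can be integrated by the midpoint rule.
#'
#' @param x A density field as returned by [density_at_points()],
#'   [region_density()] or [histogram_density()].
#' @return `field_time()` the evaluation time; `field_grid()` the attached
#'   grid or `NULL`.
#' @export
field_time <- function(x) attr(x, "time")

#' @rdname field_time
#' @export
field_grid <- function(x) attr(x, "grid")

#' @export
print.density_field <- function(x, ...) {
  cat("<density_field> at time", attr(x, "time"),
      if (!is.null(attr(x, "grid"))) "(grid-attached)" else "(scattered)",
      if (isTRUE(attr(x, "estimate"))) "[estimate]", "\n")
  NextMethod()
}

#' Write a density field to CSV with a JSON metadata sidecar
#'
#' The CSV has one row per point with coordinate columns followed by
#' `log_density` and `density`, written in shortest round-trip numeric
#' representation so identical runs produce byte-identical files. The sidecar
#' records the evaluation time, grid axes, and any extra metadata supplied.
#'
#' @param x A density field.
#' @param file CSV path; the sidecar is written next to it as `<file>.json`
#'   unless `metadata_file` is given.
#' @param metadata_file Optional explicit sidecar path.
#' @param metadata Named list merged into the sidecar (model, settings, seed, ...).
#' @return `file`, invisibly.
#' @export
write_density_field <- function(x, file, metadata_file = NULL, metadata = list()) {
  stopifnot(inherits(x, "density_field"))
  readr::write_csv(tibble::as_tibble(x), file)
  g <- attr(x, "grid")
  meta <- c(list(time = attr(x, "time"),
                 n_points = nrow(x),
                 estimate = isTRUE(attr(x, "estimate")),
                 grid = if (!is.null(g)) grid_metadata(g)),
            metadata)
  jsonlite::write_json(meta, metadata_file %||% paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @export
tidy.density_field <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.density_field <- function(x, ...) {
  tibble::tibble(
    time = attr(x, "time"),
    n_points = nrow(x),
    grid_attached = !is.null(attr(x, "grid")),
    estimate = isTRUE(attr(x, "estimate")),
    total_mass = if (!is.null(attr(x, "grid")) && !isTRUE(attr(x, "estimate")))
      midpoint_integrate(x) else NA_real_,
    max_density = max(x$density, na.rm = TRUE)
  )
}

#' Plot a density field
#'
#' One-dimensional fields are drawn as a density curve; two-dimensional
#' grid-attached fields as a filled raster.
#'
#' @param object A density field.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_field <- function(object, ...) {
  nm <- attr(object, "state_names")
  d <- length(nm)
  if (d == 1L) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[nm[1]]], y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = sprintf("density at t = %g", attr(object, "time")))
  } else if (d == 2L && !is.null(attr(object, "grid"))) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                         fill = .data$density)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(fill = sprintf("u(t = %g)", attr(object, "time")))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                         colour = .data$density)) +
      ggplot2::geom_point() +
      ggplot2::scale_colour_viridis_c()
  }
}
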