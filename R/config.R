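#' Read, validate and write run configurations
#'
#' A run configuration is a single YAML document describing one task:
#' `propagate`, `region_mass`, `marginal`, `likelihood`, `profile` or
#' `mc_compare`. It names a built-in model with parameter overrides, an
#' initial density (a list of independent blocks forming a product), the
#' task-specific blocks (grids, times, data, profile grid, sample count), and
#' optional `settings` (`rel_tol`, `abs_tol`) and `seed`. See the files under
#' `system.file("extdata/configs", package = "liouville")` for complete
#' examples.
#'
#' @param path YAML file path (for `read_run_config()` / `write_run_config()`).
#' @param config A config list (as returned by `read_run_config()`).
#' @return `read_run_config()` returns a validated config list of class
#'   `run_config`; `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

run_tasks <- c("propagate", "region_mass", "marginal", "likelihood",
               "profile", "mc_compare")

cfg_abort <- function(field, msg) {
  abort(sprintf("config field `%s`: %s", field, msg),
        class = "liouville_config_error")
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) cfg_abort("(root)", "must be a mapping.")
  task <- config$task
  if (is.null(task) || length(task) != 1 || !task %in% run_tasks) {
    cfg_abort("task", sprintf("must be exactly one of %s.",
                              paste(run_tasks, collapse = ", ")))
  }
  if (is.null(config$model$name)) cfg_abort("model.name", "is required.")
  # resolves the model now so unknown names/parameters fail at parse time
  pars <- resolve_params(config$model$name, config$model$params %||% list())
  if (!is.null(config$extend) &&
      !all(unlist(config$extend) %in% names(pars))) {
    cfg_abort("extend", "lists parameters the model does not have.")
  }
  if (is.null(config$initial_density)) {
    cfg_abort("initial_density", "is required.")
  }
  build_density_from_config(config$initial_density)
  need <- switch(task,
                 propagate = c("initial_grid", "times"),
                 region_mass = c("region", "time"),
                 marginal = c("grid", "time", "keep"),
                 likelihood = "data",
                 profile = c("profile", "data"),
                 mc_compare = c("grid", "time", "n_samples"))
  for (f in need) {
    if (is.null(config[[f]])) cfg_abort(f, sprintf("is required for task '%s'.", task))
  }
  if (task %in% c("likelihood", "profile")) {
    d <- config$data
    if (is.null(d$time)) cfg_abort("data.time", "is required.")
    vals <- config_data_values(d)
    if (length(vals) == 0) cfg_abort("data.values", "must contain at least one observation.")
  }
  if (task == "profile") {
    p <- config$profile
    for (f in c("parameter", "lo", "hi", "h")) {
      if (is.null(p[[f]])) cfg_abort(paste0("profile.", f), "is required.")
    }
  }
  structure(config, class = "run_config")
}

config_data_values <- function(d) {
  if (!is.null(d$csv)) {
    df <- readr::read_csv(d$csv, show_col_types = FALSE)
    as.matrix(df[setdiff(names(df), "time")])
  } else {
    v <- d$values
    if (is.list(v)) do.call(rbind, lapply(v, as.numeric)) else as.numeric(v)
  }
}

build_density_from_config <- function(blocks) {
  if (!is.null(blocks$kind)) blocks <- list(blocks)  # single block shortcut
  parts <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    fld <- sprintf("initial_density[%d]", i)
    kind <- b$kind %||% cfg_abort(fld, "needs a `kind`.")
    switch(kind,
           normal = {
             if (is.null(b$mean)) cfg_abort(fld, "normal block needs `mean`.")
             cov <- if (!is.null(b[["cov"]])) {
               matrix(unlist(b[["cov"]]), nrow = length(b$mean))
             } else {
               b[["cov_diag"]] %||% cfg_abort(fld, "normal block needs `cov_diag` or `cov`.")
             }
             normal_density(as.numeric(b$mean), cov)
           },
           exponential = exponential_density(b$mean %||% cfg_abort(fld, "exponential block needs `mean`.")),
           uniform = uniform_density(
             b$lower %||% cfg_abort(fld, "uniform block needs `lower`."),
             b$upper %||% cfg_abort(fld, "uniform block needs `upper`.")),
           cfg_abort(fld, sprintf("unknown kind '%s'.", kind)))
  })
  product_density(parts)
}

grid_from_config <- function(axes, fld = "grid") {
  if (!is.null(axes$axes)) axes <- axes$axes
  if (!is.null(axes$lo)) axes <- list(axes)
  lo <- vapply(axes, function(a) as.numeric(a$lo), numeric(1))
  hi <- vapply(axes, function(a) as.numeric(a$hi), numeric(1))
  h <- vapply(axes, function(a) as.numeric(a$h), numeric(1))
  uniform_grid(lo, hi, h)
}

settings_from_config <- function(config, tol = NULL) {
  s <- config$settings %||% list()
  solver_settings(rel_tol = tol %||% s$rel_tol %||% 1e-8,
                  abs_tol = s$abs_tol %||% 1e-10,
                  max_step = s$max_step)
}

#' Execute a run configuration
#'
#' Runs the configured task and writes its outputs (CSV results, a JSON
#' summary, and a JSON log with settings, seed, package version and wall
#' time) into `outdir`. Identical configurations produce byte-identical CSV
#' outputs; stochastic tasks are identical given the seed.
#'
#' @param config A `run_config` (from [read_run_config()]) or a path to a
#'   YAML file.
#' @param outdir Output directory (created if missing).
#' @param seed Optional integer overriding the config's seed.
#' @param tol Optional relative tolerance overriding the config's settings.
#' @return Invisibly, a list with the task `summary` and the paths written.
#' @export
run_config <- function(config, outdir, seed = NULL, tol = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  seed <- seed %||% config$seed
  settings <- settings_from_config(config, tol)
  # `extend` lifts the model to the joint (state, parameter) space, with the
  # listed parameters drawn from the initial density's trailing coordinates
  field <- if (!is.null(config$extend)) {
    extend_state(build_parametric(config$model$name,
                                  free = unlist(config$extend),
                                  params = config$model$params %||% list()))
  } else {
    build_model(config$model$name, config$model$params %||% list())
  }
  u0 <- build_density_from_config(config$initial_density)
  task <- config$task
  paths <- character()
  meta <- list(model = config$model$name,
               params = as.list(resolve_params(config$model$name,
                                               config$model$params %||% list())),
               task = task, seed = seed,
               settings = list(rel_tol = settings$rel_tol,
                               abs_tol = settings$abs_tol))

  summary <- switch(
    task,
    propagate = {
      grid <- grid_from_config(config$initial_grid, "initial_grid")
      times <- config_times(config$times)
      tr <- propagate_density(field, u0, grid, times, settings)
      p <- file.path(outdir, "trajectories.csv")
      write_trajectories(tr, p, metadata = meta)
      paths <- p
      list(n_trajectories = length(unique(tr$id)), times = times)
    },
    region_mass = {
      region <- grid_from_config(config$region, "region")
      f <- region_density(field, u0, region, config$time, settings)
      mass <- midpoint_integrate(f)
      p <- file.path(outdir, "region_density.csv")
      write_density_field(f, p, metadata = meta)
      paths <- p
      list(time = config$time, mass = mass, n_cells = nrow(f))
    },
    marginal = {
      grid <- grid_from_config(config$grid)
      f <- density_at_points(field, u0, grid, config$time, settings)
      keep <- config$keep
      mg <- marginalize(f, if (is.character(keep)) keep else as.integer(keep))
      p <- file.path(outdir, "marginal_density.csv")
      write_density_field(mg, p, metadata = meta)
      paths <- p
      list(time = config$time, keep = keep,
           total_mass = midpoint_integrate(mg))
    },
    likelihood = {
      obs <- observation_set(config$data$time, config_data_values(config$data))
      ll <- likelihood_of_data(field, u0, obs, settings)
      p <- file.path(outdir, "likelihood_points.csv")
      write_density_field(ll$points, p, metadata = meta)
      paths <- p
      list(time = obs$time, n_obs = obs$n,
           log_likelihood = ll$log_likelihood)
    },
    profile = {
      pc <- config$profile
      model <- build_parametric(config$model$name, free = pc$parameter,
                                params = config$model$params %||% list())
      obs <- observation_set(config$data$time, config_data_values(config$data))
      vals <- profile_points(pc$lo, pc$hi, pc$h)
      pr <- profile_parameter(model, u0, obs, vals, settings)
      p <- file.path(outdir, "profile.csv")
      write_profile(pr, p, metadata = meta)
      paths <- p
      mx <- attr(pr, "maximizer")
      list(parameter = pc$parameter, n_values = nrow(pr),
           maximizer = if (!is.null(mx)) as.list(mx$value),
           max_log_likelihood = if (!is.null(mx)) mx$log_likelihood,
           gap = if (!is.null(mx)) mx$gap)
    },
    mc_compare = {
      grid <- grid_from_config(config$grid)
      cmp <- mc_compare(field, u0, grid, n = config$n_samples,
                        time = config$time, seed = seed, settings = settings)
      p <- file.path(outdir, "mc_compare.csv")
      readr::write_csv(cmp, p)
      paths <- p
      pop <- cmp$count >= 10
      list(time = config$time, n_samples = config$n_samples,
           n_cells = nrow(cmp), n_populated = sum(pop),
           max_abs_z_populated = if (any(pop)) max(abs(cmp$z[pop])) else NA)
    })

  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(c(meta, summary), summary_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_path <- file.path(outdir, "log.json")
  jsonlite::write_json(
    c(meta, list(package_version = as.character(utils::packageVersion("liouville")),
                 r_version = R.version.string,
                 wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    log_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(summary = summary, paths = c(paths, summary_path, log_path)))
}

config_times <- function(tm) {
  if (is.list(tm) && !is.null(tm$from)) {
    seq(tm$from, tm$to, by = tm$by)
  } else {
    as.numeric(unlist(tm))
  }
}
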