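test_that("cell-centered grids have the stated centers and counts", {
  g <- uniform_grid(0, 1, 0.5)
  expect_equal(g$centers$x1, c(0.25, 0.75))

  g2 <- uniform_grid(0, 10, 0.1)
  expect_equal(g2$n, 100L)
  expect_equal(g2$centers$x1[1], 0.05)
  expect_equal(g2$centers$x1[100], 9.95)
  expect_true(all(g2$centers$x1 > 0 & g2$centers$x1 < 10))

  g3 <- uniform_grid(c(0.5, 3.5), c(1.5, 4.5), 0.01)
  expect_equal(g3$n, c(100L, 100L))
  expect_equal(nrow(grid_points(g3)), 10000L)

  expect_error(uniform_grid(0, 1, 0.3), "axis 1")
  expect_error(uniform_grid(1, 0, 0.1), "strictly below")
})

test_that("grid point order is row-major in declaration order", {
  g <- uniform_grid(c(0, 0), c(1, 2), c(0.5, 0.5))
  pts <- grid_points(g)
  # first axis varies slowest
  expect_equal(pts$x1, rep(c(0.25, 0.75), each = 4))
  expect_equal(pts$x2, rep(c(0.25, 0.75, 1.25, 1.75), times = 2))
})

test_that("profile grids are node-inclusive", {
  v <- profile_points(0, 2, 0.05)
  expect_length(v, 41)
  expect_equal(v[1], 0)
  expect_equal(v[41], 2)
  expect_error(profile_points(0, 1, 0.3), "integer multiple")
})

test_that("midpoint quadrature matches closed forms", {
  expect_equal(midpoint_integrate(as_density_field(uniform_grid(0, 1, 0.1), 1)), 1)

  g <- uniform_grid(-8, 8, 0.01)
  f <- as_density_field(g, dnorm(g$centers$x1))
  expect_equal(midpoint_integrate(f), 1, tolerance = 1e-6)

  gq <- uniform_grid(0, 1, 0.25)
  fq <- as_density_field(gq, gq$centers$x1^2)
  expect_equal(midpoint_integrate(fq), 21 / 64)

  scattered <- density_at_points(decay_field(), normal_density(0, 1),
                                 c(0, 1), time = 0.5)
  expect_error(midpoint_integrate(scattered),
               class = "liouville_capability_error")
})

test_that("marginalization preserves total mass and separates products", {
  g <- uniform_grid(c(-4, 0), c(4, 2), c(0.1, 0.1))
  pts <- grid_points(g)
  vals <- dnorm(pts$x1) * dunif(pts$x2, 0, 2)
  f <- as_density_field(g, vals)
  mx <- marginalize(f, "x1")
  # separability: marginal proportional to the x1 factor
  expect_equal(mx$density, dnorm(mx$x1) * sum(dunif(g$centers$x2, 0, 2)) * 0.1,
               tolerance = 1e-12)
  # integrating the marginal equals integrating the full field (up to
  # floating-point reassociation of the sum)
  expect_equal(midpoint_integrate(mx), midpoint_integrate(f),
               tolerance = 1e-13)
  # both marginalization orders agree on the total
  my <- marginalize(f, 2)
  expect_equal(midpoint_integrate(my), midpoint_integrate(mx), tolerance = 1e-14)
  expect_error(marginalize(f, integer()), "at least one")
  expect_error(marginalize(f, c(1, 2)), "strict subset")
})

test_that("region mass at time zero recovers the initial normalization", {
  mass <- region_mass(autoregulation_model(), normal_density(2, 0.2),
                      uniform_grid(0, 6, 0.02), time = 0)
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("region mass matches the normal CDF for linear decay", {
  # u0 = N(0,1), dx/dt = -x: at t = 1 the state is N(0, e^{-2})
  f <- decay_field(1)
  u0 <- normal_density(0, 1)
  lim <- 4 * exp(-1)
  exact <- pnorm(lim, sd = exp(-1)) - pnorm(-lim, sd = exp(-1))
  expect_equal(exact, 0.9999367, tolerance = 1e-5)
  mass <- region_mass(f, u0, uniform_grid(-lim, lim, lim / 20), time = 1)
  expect_equal(mass, exact, tolerance = 1e-4)

  # quadrature convergence: halving h shrinks the error ~4x (midpoint is O(h^2))
  conv <- region_mass_convergence(f, u0, uniform_grid(-lim, lim, lim / 10),
                                  time = 1, halvings = 2)
  errs <- abs(conv$mass - exact)
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 2.5 & ratios < 6))
  expect_true(all(diff(abs(conv$rel_change[-1])) <= 0))
})

test_that("density fields serialize to CSV with a JSON sidecar", {
  g <- uniform_grid(0, 1, 0.25)
  f <- as_density_field(g, c(1, 2, 3, 4) / 2.5, time = 2)
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "field.csv")
  write_density_field(f, p, metadata = list(model = "test"))
  expect_true(file.exists(p))
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(back$density, f$density)
  expect_equal(back$x1, g$centers$x1)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$time, 2)
  expect_equal(meta$model, "test")
  expect_equal(unlist(meta$grid$h), 0.25)
})
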