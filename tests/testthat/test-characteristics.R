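test_that("density grows at rate +1 along contracting linear decay", {
  tr <- propagate_pair(decay_field(1), x0 = 1, log_rho0 = 0, times = c(0, 1),
                       settings = tight)
  expect_equal(tr$x1[2], exp(-1), tolerance = 1e-9)
  expect_equal(tr$log_density[2], 1, tolerance = 1e-9)
})

test_that("density is constant along divergence-free rotation", {
  tr <- propagate_pair(rotation_field(), c(1, 0), log_rho0 = -0.7,
                       times = seq(0, 2, by = 0.5))
  expect_equal(tr$log_density, rep(-0.7, 5), tolerance = 1e-8)
  # states follow the closed-form rotation
  expect_equal(tr$x1, cos(tr$time), tolerance = 1e-7)
  expect_equal(tr$x2, sin(tr$time), tolerance = 1e-7)
})

test_that("a -Inf initial log-density short-circuits but states propagate", {
  tr <- propagate_pair(decay_field(), 1, -Inf, c(0, 1))
  expect_equal(tr$log_density, c(-Inf, -Inf))
  expect_equal(tr$density, c(0, 0))
  expect_equal(tr$x1[2], exp(-1), tolerance = 1e-7)
})

test_that("output times must start at zero and increase", {
  expect_error(propagate_pair(decay_field(), 1, 0, c(1, 2)), "start at 0")
  expect_error(propagate_pair(decay_field(), 1, 0, c(0, 2, 1)), "increasing")
})

test_that("backward map inverts the flow", {
  expect_equal(backward_map(decay_field(), 5, time = 0), 5)
  expect_equal(backward_map(decay_field(), exp(-1), time = 1), 1,
               tolerance = 1e-7)
  # round trip on the autoregulation model from the observation used for
  # parameter estimation: xT = 5 at T = 20
  f <- autoregulation_model()
  x0 <- backward_map(f, 5, time = 20)
  fwd <- liouville:::flow_points(f, matrix(x0, 1, 1), 20,
                                 solver_settings(), direction = 1)
  expect_equal(as.numeric(fwd$states), 5, tolerance = 1e-6)
})

test_that("round trips hold across built-in models at random points", {
  set <- list(list(f = autoregulation_model(), lo = 1, hi = 10, t = 20),
              list(f = toggle_switch_model(), lo = 0.5, hi = 4, t = 5))
  withr::with_seed(21, {
    for (cs in set) {
      pts <- matrix(runif(10 * cs$f$dim, cs$lo, cs$hi), ncol = cs$f$dim)
      x0 <- backward_map(cs$f, pts, time = cs$t)
      fwd <- liouville:::flow_points(cs$f, x0, cs$t, solver_settings(),
                                     direction = 1)
      expect_lt(max(abs(fwd$states - pts) / pmax(1, abs(pts))), 1e-6)
    }
  })
})

test_that("density_at_points at time zero returns the initial density", {
  u0 <- normal_density(2, 0.2)
  f <- autoregulation_model()
  q <- c(1, 2, 3)
  out <- density_at_points(f, u0, q, time = 0)
  expect_equal(out$log_density, log_density(u0, matrix(q)))
  expect_true(all(out$status == "ok"))
})

test_that("linear decay density matches the closed-form pushforward", {
  # dx/dt = -k x with u0 = N(0,1): u(t, x) = e^{kt} phi(x e^{kt})
  k <- 0.8; t <- 1.3
  f <- decay_field(k)
  q <- seq(-1, 1, by = 0.25)
  out <- density_at_points(f, normal_density(0, 1), q, time = t)
  expect_equal(out$density, exp(k * t) * dnorm(q * exp(k * t)),
               tolerance = 1e-7)
})

test_that("2-D linear flow reproduces the exact normal pushforward", {
  skip_if_not_installed("Matrix")
  A <- matrix(c(-0.4, 0.3, -0.2, -0.5), 2)
  t1 <- 1
  mu0 <- c(1, -0.5)
  S0 <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  eA <- as.matrix(Matrix::expm(A * t1))
  mu1 <- as.numeric(eA %*% mu0)
  S1 <- eA %*% S0 %*% t(eA)
  withr::with_seed(31, {
    q <- MASS::mvrnorm(50, mu1, S1)  # query points where the density is live
  })
  out <- density_at_points(linear_field(A), normal_density(mu0, S0), q,
                           time = t1, settings = tight)
  expected <- vapply(seq_len(50), function(i) mvn_logpdf(q[i, ], mu1, S1), 1)
  expect_equal(out$log_density, expected, tolerance = 1e-6)
})

test_that("points with zero-density pre-image are reported without solving", {
  f <- decay_field(1)
  u0 <- uniform_density(0.5, 1.5)
  # at t = 1 the support maps to [0.5, 1.5] * e^{-1}; query far outside
  out <- density_at_points(f, u0, c(0.2, 3), time = 1)
  expect_equal(out$status, c("ok", "zero_density"))
  expect_equal(out$density[2], 0)
  expect_gt(out$density[1], 0)
})

test_that("semigroup: two-stage propagation equals one-stage", {
  f <- autoregulation_model()
  u0 <- normal_density(2, 0.2)
  x0 <- 2.4
  lr0 <- log_density(u0, x0)
  one <- propagate_pair(f, x0, lr0, c(0, 30))
  a <- propagate_pair(f, x0, lr0, c(0, 12))
  b <- propagate_pair(f, as.numeric(a$x[2]), a$log_density[2], c(0, 18))
  expect_equal(b$x[2], one$x[2], tolerance = 1e-6)
  expect_equal(b$log_density[2], one$log_density[2], tolerance = 1e-6)
})

test_that("forward grid propagation is consistent with backward-forward", {
  f <- toggle_switch_model()
  u0 <- normal_density(c(3, 3), c(0.1, 0.1))
  x0 <- as.matrix(expand.grid(x1 = seq(2.6, 3.4, 0.4), x2 = seq(2.6, 3.4, 0.4)))
  tr <- propagate_density(f, u0, x0, times = c(0, 2), settings = tight)
  end <- dplyr::filter(tr, time == 2)
  back <- density_at_points(f, u0, as.matrix(end[c("x1", "x2")]), time = 2,
                            settings = tight)
  expect_equal(back$density, end$density, tolerance = 1e-8)
})

test_that("constant fields transport density unchanged", {
  f <- constant_field(2)
  u0 <- normal_density(0, 1)
  tr <- propagate_density(f, u0, matrix(c(-1, 0, 1)), times = c(0, 1, 3))
  by_id <- split(tr$log_density, tr$id)
  for (v in by_id) expect_equal(diff(range(v)), 0, tolerance = 1e-9)
  expect_equal(dplyr::filter(tr, id == 2)$x1, c(0, 2, 6), tolerance = 1e-8)
})

test_that("forward propagation from an initial grid covers the transported bulk", {
  f <- autoregulation_model()
  u0 <- normal_density(2, 0.2)
  x0 <- profile_points(0, 5, 0.05)  # 101 discretization points
  tr <- propagate_density(f, u0, matrix(x0), times = c(0, 50))
  expect_equal(length(unique(tr$id)), 101)
  end <- dplyr::filter(tr, time == 50)
  expect_true(all(end$status == "ok"))
  # characteristics cannot cross: order of states is preserved
  expect_true(all(diff(end$x[order(x0)]) > 0))
  # the bulk (started above the unstable threshold) has moved far up
  expect_gt(max(end$x), 30)
})

test_that("total probability is conserved under autoregulation transport", {
  mass <- region_mass(autoregulation_model(), normal_density(2, 0.2),
                      uniform_grid(0, 60, h = 0.25), time = 50)
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("total probability is conserved under toggle-switch transport", {
  f <- toggle_switch_model()
  u0 <- normal_density(c(3, 3), c(0.1, 0.1))
  # locate the support at t = 1 from a propagated sample cloud, then
  # quadrature the exact density on a grid padded around it
  ens <- monte_carlo_ensemble(f, u0, 400, time = 1, seed = 17)
  lo <- floor((apply(ens$points, 2, min) - 0.4) * 10) / 10
  hi <- ceiling((apply(ens$points, 2, max) + 0.4) * 10) / 10
  g <- uniform_grid(lo, hi, h = (hi - lo) / 60)
  mass <- region_mass(f, u0, g, time = 1)
  expect_equal(mass, 1, tolerance = 1e-3)
})
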