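test_that("built-in model right-hand sides match hand-computed values", {
  f <- autoregulation_model(V_max = 1, K = 2, k_d = 0.01, beta = 4)
  expect_equal(eval_rhs(f, 2), 1 * 16 / (16 + 16) - 0.01 * 2)  # 0.48
  expect_equal(eval_rhs(f, 2), 0.48)
  expect_equal(field_divergence(f, 2), 512 / 1024 - 0.01)      # 0.49

  g <- toggle_switch_model()
  expect_equal(eval_rhs(g, c(3, 3)), c(5 / (1 + 9) - 3, 5 / (1 + 9) - 3))
  expect_equal(field_divergence(g, c(3, 3)), -2)

  zero <- vector_field(function(x) numeric(2), dim = 2)
  expect_equal(eval_rhs(zero, c(3, -7)), c(0, 0))

  expect_equal(field_divergence(decay_field(1), 0.37), -1)
  expect_equal(field_divergence(rotation_field(), c(2, -1)), 0)
})

test_that("construction and evaluation reject bad input", {
  expect_error(eval_rhs(autoregulation_model(), c(1, 2)), "length")
  expect_error(eval_rhs(autoregulation_model(), -1),
               class = "liouville_domain_error")
  expect_error(eval_rhs(toggle_switch_model(), c(1, -0.5)), "x2")
  expect_error(vector_field(function(t, x) -x, dim = 1), "autonomous")
  expect_error(autoregulation_model(V_max = -1), "positive")
  expect_error(toggle_switch_model(k_d = 0), "positive")
  expect_error(build_model("autoregulation", list(vmax = 2)), "unknown")
  expect_error(build_model("lorenz"), "unknown model")
})

test_that("analytic divergence agrees with finite-difference Jacobian trace", {
  withr::with_seed(42, {
    for (cs in list(list(f = autoregulation_model(), lo = 0.05, hi = 60, d = 1),
                      list(f = toggle_switch_model(), lo = 0.05, hi = 6, d = 2))) {
      pts <- matrix(runif(100 * cs$d, cs$lo, cs$hi), ncol = cs$d)
      for (i in seq_len(100)) {
        x <- pts[i, ]
        expect_equal(cs$f$divergence(x),
                     liouville:::fd_divergence(cs$f$rhs, x),
                     tolerance = 1e-6)
      }
    }
  })
})

test_that("finite-difference fallback is used when no divergence is declared", {
  f <- vector_field(function(x) c(x[1]^2, -3 * x[2]), dim = 2)
  expect_equal(field_divergence(f, c(2, 1)), 2 * 2 - 3, tolerance = 1e-7)
})

test_that("extending a parametric model stacks zeros over the parameters", {
  m <- build_parametric("autoregulation", free = "V_max")
  f <- extend_state(m)
  expect_equal(f$dim, 2)
  expect_equal(eval_rhs(f, c(2, 1)), c(0.48, 0))
  # divergence of the extended field is the state divergence alone
  expect_equal(field_divergence(f, c(2, 1)), 0.49)

  tg <- parametric_model(
    function(z, p) {
      c(p[1] / (1 + z[2]^2) - z[1], p[2] / (1 + z[1]^2) - z[2])
    }, state_dim = 2, param_names = c("alpha1", "alpha2"))
  ext <- extend_state(tg)
  expect_equal(eval_rhs(ext, c(3, 3, 5, 5)), c(-2.5, -2.5, 0, 0))
})

test_that("extension with no parameters behaves like the plain model", {
  m <- parametric_model(function(z, p) -z, state_dim = 1)
  f <- extend_state(m)
  expect_equal(f$dim, 1)
  expect_equal(eval_rhs(f, 2), -2)
})

test_that("projection of the extended rhs reproduces the parametric rhs", {
  m <- build_parametric("toggle_switch", free = c("alpha1", "k_d"))
  f <- extend_state(m)
  withr::with_seed(7, {
    for (i in 1:20) {
      z <- runif(2, 0, 5); p <- runif(2, 0.5, 3)
      expect_identical(eval_rhs(f, c(z, p))[1:2], m$rhs(z, p))
      expect_identical(eval_rhs(f, c(z, p))[3:4], c(0, 0))
    }
  })
})

test_that("autoregulation saturates to constant synthesis at large x", {
  f <- autoregulation_model()
  x <- 1e6
  expect_equal(eval_rhs(f, x), 1 - 0.01 * x, tolerance = 1e-10)
  expect_equal(eval_rhs(f, 0), 0)
  expect_equal(field_divergence(f, 0), -0.01)
})

test_that("toggle switch symmetry and equilibrium residual", {
  f <- toggle_switch_model()
  a <- c(1.2, 3.4)
  expect_equal(eval_rhs(f, a), rev(eval_rhs(f, rev(a))))
  # symmetric fixed point from a root-finding oracle on x(1 + x^2) = alpha
  root <- uniroot(function(x) 5 / (1 + x^2) - x, c(1, 2), tol = 1e-12)$root
  expect_lt(max(abs(eval_rhs(f, c(root, root)))), 1e-9)
})

test_that("vectorized and scalar rhs paths agree", {
  for (f in list(autoregulation_model(), toggle_switch_model(),
                 extend_state(build_parametric("autoregulation", free = "V_max")))) {
    withr::with_seed(11, X <- matrix(runif(f$dim * 8, 0.1, 5), nrow = f$dim))
    batch <- liouville:::rhs_at(f, X)
    for (j in seq_len(ncol(X))) {
      expect_equal(batch[, j], as.numeric(f$rhs(X[, j])))
    }
    expect_equal(liouville:::div_at(f, X),
                 vapply(seq_len(ncol(X)), function(j) f$divergence(X[, j]), 1))
  }
})
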