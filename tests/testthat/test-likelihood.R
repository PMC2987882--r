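test_that("likelihood at time zero is the prior density at the data", {
  ll <- likelihood_of_data(decay_field(), normal_density(0, 1),
                           observation_set(0, 0))
  expect_equal(exp(ll$log_likelihood), 1 / sqrt(2 * pi))
})

test_that("independent identical data points multiply the likelihood", {
  f <- autoregulation_model()
  u0 <- normal_density(2, 0.2)
  one <- likelihood_of_data(f, u0, observation_set(20, 5))
  two <- likelihood_of_data(f, u0, observation_set(20, c(5, 5)))
  expect_equal(two$log_likelihood, 2 * one$log_likelihood, tolerance = 1e-10)
})

test_that("likelihood equals the product of pointwise densities", {
  f <- autoregulation_model()
  u0 <- normal_density(2, 0.2)
  obs <- observation_set(20, c(4, 5, 6))
  ll <- likelihood_of_data(f, u0, obs)
  ref <- density_at_points(f, u0, obs$points, 20)
  expect_gt(exp(ll$log_likelihood), 0)
  expect_equal(ll$log_likelihood, sum(ref$log_density), tolerance = 1e-12)
})

test_that("observation sets validate their input", {
  expect_error(observation_set(20, numeric(0)), "at least one")
  expect_error(observation_set(20, c(1, NA)), "finite")
  expect_error(observation_set(-1, 5), "time")
  expect_error(likelihood_of_data(toggle_switch_model(),
                                  normal_density(c(3, 3), c(0.1, 0.1)),
                                  observation_set(1, 5)),
               "full-state")
})

test_that("profiling V_max reproduces both prior scenarios", {
  m <- build_parametric("autoregulation", free = "V_max")
  obs <- observation_set(20, 5)
  vals <- profile_points(0, 2, 0.05)

  pa <- profile_parameter(m, normal_density(c(2, 1), c(0.2, 0.01)), obs, vals)
  expect_s3_class(pa, "likelihood_profile")
  expect_true(all(pa$ok))
  mle_a <- mle_from_profile(pa)
  expect_lt(abs(mle_a[["V_max"]] - 1), 0.05 + 1e-12)

  pb <- profile_parameter(
    m, product_density(normal_density(2, 0.2), uniform_density(0, 2)),
    obs, vals)
  mle_b <- mle_from_profile(pb)
  expect_lt(abs(mle_b[["V_max"]] - 0.2), 0.05 + 1e-12)
})

test_that("a parameter absent from the dynamics yields a flat profile", {
  m <- parametric_model(function(z, p) -z, state_dim = 1, param_names = "mu",
                        divergence = function(z, p) -1)
  u0 <- product_density(normal_density(0, 1), uniform_density(0, 1))
  expect_warning(
    pr <- profile_parameter(m, u0, observation_set(1, 0.2),
                            profile_points(0, 1, 0.25)),
    class = "liouville_flat_profile_warning")
  expect_equal(mle_from_profile(pr)[["mu"]], 0)  # tie toward smallest value
})

test_that("argmax extraction breaks ties toward the smallest value", {
  fm <- liouville:::find_maximizer
  V <- matrix(c(0.5, 1.0, 1.5), ncol = 1)
  res <- fm(V, c(-3, -1, -2), rep(TRUE, 3), "p")
  expect_equal(res$value[["p"]], 1.0)
  expect_equal(res$gap, 1)
  tie <- fm(V, c(-1, -5, -1), rep(TRUE, 3), "p")
  expect_equal(tie$value[["p"]], 0.5)
  # missing entries are skipped
  skip1 <- fm(V, c(NA, -4, -2), c(FALSE, TRUE, TRUE), "p")
  expect_equal(skip1$value[["p"]], 1.5)
})

test_that("estimation fails cleanly when no value has finite likelihood", {
  m <- parametric_model(function(z, p) -z, state_dim = 1, param_names = "mu",
                        divergence = function(z, p) -1)
  # prior support nowhere near the data pre-image: all likelihoods are zero
  u0 <- product_density(uniform_density(100, 101), uniform_density(0, 1))
  pr <- profile_parameter(m, u0, observation_set(1, 0.2),
                          profile_points(0, 1, 0.5))
  expect_error(mle_from_profile(pr), class = "liouville_estimation_error")
})

test_that("the prior pulls the estimate to its mean as its variance shrinks", {
  m <- build_parametric("autoregulation", free = "V_max")
  obs <- observation_set(20, 5)
  vals <- profile_points(0, 2, 0.05)
  mles <- vapply(c(0.01, 0.001, 1e-4), function(v) {
    p <- profile_parameter(m, normal_density(c(2, 1), c(0.2, v)), obs, vals)
    mle_from_profile(p)[["V_max"]]
  }, numeric(1))
  expect_lt(abs(mles[2] - 1), 0.05 + 1e-12)
  expect_lt(abs(mles[3] - 1), 0.05 + 1e-12)
  expect_true(all(diff(abs(mles - 1)) <= 0))
})

test_that("refinement sharpens the maximizer inside one coarse grid step", {
  m <- build_parametric("autoregulation", free = "V_max")
  u0 <- normal_density(c(2, 1), c(0.2, 0.01))
  obs <- observation_set(20, 5)
  coarse <- profile_parameter(m, u0, obs, profile_points(0, 2, 0.25))
  v0 <- mle_from_profile(coarse)[["V_max"]]
  fine <- refine_profile(m, u0, obs, coarse, factor = 10)
  v1 <- mle_from_profile(fine)[["V_max"]]
  expect_lte(abs(v1 - v0), 0.25)
  expect_gte(attr(mle_from_profile(fine), "log_likelihood"),
             attr(mle_from_profile(coarse), "log_likelihood"))
})

test_that("profiles tidy, glance and serialize", {
  m <- build_parametric("autoregulation", free = "V_max")
  pr <- profile_parameter(m, normal_density(c(2, 1), c(0.2, 0.01)),
                          observation_set(20, 5), profile_points(0.5, 1.5, 0.25))
  td <- tidy(pr)
  expect_named(td, c("V_max", "log_likelihood", "ok"))
  gl <- glance(pr)
  expect_equal(gl$n_values, 5L)
  expect_true(is.finite(gl$max_log_likelihood))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "profile.csv")
  write_profile(pr, p)
  expect_equal(nrow(readr::read_csv(p, show_col_types = FALSE)), 5)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$maximizer$V_max, gl$mle_V_max)
})
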