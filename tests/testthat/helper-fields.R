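# Reference fields and oracles shared across tests.

decay_field <- function(k = 1) {
  vector_field(function(x) -k * x, dim = 1, divergence = function(x) -k,
               vectorized = TRUE, name = "linear decay")
}

rotation_field <- function() {
  vector_field(function(x) {
    if (is.matrix(x)) rbind(-x[2, ], x[1, ]) else c(-x[2], x[1])
  }, dim = 2, divergence = function(x) {
    if (is.matrix(x)) rep(0, ncol(x)) else 0
  }, vectorized = TRUE, name = "planar rotation")
}

constant_field <- function(c0 = 1.5) {
  vector_field(function(x) {
    if (is.matrix(x)) matrix(c0, 1, ncol(x)) else c0
  }, dim = 1, divergence = function(x) {
    if (is.matrix(x)) rep(0, ncol(x)) else 0
  }, vectorized = TRUE)
}

# general linear field dx/dt = A x with analytic divergence tr(A)
linear_field <- function(A) {
  d <- nrow(A)
  trA <- sum(diag(A))
  vector_field(function(x) {
    if (is.matrix(x)) A %*% x else as.numeric(A %*% x)
  }, dim = d, divergence = function(x) {
    if (is.matrix(x)) rep(trA, ncol(x)) else trA
  }, vectorized = TRUE)
}

# closed-form multivariate normal log pdf (independent oracle)
mvn_logpdf <- function(x, mean, sigma) {
  d <- length(mean)
  ch <- chol(sigma)
  y <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(y^2))
}

tight <- solver_settings(rel_tol = 1e-11, abs_tol = 1e-13)
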