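test_that("linear model gives constant effects with te = nde + nie", {
  d <- linear_data(n = 400, seed = 3, sigma_M = 0.4, sigma_Y = 0.4)
  fit <- fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                  rho_free = FALSE))
  cf <- monomed:::mediation_coefs(fit)
  eff <- instantaneous_effects(fit, c(0.5, 1, 2, 7))
  # constant curves equal to the coefficient products at every x
  expect_equal(eff$nde, rep(unname(cf["c_prime"]), 4))
  expect_equal(eff$nie, rep(unname(cf["a"] * cf["b"]), 4))
  expect_equal(eff$te, eff$nde + eff$nie)
  expect_equal(eff$relative_nie, eff$nie / eff$te)
  # and close to the generating values c' = 0.7, a*b = 0.4
  expect_equal(eff$nde[1], 0.7, tolerance = 0.15)
  expect_equal(eff$nie[1], 0.4, tolerance = 0.15)
})

test_that("benchmark-design fit reproduces the constant indirect effect", {
  d <- bench_data(seed = 9)
  fit <- fit_composite(d, mm_spec(p = 0.4, q = 1, q_prime = 1, p_prime = 1,
                                  rho_free = FALSE))
  eff <- instantaneous_effects(fit, 1:4)
  expect_equal(diff(eff$nie), rep(0, 3))          # constant in x
  expect_equal(eff$nie[1], 0.04, tolerance = 0.25) # near a * b = 1/25
})

test_that("te = nde + nie holds exactly over arbitrary grids when p'' = 1", {
  d <- bench_data(seed = 14)
  fit <- fit_composite(d, mm_spec(p = 0.4, q = 1, q_prime = 1.3,
                                  p_prime = 0.7, rho_free = FALSE))
  g <- exp(seq(log(0.2), log(30), length.out = 40))
  eff <- instantaneous_effects(fit, g)
  expect_equal(eff$te, eff$nde + eff$nie)
  # single-transform mediator pathway: nie keeps one sign over x > 0
  expect_true(all(eff$nie > 0) || all(eff$nie < 0))
})

test_that("power-law effect curves follow the closed forms", {
  d <- bench_data(seed = 15)
  fit <- fit_composite(d, mm_spec(p = 0.4, q = 1, q_prime = 2,
                                  p_prime = -1, rho_free = FALSE))
  cf <- monomed:::mediation_coefs(fit)
  g <- c(1, 2.5, 4)
  eff <- instantaneous_effects(fit, g)
  expect_equal(eff$nde, unname(cf["c_prime"]) * (-1) * g^(-2))
  expect_equal(eff$nie, unname(cf["b"] * cf["a"]) * 2 * g)
})

test_that("absent pathway terms give identically zero effect curves", {
  d <- bench_data(seed = 16)
  fit_no_a <- fit_composite(d, mm_spec(p = 0.4, q = 1, q_prime = NULL,
                                       p_prime = 1, rho_free = FALSE))
  eff <- instantaneous_effects(fit_no_a, 1:3)
  expect_equal(eff$nie, rep(0, 3))
  expect_false(any(is.na(eff$nde)))
  fit_no_c <- fit_composite(d, mm_spec(p = 0.4, q = 1, q_prime = 1,
                                       p_prime = NULL, rho_free = FALSE))
  eff2 <- instantaneous_effects(fit_no_c, 1:3)
  expect_equal(eff2$nde, rep(0, 3))
  expect_error(instantaneous_effects(fit_no_a, c(1, -2)), "positive")
})

test_that("retransformed mediator effects match an integration oracle", {
  # p'' = 2: outcome depends on the squared mediator
  set.seed(71)
  n <- 300
  x <- runif(n, 1, 5)
  m <- 2 + 0.8 * x + rnorm(n, 0, 0.3)
  y <- 1 + 0.3 * x + 0.1 * m^2 + rnorm(n, 0, 0.3)
  d <- data.frame(x = x, m = m, y = y)
  spec2 <- mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1, m_power = 2,
                   rho_free = FALSE)
  fit2 <- fit_composite(d, spec2)
  cf <- monomed:::mediation_coefs(fit2)
  s2M <- mean(monomed:::subject_covariances(fit2)[, "s2M"])
  g <- c(1.5, 3, 4.5)
  eff2 <- instantaneous_effects(fit2, g)
  # oracle: numeric d/dx of b * E[(i_M + a x + U)^k] with the expectation
  # by quadrature over the fitted mediator-error distribution
  oracle <- function(k, xx, cfk, s2) {
    Eg <- function(x0) integrate(function(u)
      (cfk["i_M"] + cfk["a"] * x0 + u)^k * dnorm(u, 0, sqrt(s2)),
      -Inf, Inf)$value
    h <- 1e-4
    unname(cfk["b"]) * (Eg(xx + h) - Eg(xx - h)) / (2 * h)
  }
  expect_equal(eff2$nie, vapply(g, function(xx) oracle(2, xx, cf, s2M), 0),
               tolerance = 1e-5)
  # p'' = 3
  spec3 <- mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1, m_power = 3,
                   rho_free = FALSE)
  y3 <- 1 + 0.3 * x + 0.02 * m^3 + rnorm(n, 0, 0.3)
  fit3 <- fit_composite(data.frame(x = x, m = m, y = y3), spec3)
  cf3 <- monomed:::mediation_coefs(fit3)
  s2M3 <- mean(monomed:::subject_covariances(fit3)[, "s2M"])
  eff3 <- instantaneous_effects(fit3, g)
  expect_equal(eff3$nie, vapply(g, function(xx) oracle(3, xx, cf3, s2M3), 0),
               tolerance = 1e-5)
  # unsupported retransformation powers are refused
  spec_bad <- mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                      m_power = 1.5, rho_free = FALSE)
  fit_bad <- fit_composite(d, spec_bad)
  expect_error(instantaneous_effects(fit_bad, g), "p''")
})

test_that("normalized width matches its worked examples and bounds", {
  expect_equal(round(normalized_width(2.28, 8.19), 2), 0.72)
  expect_equal(round(normalized_width(2.00, 11.96), 2), 0.83)
  expect_equal(normalized_width(3, 3), 0)
  expect_equal(normalized_width(-4, 2), 0.5)   # uses absolute bounds
  expect_error(normalized_width(0, 0), "zero")
  set.seed(2)
  for (i in 1:20) {
    w <- normalized_width(rnorm(1), rnorm(1))
    expect_gte(w, 0)
    expect_lte(w, 1)
  }
})

test_that("bootstrap CI is reproducible, bracketing, and x-scales W-invariant", {
  d <- bench_data(seed = 3)
  spec <- mm_spec(p = 0.4, q = 1, q_prime = 1.2, p_prime = 1,
                  rho_free = FALSE)
  b1 <- bootstrap_nie(d, spec, 1:4, B = 300, seed = 11)
  b2 <- bootstrap_nie(d, spec, 1:4, B = 300, seed = 11)
  expect_identical(b1$ab_bounds, b2$ab_bounds)
  b3 <- bootstrap_nie(d, spec, 1:4, B = 300, seed = 12)
  expect_false(identical(b1$ab_bounds, b3$ab_bounds))
  expect_true(all(b1$L < b1$U))
  # W identical at every grid point and invariant to rescaling the grid
  b4 <- bootstrap_nie(d, spec, 10 * (1:4), B = 300, seed = 11)
  expect_equal(b1$W, b4$W, tolerance = 1e-12)
  expect_equal(b1$W, normalized_width(b1$ab_bounds[1], b1$ab_bounds[2]),
               tolerance = 1e-12)
  # q' != 1 makes the bounds scale as x^(q' - 1)
  expect_equal(b1$U[4] / b1$U[1], 4^0.2, tolerance = 1e-10)
})

test_that("BC and percentile intervals nearly coincide when symmetric", {
  d <- bench_data(seed = 3)
  spec <- mm_spec(p = 0.4, q = 1, q_prime = 1, p_prime = 1,
                  rho_free = FALSE)
  bc <- bootstrap_nie(d, spec, 1, B = 800, seed = 5, bias_correct = TRUE)
  pc <- bootstrap_nie(d, spec, 1, B = 800, seed = 5, bias_correct = FALSE)
  expect_lt(max(abs(bc$ab_bounds - pc$ab_bounds)) /
              diff(pc$ab_bounds), 0.15)
  # both contain the generating constant indirect effect here
  expect_lt(bc$ab_bounds[1], 0.04)
  expect_gt(bc$ab_bounds[2], 0.04)
})

test_that("bootstrap orientation survives a negative multiplier", {
  # q' < 0: the indirect-effect multiplier q' x^(q'-1) is negative, so the
  # scaled bounds must be re-sorted to keep L(x) < U(x)
  d <- simulate_mediation(n = 150, seed = 31, x_range = c(0.5, 5),
                          p = 1, q = 1, p_prime = 1, q_prime = -1,
                          i_M = 2, a = 3, i_Y = 4, c_prime = 0.5, b = 0.6,
                          sigma_M = 0.3, sigma_Y = 0.3)
  spec <- mm_spec(p = 1, q = 1, q_prime = -1, p_prime = 1, rho_free = FALSE)
  bb <- bootstrap_nie(d, spec, c(1, 2, 4), B = 200, seed = 2)
  expect_true(all(bb$L < bb$U))
  expect_true(all(bb$U < 0))   # negative indirect effect at every x
})

test_that("bootstrap refuses absent pathways and degenerate inputs", {
  d <- bench_data(seed = 17)
  expect_error(
    bootstrap_nie(d, mm_spec(p = 0.4, q = 1, q_prime = NULL, p_prime = 1,
                             rho_free = FALSE), 1:2, B = 100, seed = 1),
    "pathway")
  expect_error(
    bootstrap_nie(d, mm_spec(p = 0.4, q = 1, q_prime = 1, p_prime = 1,
                             rho_free = FALSE), 1:2, B = 50, seed = 1),
    "B >= 100")
})
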