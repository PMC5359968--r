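test_that("rho = 0 constant-variance fit equals stream-wise OLS", {
  d <- linear_data(n = 80, seed = 2)
  fit <- fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                  rho_free = FALSE))
  lmM <- lm(m ~ x, data = d)
  lmY <- lm(y ~ x + m, data = d)
  expect_equal(unname(fit$coefficients$M), unname(coef(lmM)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$Y),
               unname(coef(lmY)[c("(Intercept)", "x", "m")]),
               tolerance = 1e-8)
  # ML variances are RSS / n
  expect_equal(exp(fit$gamma_M), sum(resid(lmM)^2) / 80, tolerance = 1e-8)
  expect_equal(exp(fit$gamma_Y), sum(resid(lmY)^2) / 80, tolerance = 1e-8)
  expect_equal(fit$rho, 0)
})

test_that("log-likelihood equals the sum of per-subject contributions", {
  d <- linear_data(n = 40, seed = 9, rho = 0.4)
  fit <- fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                  rho_free = TRUE))
  expect_equal(per_subject_loglik(fit), fit$loglik, tolerance = 1e-8)
  # independent oracle: conditional factorization of the bivariate normal
  res <- residuals(fit, type = "raw")
  sc <- monomed:::subject_covariances(fit)
  ll <- 0
  for (s in seq_len(nrow(d))) {
    s1 <- sqrt(sc[s, "s2M"]); s2 <- sqrt(sc[s, "s2Y"]); r <- fit$rho
    ll <- ll + dnorm(res[s, "M"], 0, s1, log = TRUE) +
      dnorm(res[s, "Y"], r * s2 / s1 * res[s, "M"],
            s2 * sqrt(1 - r^2), log = TRUE)
  }
  expect_equal(unname(ll), fit$loglik, tolerance = 1e-8)
})

test_that("numerical gradient vanishes at the CSH optimum", {
  d <- linear_data(n = 60, seed = 4, rho = 0.3)
  spec <- mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1, rho_free = TRUE)
  fit <- fit_composite(d, spec)
  des <- monomed:::build_design(d, spec)
  par0 <- monomed:::.fit_par(fit)
  pack <- c(par0$betaM, par0$betaY, par0$gM, par0$gY, atanh(par0$rho))
  ll_at <- function(th) {
    p <- list(betaM = th[1:2], betaY = th[3:5], gM = th[6], gY = th[7],
              rho = tanh(th[8]))
    sum(monomed:::.core_loglik(p, des))
  }
  eps <- 1e-6
  grad <- vapply(seq_along(pack), function(j) {
    e <- replace(numeric(length(pack)), j, eps)
    (ll_at(pack + e) - ll_at(pack - e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(grad)), 1e-3 * (1 + abs(fit$loglik)) / 60)
})

test_that("parameters are recovered on large low-noise data", {
  d <- simulate_mediation(n = 2000, seed = 11, x_range = c(1, 10),
                          p = 1, q = 1, p_prime = 1, q_prime = 1,
                          i_M = 4, a = 0.8, i_Y = 6, c_prime = 0.7,
                          b = 0.5, sigma_M = 0.3, sigma_Y = 0.3, rho = 0)
  fit <- fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                  rho_free = FALSE))
  cf <- monomed:::mediation_coefs(fit)
  # tolerances sized to roughly 3 standard errors at n = 2000
  expect_equal(unname(cf["i_M"]), 4, tolerance = 0.02)
  expect_equal(unname(cf["a"]), 0.8, tolerance = 0.02)
  expect_equal(unname(cf["i_Y"]), 6, tolerance = 0.05)
  expect_equal(unname(cf["c_prime"]), 0.7, tolerance = 0.1)
  expect_equal(unname(cf["b"]), 0.5, tolerance = 0.15)
  # free rho on independent-error data: estimated correlation is small
  fit2 <- fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                   rho_free = TRUE))
  expect_lt(abs(fit2$rho), 0.1)
})

test_that("CSH likelihood is flat along the (b, rho) ridge", {
  # with observed M^q as a Y-stream regressor and free rho, only the
  # combinations b + rho * sigma_Y / sigma_M (and its x / intercept
  # counterparts) are identified; the fitted likelihood must match the
  # likelihood at the generating structural parameters
  tr <- list(i_M = 4, a = 0.8, i_Y = 6, c_prime = 0.7, b = 0.5,
             sM = 0.3, sY = 0.3, rho = 0.5)
  d <- simulate_mediation(n = 1500, seed = 12, x_range = c(1, 10),
                          p = 1, q = 1, p_prime = 1, q_prime = 1,
                          i_M = tr$i_M, a = tr$a, i_Y = tr$i_Y,
                          c_prime = tr$c_prime, b = tr$b,
                          sigma_M = tr$sM, sigma_Y = tr$sY, rho = tr$rho)
  spec <- mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1, rho_free = TRUE)
  fit <- fit_composite(d, spec)
  des <- monomed:::build_design(d, spec)
  ll_truth <- sum(monomed:::.core_loglik(
    list(betaM = c(tr$i_M, tr$a), betaY = c(tr$i_Y, tr$c_prime, tr$b),
         gM = log(tr$sM^2), gY = log(tr$sY^2), rho = tr$rho), des))
  expect_gte(fit$loglik + 1e-6, ll_truth)
  # identified ridge combinations recovered
  cf <- monomed:::mediation_coefs(fit)
  kap <- fit$rho * sqrt(exp(fit$gamma_Y) / exp(fit$gamma_M))
  kap0 <- tr$rho * tr$sY / tr$sM
  expect_equal(unname(cf["b"]) + kap, tr$b + kap0, tolerance = 0.05)
  expect_equal(unname(cf["c_prime"]) - kap * unname(cf["a"]),
               tr$c_prime - kap0 * tr$a, tolerance = 0.05)
})

test_that("standardized residuals whiten by the subject covariance", {
  d <- linear_data(n = 50, seed = 6)
  fit <- fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                  rho_free = FALSE))
  raw <- residuals(fit, type = "raw")
  std <- standardized_residuals(fit)
  # diagonal covariance: components are u / sigma per stream
  expect_equal(std[, "M"], raw[, "M"] / sqrt(exp(fit$gamma_M)),
               tolerance = 1e-10)
  expect_equal(std[, "Y"], raw[, "Y"] / sqrt(exp(fit$gamma_Y)),
               tolerance = 1e-10)
  # correlated case: whitened residuals have near-identity covariance
  d2 <- linear_data(n = 400, seed = 7, rho = 0.6)
  fit2 <- fit_composite(d2, mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1,
                                    rho_free = TRUE))
  std2 <- standardized_residuals(fit2)
  expect_equal(unname(crossprod(std2) / 400), diag(2), tolerance = 0.1)
})

test_that("correctly specified models pass normality checks in most runs", {
  pass <- 0L
  for (r in 1:10) {
    d <- bench_data(seed = 300 + r)
    fit <- fit_composite(d, mm_spec(p = 0.4, q = 1, q_prime = 1,
                                    p_prime = 1, rho_free = FALSE))
    na <- normality_assessment(standardized_residuals(fit))
    if (na$shapiro_p > 0.05) pass <- pass + 1L
  }
  expect_gte(pass, 8L)
})

test_that("normality assessment flags skewness and reports outliers", {
  set.seed(5)
  na_n <- normality_assessment(rnorm(500))
  expect_gt(na_n$shapiro_p, 1e-3)
  expect_equal(nrow(na_n$plot_points), 500)
  na_s <- normality_assessment(rexp(500))
  expect_lt(na_s$shapiro_p, 1e-6)
  expect_equal(normality_assessment(c(rnorm(50), 4, -5))$n_outliers, 2)
  expect_error(normality_assessment(c(1, 2)), "at least 3")
})

test_that("variance search keeps constant variances on homoscedastic data", {
  d <- bench_data(seed = 5)
  folds <- assign_folds(101, 15, seed = 3)
  base <- mm_spec(p = 0.4, q = 1, q_prime = 1, p_prime = 1, rho_free = FALSE)
  vs <- search_variance_model(d, base, folds)
  expect_equal(nrow(vs$spec$var_M), 0L)
  expect_equal(nrow(vs$spec$var_Y), 0L)
})

test_that("variance search recovers outcome-stream heteroscedasticity", {
  set.seed(9)
  n <- 150
  x <- runif(n, 1, 10)
  m <- 1 + x + rnorm(n)
  yp <- 5 + x + m + rnorm(n, 0, 0.25 * x)   # sd grows linearly in x
  d <- data.frame(x = x, m = m, y = (yp / 25)^2.5)
  folds <- assign_folds(n, 5, seed = 3)
  base <- mm_spec(p = 0.4, q = 1, q_prime = 1, p_prime = 1, rho_free = FALSE)
  vs <- search_variance_model(d, base, folds)
  expect_true("x" %in% vs$spec$var_Y$var)
  # fitted sd ratio across the x range near the true factor of 10
  fit <- fit_composite(d, vs$spec)
  sc <- monomed:::subject_covariances(fit)
  ratio <- sqrt(sc[which.max(x), "s2Y"] / sc[which.min(x), "s2Y"])
  expect_gt(ratio, 4)
  expect_lt(ratio, 25)
})

test_that("empty variance candidate list returns the base spec", {
  d <- linear_data(n = 40, seed = 1)
  folds <- assign_folds(40, 4, seed = 1)
  base <- mm_spec(p = 1, q = 1, q_prime = 1, p_prime = 1, rho_free = FALSE)
  vs <- search_variance_model(d, base, folds,
                              candidates = data.frame(stream = character(),
                                                      var = character()))
  expect_identical(vs$spec$var_M, base$var_M)
  expect_identical(vs$spec$var_Y, base$var_Y)
})

test_that("rank-deficient designs are rejected", {
  d <- linear_data(n = 30, seed = 2)
  d$x <- 2   # constant predictor -> collinear with the intercept
  expect_error(fit_composite(d, mm_spec(p = 1, q = 1, q_prime = 1,
                                        p_prime = 1, rho_free = FALSE)),
               "singular")
})
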