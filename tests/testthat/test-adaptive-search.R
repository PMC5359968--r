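# Brute-force oracle: maximize the same LCV objective over a fine power
# grid (coarse pass then 0.001 resolution around the best), independent of
# the staged search path.
brute_force_power <- function(scorer, base_spec, add_fn, lo = -5, hi = 5) {
  sval <- function(p) {
    s <- scorer(add_fn(base_spec, p))
    if (is.finite(s)) s else -Inf
  }
  g1 <- seq(lo, hi, by = 0.01)
  g1 <- g1[abs(g1) >= 1e-4]
  s1 <- vapply(g1, sval, numeric(1))
  c1 <- g1[which.max(s1)]
  g2 <- seq(c1 - 0.01, c1 + 0.01, by = 0.001)
  g2 <- g2[abs(g2) >= 1e-4 & g2 >= lo & g2 <= hi]
  s2 <- vapply(g2, sval, numeric(1))
  list(power = g2[which.max(s2)], score = max(s2))
}

test_that("staged power search matches the brute-force grid oracle", {
  # unimodal LCV surfaces from strong monotone signals at several true
  # exponents; full refinement forced (stop tolerance 0)
  cfg <- mm_search_config(stop_tolerance = 0)
  truths <- c(0.5, 1.37, 2.2)
  for (i in seq_along(truths)) {
    qp <- truths[i]
    set.seed(20 + i)
    n <- 150
    x <- runif(n, 1, 6)
    m <- (3 + 2 * x^qp + rnorm(n, 0, 0.4))
    y <- (6 + 0.5 * m + rnorm(n, 0, 0.4)) / 4
    d <- data.frame(x = x, m = m, y = y)
    folds <- assign_folds(n, 5, seed = i)
    scorer <- make_scorer(d, folds)
    base <- mm_spec(p = 1, q = 1, q_prime = NULL, p_prime = NULL,
                    rho_free = FALSE)
    add_M <- function(s, p) monomed:::set_x_power(s, "M", p)
    got <- monomed:::search_term_power(scorer, base, add_M, cfg,
                                       m = 2L * n)
    oracle <- brute_force_power(scorer, base, add_M)
    expect_lt(abs(got$power - oracle$power), 0.011,
              label = sprintf("truth %g: search %.3f vs oracle %.3f",
                              qp, got$power, oracle$power))
  }
})

test_that("boundary marching follows the score beyond the initial grid", {
  # true exponent 4.5 lies outside the [-3, 3] grid
  set.seed(31)
  n <- 200
  x <- runif(n, 1, 3)
  m <- 2 + 0.5 * x^4.5 + rnorm(n, 0, 0.2)
  y <- (5 + 0.4 * m + rnorm(n, 0, 0.3)) / 4
  d <- data.frame(x = x, m = m, y = y)
  folds <- assign_folds(n, 5, seed = 2)
  res <- search_x_power(d, mm_spec(p = 1, q = 1, q_prime = NULL,
                                   p_prime = NULL, rho_free = FALSE),
                        stream = "M", folds = folds)
  expect_true(res$added)
  expect_gt(res$power, 3.5)
  expect_lt(res$power, 5.5)
})

test_that("search stops at coarse resolution on flat surfaces", {
  # binary regressor: every power gives the same column, so the surface is
  # exactly flat and refinement must stop at the grid argmax
  set.seed(40)
  n <- 80
  z <- rep(c(0, 1), each = n / 2)
  d <- data.frame(x = runif(n, 1, 5), m = 2 + z + rnorm(n, 0, 0.3),
                  y = 3 + rnorm(n, 0, 0.3), z = z)
  folds <- assign_folds(n, 5, seed = 1)
  scorer <- make_scorer(d, folds)
  base <- mm_spec(p = 1, q = 1, q_prime = NULL, p_prime = NULL,
                  rho_free = FALSE)
  res <- monomed:::search_term_power(
    scorer, base, function(s, p) monomed:::add_cov_term(s, "M", "z", p),
    mm_search_config(), m = 2L * n)
  expect_true(res$added)
  expect_equal(res$power %% 0.5, 0)   # never refined below the half-grid
})

test_that("constrained expansion recovers linear X transforms", {
  d <- bench_data(seed = 2)
  folds <- assign_folds(101, 15, seed = 3)
  ce <- constrained_expansion(d, p = 0.4, q = 1, folds = folds,
                              rho_free = FALSE)
  qp <- monomed:::get_x_power(ce$spec, "M")
  pp <- monomed:::get_x_power(ce$spec, "Y")
  expect_false(is.na(qp))
  expect_false(is.na(pp))
  expect_lt(abs(qp - 1), 0.35)
  expect_lt(abs(pp - 1), 0.35)
})

test_that("search is deterministic for fixed data and folds", {
  d <- bench_data(seed = 4)
  folds <- assign_folds(101, 10, seed = 5)
  ce1 <- constrained_expansion(d, p = 0.4, q = 1, folds = folds,
                               rho_free = FALSE)
  ce2 <- constrained_expansion(d, p = 0.4, q = 1, folds = folds,
                               rho_free = FALSE)
  expect_identical(ce1$spec, ce2$spec)
  expect_identical(ce1$score, ce2$score)
})

test_that("outcome-power search recovers known outcome powers", {
  # wide-range design: power transforms are weakly identified on
  # narrow-ratio variables, so the outcome spans a large relative range
  for (p_true in c(0.5, 2)) {
    hits <- 0L
    for (s in 1:3) {
      d <- simulate_mediation(n = 300, seed = 80 + s,
                              x_range = c(0.25, 10), p = p_true, q = 1,
                              p_prime = 1, q_prime = 1, i_M = 0.5, a = 1,
                              i_Y = 0.1, c_prime = 1.5, b = 0.3,
                              sigma_M = 0.2, sigma_Y = 0.2)
      folds <- assign_folds(300, 5, seed = s)
      r <- search_outcome_powers(d, folds, rho_free = FALSE)
      expect_lt(abs(r$p - p_true), 0.25)
      expect_lt(abs(r$q - 1), 0.11)
      if (abs(r$p - p_true) < 0.11) hits <- hits + 1L
    }
    expect_gte(hits, 2L)
  }
})

test_that("outcome-power search stays near (1, 1) on linear data", {
  d <- linear_data(n = 200, seed = 13, sigma_M = 0.3, sigma_Y = 0.3)
  folds <- assign_folds(200, 5, seed = 3)
  r <- search_outcome_powers(d, folds, rho_free = FALSE)
  expect_lte(abs(r$p - 1), 0.5)
  expect_lte(abs(r$q - 1), 0.5)
})

test_that("accepted LCV never decreases across accepted search steps", {
  d <- bench_data(seed = 6)
  folds <- assign_folds(101, 10, seed = 1)
  scorer <- make_scorer(d, folds)
  base <- mm_spec(p = 0.4, q = 1, q_prime = NULL, p_prime = NULL,
                  rho_free = FALSE)
  ce <- constrained_expansion(d, p = 0.4, q = 1, folds = folds,
                              rho_free = FALSE, scorer = scorer)
  s_base <- scorer(base)
  # each accepted expansion kept a score no worse than generously below
  # the previous accepted score, and the final score beats the base
  expect_gte(ce$score, s_base)
})

test_that("power adjustment recovers a perturbed optimum and is idempotent", {
  set.seed(61)
  n <- 150
  x <- runif(n, 1, 6)
  m <- 3 + 2 * x^1.5 + rnorm(n, 0, 0.3)
  y <- (6 + 0.5 * m + rnorm(n, 0, 0.3)) / 4
  d <- data.frame(x = x, m = m, y = y)
  folds <- assign_folds(n, 5, seed = 4)
  cfg <- mm_search_config(stop_tolerance = 0)
  scorer <- make_scorer(d, folds)
  start <- mm_spec(p = 1, q = 1, q_prime = 2, p_prime = NULL,
                   rho_free = FALSE)   # q' perturbed from the optimum
  adj <- adjust_powers(d, start, folds, cfg = cfg, scorer = scorer)
  oracle <- brute_force_power(
    scorer, mm_spec(p = 1, q = 1, q_prime = NULL, p_prime = NULL,
                    rho_free = FALSE),
    function(s, p) monomed:::set_x_power(s, "M", p))
  expect_lt(abs(monomed:::get_x_power(adj$spec, "M") - oracle$power), 0.02)
  # already-optimal spec is left unchanged
  adj2 <- adjust_powers(d, adj$spec, folds, cfg = cfg, scorer = scorer)
  expect_identical(adj2$spec, adj$spec)
})

test_that("pathway ratio tests separate real and null mediation", {
  # real pathway: removing the X -> M term costs a substantial decrease
  d <- bench_data(seed = 21)
  folds <- assign_folds(101, 10, seed = 2)
  scorer <- make_scorer(d, folds)
  full <- constrained_expansion(d, p = 0.4, q = 1, folds = folds,
                                rho_free = FALSE, scorer = scorer)
  a0 <- constrained_expansion(
    d, p = 0.4, q = 1, folds = folds, rho_free = FALSE, streams = "Y",
    base_spec = mm_spec(p = 0.4, q = 1, q_prime = NULL, p_prime = NULL,
                        rho_free = FALSE),
    scorer = scorer)
  tst <- lcv_ratio_test(min(a0$score, full$score),
                        max(a0$score, full$score), 202)
  expect_true(tst$substantial)

  # null pathway (a = 0): the a = 0 model is competitive in most replicates
  verdicts <- logical(5)
  for (r in 1:5) {
    dn <- null_pathway_data(seed = 70 + r)
    fn <- assign_folds(100, 10, seed = r)
    sc <- make_scorer(dn, fn)
    fu <- constrained_expansion(dn, p = 1, q = 1, folds = fn,
                                rho_free = FALSE, scorer = sc)
    z0 <- constrained_expansion(
      dn, p = 1, q = 1, folds = fn, rho_free = FALSE, streams = "Y",
      base_spec = mm_spec(p = 1, q = 1, q_prime = NULL, p_prime = NULL,
                          rho_free = FALSE),
      scorer = sc)
    verdicts[r] <- !lcv_ratio_test(min(z0$score, fu$score),
                                   max(z0$score, fu$score), 200)$substantial
  }
  expect_gte(sum(verdicts), 3)
})
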