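# The monotonic mediation analysis protocol: fold selection, outcome-power
# search, the battery of LCV ratio tests, variance/covariate modelling,
# correlation assessment, retransformation, diagnostics, and effect
# estimation, orchestrated into one fitting function returning a classed
# model object.

#' Adaptive monotonic mediation analysis
#'
#' Runs the full adaptive analysis protocol on per-subject mediation data:
#' \enumerate{
#'   \item fold-count selection on the \code{p = q = 1} benchmark model;
#'   \item two-stage power-adjusted LCV search for the outcome and mediator
#'     powers \code{(p, q)}, with the X transforms re-searched at every
#'     candidate;
#'   \item ratio test of the selected powers against \code{p = q = 1}
#'     (nonlinearity in Y and M);
#'   \item ratio tests against the model linear in X, and, when
#'     \code{q' != 1}, against the model forced to \code{q' = 1}
#'     (constant-NIE assessment);
#'   \item ratio tests removing the X-to-M term (\code{a = 0}), the
#'     mediator term (\code{b = 0}), and the X-to-Y term (\code{c' = 0}),
#'     with the remaining transforms re-searched;
#'   \item adaptive expansion/contraction of the log-variance models;
#'   \item covariate expansion/contraction for means and variances;
#'   \item comparison of free-correlation (CSH) and independent-errors
#'     fits, keeping the better by LCV;
#'   \item retransformation allowing \code{p'' != 1}, with a ratio test
#'     for the \code{p'' = 1} simplification;
#'   \item standardized-residual diagnostics (normal plot coordinates and
#'     Shapiro-Wilk);
#'   \item instantaneous effect curves and bias-corrected bootstrap CIs
#'     for the instantaneous natural indirect effect.
#' }
#' Any subset of steps can be run; later steps use the last selected model.
#'
#' @param data data frame of per-subject measurements.
#' @param x,m,y names of the predictor, mediator, and outcome columns
#'   (all strictly positive).
#' @param covariates optional character vector of covariate column names.
#' @param moderator optional moderator column name; when given, a
#'   moderated fit and component tests are added after the main protocol.
#' @param k number of cross-validation folds; \code{NULL} (default) selects
#'   it in step 1.
#' @param seed integer seed governing folds and bootstrap resampling.
#' @param steps integer vector of protocol steps to run (default all).
#' @param rho \code{"auto"} (CSH during the search, compared against
#'   \eqn{\rho = 0} in step 8), \code{"zero"}, or \code{"free"}.
#' @param B bootstrap resample count for step 11.
#' @param bias_correct logical: bias-corrected bootstrap interval.
#' @param x_grid predictor grid for the effect curves (default: four
#'   equally spaced values spanning the observed predictor range).
#' @param cfg an \code{\link{mm_search_config}}.
#' @param k_candidates candidate fold counts for step 1.
#' @param power_adjust logical: run the optional cyclic power adjustment
#'   after the X expansion (default \code{FALSE}).
#' @return an object of class \code{"monomed"}; see
#'   \code{\link{print.monomed}}, \code{summary}, \code{coef},
#'   \code{residuals}, \code{plot}.
#' @examples
#' \donttest{
#' d <- simulate_mediation(seed = 7)
#' fit <- monomed(d, k = 5, seed = 1, steps = c(2, 10, 11), B = 200,
#'                rho = "zero")
#' print(fit)
#' }
#' @export
monomed <- function(data, x = "x", m = "m", y = "y", covariates = NULL,
                    moderator = NULL, k = NULL, seed = 1L,
                    steps = 1:11, rho = c("auto", "zero", "free"),
                    B = 1000L, bias_correct = TRUE, x_grid = NULL,
                    cfg = mm_search_config(),
                    k_candidates = seq(5L, 30L, 5L),
                    power_adjust = FALSE) {
  rho <- match.arg(rho)
  cl <- match.call()
  dat <- data.frame(x = data[[x]], m = data[[m]], y = data[[y]])
  if (is.null(dat$x) || is.null(dat$m) || is.null(dat$y))
    stop("columns not found in data: check x, m, y arguments")
  for (z in c(covariates, moderator)) dat[[z]] <- data[[z]]
  check_mediation_data(dat)
  n <- nrow(dat)
  mtot <- 2L * n
  rho_free <- rho != "zero"

  models <- list()
  tests <- list()
  note <- function(label, spec, score)
    models[[label]] <<- list(spec = spec, score = score)

  # Step 1: number of folds -------------------------------------------------
  k_selection <- NULL
  if (is.null(k) && 1 %in% steps) {
    k_selection <- select_folds(dat, seed = seed,
                                k_candidates = k_candidates,
                                rho_free = rho_free, cfg = cfg)
    k <- k_selection$k
    folds <- k_selection$folds
  } else {
    if (is.null(k)) k <- min(10L, n)
    folds <- assign_folds(n, k, derive_seed(seed, paste0("folds", k)))
  }
  scorer <- make_scorer(dat, folds)

  # benchmark: p = q = 1 constrained expansion under the same folds
  ce11 <- constrained_expansion(dat, p = 1, q = 1, folds = folds, cfg = cfg,
                                rho_free = rho_free, scorer = scorer)
  note("benchmark_p1_q1", ce11$spec, ce11$score)

  # Step 2: outcome/mediator powers ------------------------------------------
  if (2 %in% steps) {
    pq <- search_outcome_powers(dat, folds, cfg = cfg, rho_free = rho_free)
    spec_cur <- pq$spec
    score_cur <- pq$score
  } else {
    pq <- list(p = 1, q = 1, trail = NULL)
    spec_cur <- ce11$spec
    score_cur <- ce11$score
  }
  if (power_adjust) {
    adj <- adjust_powers(dat, spec_cur, folds, cfg = cfg, scorer = scorer)
    spec_cur <- adj$spec
    score_cur <- adj$score
  }
  note("selected_powers", spec_cur, score_cur)

  # Step 3: need for transforming M and Y ------------------------------------
  if (3 %in% steps && (spec_cur$p != 1 || spec_cur$q != 1))
    tests$transform_MY <- lcv_ratio_test(min(ce11$score, score_cur),
                                         max(ce11$score, score_cur), mtot)

  # Step 4: need for transforming X; constant-NIE assessment -----------------
  if (4 %in% steps) {
    lin <- spec_cur
    if (!is.na(get_x_power(lin, "M"))) lin <- set_x_power(lin, "M", 1)
    if (!is.na(get_x_power(lin, "Y"))) lin <- set_x_power(lin, "Y", 1)
    lin_score <- scorer(lin)
    note("linear_in_X", lin, lin_score)
    if (is.finite(lin_score))
      tests$transform_X <- lcv_ratio_test(min(lin_score, score_cur),
                                          max(lin_score, score_cur), mtot)
    qp <- get_x_power(spec_cur, "M")
    if (!is.na(qp) && qp != 1) {
      cn <- set_x_power(spec_cur, "M", 1)
      cn_score <- scorer(cn)
      note("constant_nie", cn, cn_score)
      if (is.finite(cn_score))
        tests$constant_nie <- lcv_ratio_test(min(cn_score, score_cur),
                                             max(cn_score, score_cur), mtot)
    }
  }

  # Step 5: mediation-pathway ratio tests ------------------------------------
  if (5 %in% steps) {
    p_cur <- spec_cur$p; q_cur <- spec_cur$q
    drop_test <- function(label, streams, base_mod) {
      ce <- constrained_expansion(dat, p = p_cur, q = q_cur, folds = folds,
                                  cfg = cfg, rho_free = spec_cur$rho_free,
                                  base_spec = base_mod, streams = streams,
                                  scorer = scorer)
      note(label, ce$spec, ce$score)
      if (is.finite(ce$score))
        tests[[label]] <<- lcv_ratio_test(min(ce$score, score_cur),
                                          max(ce$score, score_cur), mtot)
    }
    base0 <- mm_spec(p = p_cur, q = q_cur, q_prime = NULL, p_prime = NULL,
                     include_b = TRUE, rho_free = spec_cur$rho_free)
    drop_test("a_zero", "Y", base0)
    base_nb <- mm_spec(p = p_cur, q = q_cur, q_prime = NULL, p_prime = NULL,
                       include_b = FALSE, rho_free = spec_cur$rho_free)
    drop_test("b_zero", c("M", "Y"), base_nb)
    drop_test("c_prime_zero", "M", base0)
  }

  # Step 6: variance models --------------------------------------------------
  if (6 %in% steps) {
    vs <- search_variance_model(dat, spec_cur, folds, cfg = cfg,
                                scorer = scorer)
    note("variance_model", vs$spec, vs$score)
    spec_cur <- vs$spec
    score_cur <- vs$score
  }

  # Step 7: covariates -------------------------------------------------------
  if (7 %in% steps && length(covariates)) {
    cs <- search_covariates(dat, spec_cur, covariates, folds, cfg = cfg,
                            scorer = scorer)
    note("covariate_model", cs$spec, cs$score)
    if (is.finite(cs$score)) {
      tests$covariates <- lcv_ratio_test(min(score_cur, cs$score),
                                         max(score_cur, cs$score), mtot)
      if (cs$score > score_cur) {
        spec_cur <- cs$spec
        score_cur <- cs$score
      }
    }
  }

  # Step 8: rho = 0 versus CSH ------------------------------------------------
  if (8 %in% steps && rho == "auto") {
    alt <- spec_cur
    alt$rho_free <- !alt$rho_free
    alt_score <- scorer(alt)
    note(if (alt$rho_free) "rho_free" else "rho_zero", alt, alt_score)
    if (is.finite(alt_score)) {
      tests$rho_zero <- lcv_ratio_test(min(score_cur, alt_score),
                                       max(score_cur, alt_score), mtot)
      if (alt_score > score_cur) {
        spec_cur <- alt
        score_cur <- alt_score
      }
    }
  }

  # Step 9: retransformation (p'' != 1) ---------------------------------------
  if (9 %in% steps && any(spec_cur$bm$include)) {
    stop_tol <- cfg$stop_tolerance %||% lcv_cutoff(mtot)
    ev <- function(pw) {
      s <- spec_cur
      s$m_power <- round(pw, 6)
      scorer(s)
    }
    mp <- refine_power(ev, spec_cur$m_power, cfg, stop_tol,
                       lo_bound = -cfg$max_abs_power,
                       hi_bound = cfg$max_abs_power)
    rt <- spec_cur
    rt$m_power <- mp
    r <- list(spec = rt, score = .finite_or(ev(mp)))
    if (r$score > score_cur && mp != spec_cur$m_power) {
      note("retransformed", r$spec, r$score)
      tests$pdp_one <- lcv_ratio_test(min(score_cur, r$score),
                                      max(score_cur, r$score), mtot)
      if (tests$pdp_one$substantial) {
        spec_cur <- r$spec
        score_cur <- r$score
      }
    }
  }

  note("final", spec_cur, score_cur)
  final_fit <- fit_composite(dat, spec_cur)

  # Step 10: diagnostics ------------------------------------------------------
  diagnostics <- NULL
  if (10 %in% steps) {
    stdres <- standardized_residuals(final_fit)
    diagnostics <- normality_assessment(stdres)
    diagnostics$residuals <- stdres
  }

  # Step 11: effects and bootstrap CIs ----------------------------------------
  effects <- NULL
  ci <- NULL
  if (11 %in% steps) {
    if (is.null(x_grid))
      x_grid <- round(seq(min(dat$x), max(dat$x), length.out = 4), 2)
    cf <- mediation_coefs(final_fit)
    effects <- tryCatch(instantaneous_effects(final_fit, x_grid),
                        error = function(e) NULL)
    if (!is.na(cf["a"]) && !is.na(cf["b"]))
      ci <- tryCatch(
        bootstrap_nie(dat, spec_cur, x_grid, B = B,
                      bias_correct = bias_correct,
                      seed = derive_seed(seed, "bootstrap")),
        error = function(e) NULL)
  }

  # optional moderated analysis ----------------------------------------------
  moderated <- NULL
  if (!is.null(moderator)) {
    md <- fit_moderated(dat, moderator, p = spec_cur$p, q = spec_cur$q,
                        folds = folds, cfg = cfg,
                        rho_free = spec_cur$rho_free)
    md_tests <- moderation_component_tests(dat, md$spec, folds, cfg = cfg)
    md_cmp <- NULL
    if (is.finite(md$score))
      md_cmp <- lcv_ratio_test(min(score_cur, md$score),
                               max(score_cur, md$score), mtot)
    moderated <- list(spec = md$spec, fit = md$fit, score = md$score,
                      versus_unmoderated = md_cmp,
                      component_tests = md_tests)
  }

  structure(list(
    call = cl, data = dat, n = n, seed = seed,
    columns = c(x = x, m = m, y = y),
    k = k, folds = folds, k_selection = k_selection,
    pq_trail = pq$trail,
    models = models, tests = tests,
    spec = spec_cur, score = score_cur, fit = final_fit,
    diagnostics = diagnostics, effects = effects, ci = ci,
    moderated = moderated, steps = steps
  ), class = "monomed")
}

#' @export
print.monomed <- function(x, ...) {
  cat("Adaptive monotonic mediation analysis\n")
  cat(sprintf("  n = %d subjects, k = %d folds (seed %s)\n",
              x$n, x$k, format(x$seed)))
  cat(sprintf("  selected powers: p = %g, q = %g", x$spec$p, x$spec$q))
  fmtp <- function(v) if (is.na(v)) "absent" else format(v)
  if (!is_moderated(x$spec))
    cat(sprintf(", q' = %s, p' = %s", fmtp(get_x_power(x$spec, "M")),
                fmtp(get_x_power(x$spec, "Y"))))
  cat(sprintf("\n  covariance: %s; LCV(%g, %g) = %s\n",
              if (x$spec$rho_free) "CSH" else "independent errors",
              x$spec$p, x$spec$q, format(x$score, digits = 6)))
  if (length(x$tests)) {
    cat("  LCV ratio tests (percent decrease vs cutoff):\n")
    for (nm in names(x$tests)) {
      t <- x$tests[[nm]]
      cat(sprintf("    %-14s %6.2f%% vs %.2f%% -> %s\n", nm,
                  t$percent_decrease, t$cutoff,
                  if (t$substantial) "substantial" else "insubstantial"))
    }
  }
  if (!is.null(x$diagnostics))
    cat(sprintf("  Shapiro-Wilk p = %.3f, |residual| > 3: %d\n",
                x$diagnostics$shapiro_p, x$diagnostics$n_outliers))
  if (!is.null(x$effects)) {
    cat("  instantaneous effects:\n")
    print(x$effects, row.names = FALSE)
  }
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI for a*b: [%.4g, %.4g], W = %.2f\n",
                x$ci$ab_bounds[1], x$ci$ab_bounds[2], x$ci$W))
  invisible(x)
}

#' @export
summary.monomed <- function(object, ...) {
  out <- list(
    n = object$n, k = object$k, seed = object$seed,
    spec = object$spec, score = object$score,
    coefficients = coef(object$fit),
    rho = object$fit$rho,
    models = data.frame(
      label = names(object$models),
      score = vapply(object$models, function(z)
        if (is.null(z$score)) NA_real_ else z$score, numeric(1)),
      row.names = NULL),
    tests = if (length(object$tests)) data.frame(
      test = names(object$tests),
      percent_decrease = vapply(object$tests, `[[`, 0, "percent_decrease"),
      cutoff = vapply(object$tests, `[[`, 0, "cutoff"),
      substantial = vapply(object$tests, `[[`, TRUE, "substantial"),
      row.names = NULL) else NULL,
    shapiro_p = object$diagnostics$shapiro_p,
    effects = object$effects,
    ci = object$ci)
  class(out) <- "summary.monomed"
  out
}

#' @export
print.summary.monomed <- function(x, ...) {
  cat(sprintf("Monotonic mediation summary (n = %d, k = %d folds)\n\n",
              x$n, x$k))
  print(x$spec)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("rho = %.4f\n\nModel scores:\n", x$rho))
  print(x$models, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nLCV ratio tests:\n")
    print(x$tests, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$effects)) {
    cat("\nInstantaneous effects:\n")
    print(x$effects, row.names = FALSE)
  }
  if (!is.null(x$ci))
    cat(sprintf("\nBootstrap 95%% CI for a*b: [%.4g, %.4g], W = %.2f\n",
                x$ci$ab_bounds[1], x$ci$ab_bounds[2], x$ci$W))
  invisible(x)
}

#' @export
coef.monomed <- function(object, ...) coef(object$fit)

#' @export
residuals.monomed <- function(object, ...) residuals(object$fit, ...)

#' @export
predict.monomed <- function(object, newdata = NULL, ...)
  predict(object$fit, newdata = newdata, ...)

#' @export
logLik.monomed <- function(object, ...) logLik(object$fit)

#' @export
plot.monomed <- function(x, which = c("effects", "qq"), ...) {
  which <- match.arg(which)
  if (which == "qq") {
    if (is.null(x$diagnostics)) stop("diagnostics step was not run")
    pts <- x$diagnostics$plot_points
    graphics::plot(pts$theoretical, pts$observed,
                   xlab = "theoretical quantile",
                   ylab = "standardized residual", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    if (is.null(x$effects)) stop("effects step was not run")
    plot(x$effects, ...)
  }
  invisible(x)
}

#' Simulate data from a fitted composite model
#'
#' Parametric simulation: mediator-stream values are drawn from the fitted
#' means and variances, the outcome-stream mean is rebuilt with the
#' simulated mediator, and the transforms are inverted back to the data
#' scale.  Predictors, covariates, and the moderator are carried over from
#' the fitting data.
#'
#' @param object a \code{"monomed"} fit.
#' @param nsim number of simulated data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of \code{nsim} data frames shaped like the fitting data.
#' @export
simulate.monomed <- function(object, nsim = 1, seed = NULL, ...) {
  fit <- object$fit
  spec <- fit$spec
  dat <- object$data
  des <- build_design(dat, spec)
  sc <- subject_covariances(fit)
  muM <- drop(des$XM %*% unname(fit$coefficients$M))
  # outcome-stream mean without the mediator terms
  m_cols <- which(fit$info_Y$role == "m")
  bY <- unname(fit$coefficients$Y)
  keep <- setdiff(seq_along(bY), m_cols)
  muY_base <- drop(des$XY[, keep, drop = FALSE] %*% bY[keep])
  inv_out <- function(v, pw) if (pw == 0) exp(v) else v^(1 / pw)
  draw_rows <- function(rows) {
    uM <- stats::rnorm(length(rows), 0, sqrt(sc[rows, "s2M"]))
    cond_sd <- sqrt(sc[rows, "s2Y"] * (1 - fit$rho^2))
    uY <- fit$rho * sqrt(sc[rows, "s2Y"] / sc[rows, "s2M"]) * uM +
      stats::rnorm(length(rows), 0, cond_sd)
    Mq <- muM[rows] + uM
    m_new <- inv_out(Mq, spec$q)
    mterm <- rep(0, length(rows))
    for (j in m_cols) {
      lv <- fit$info_Y$level[j]
      ind <- level_ind(dat, spec, lv)[rows]
      mterm <- mterm + bY[j] * ind *
        power_transform_outcome(pmax(m_new, .Machine$double.eps),
                                spec$m_power)
    }
    Yp <- muY_base[rows] + mterm + uY
    bad <- (spec$q != 0 & Mq <= 0) | (spec$p != 0 & Yp <= 0) |
      !is.finite(m_new)
    list(m = m_new, y = inv_out(Yp, spec$p), bad = bad)
  }
  one <- function() {
    out <- dat
    out$m <- out$y <- NA_real_
    todo <- seq_len(nrow(dat))
    for (round in seq_len(50L)) {     # redraw out-of-domain subjects
      if (!length(todo)) break
      dr <- draw_rows(todo)
      ok <- todo[!dr$bad]
      out$m[ok] <- dr$m[!dr$bad]
      out$y[ok] <- dr$y[!dr$bad]
      todo <- todo[dr$bad]
    }
    out
  }
  with_seed(seed, replicate(nsim, one(), simplify = FALSE))
}
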