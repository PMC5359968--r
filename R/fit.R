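# Maximum-likelihood estimation of the composite bivariate mediation model.
#
# Estimation strategy by case:
#   * rho = 0, constant variances: the likelihood separates; stream-wise OLS
#     with ML variances RSS/n is exact.
#   * free rho (CSH), constant variances: iterated feasible GLS between the
#     two streams (seemingly-unrelated regressions); with an unrestricted
#     2x2 covariance this iteration converges to the MLE.
#   * non-constant (log-linear) variances: BFGS over mean coefficients,
#     log-variance coefficients, and atanh(rho), warm-started from the
#     constant-variance fit.

# Per-subject bivariate-normal log density of the residuals under a
# parameter list (betaM, betaY, gM, gY, rho), on the given design rows.
.core_loglik <- function(par, des, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(des$n)
  XM <- des$XM[rows, , drop = FALSE]; XY <- des$XY[rows, , drop = FALSE]
  VM <- des$VM[rows, , drop = FALSE]; VY <- des$VY[rows, , drop = FALSE]
  uM <- des$yM[rows] - drop(XM %*% par$betaM)
  uY <- des$yY[rows] - drop(XY %*% par$betaY)
  s2M <- exp(drop(VM %*% par$gM)); s2Y <- exp(drop(VY %*% par$gY))
  rho <- par$rho
  if (!all(is.finite(s2M)) || !all(is.finite(s2Y)) || abs(rho) >= 1)
    return(rep(-Inf, length(rows)))
  zM <- uM / sqrt(s2M); zY <- uY / sqrt(s2Y)
  omr <- 1 - rho^2
  -log(2 * pi) - 0.5 * (log(s2M) + log(s2Y) + log(omr)) -
    (zM^2 - 2 * rho * zM * zY + zY^2) / (2 * omr)
}

.ols_stream <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("singular mean design (rank deficiency)")
  beta <- numeric(ncol(X))
  beta[fit$pivot] <- fit$coefficients
  list(beta = beta, resid = drop(fit$residuals))
}

.fit_core <- function(des, rho_free, rows = NULL) {
  if (!is.null(rows)) {
    des <- list(XM = des$XM[rows, , drop = FALSE], XY = des$XY[rows, , drop = FALSE],
                VM = des$VM[rows, , drop = FALSE], VY = des$VY[rows, , drop = FALSE],
                yM = des$yM[rows], yY = des$yY[rows], n = length(rows))
  }
  n <- des$n
  oM <- .ols_stream(des$XM, des$yM)
  oY <- .ols_stream(des$XY, des$yY)
  const_var <- ncol(des$VM) == 1L && ncol(des$VY) == 1L
  s2M <- sum(oM$resid^2) / n; s2Y <- sum(oY$resid^2) / n
  if (s2M <= 0 || s2Y <= 0) stop("degenerate (zero-variance) stream")

  if (const_var && !rho_free) {
    par <- list(betaM = oM$beta, betaY = oY$beta,
                gM = log(s2M), gY = log(s2Y), rho = 0)
    ll <- sum(.core_loglik(par, des))
    return(c(par, list(loglik = ll, converged = TRUE)))
  }

  if (const_var && rho_free) {
    # iterated SUR: alternate GLS for the means and the ML covariance
    bM <- oM$beta; bY <- oY$beta
    XtXM <- crossprod(des$XM); XtXY <- crossprod(des$XY)
    XtXMY <- crossprod(des$XM, des$XY)
    for (it in seq_len(200L)) {
      uM <- des$yM - drop(des$XM %*% bM)
      uY <- des$yY - drop(des$XY %*% bY)
      S <- crossprod(cbind(uM, uY)) / n
      W <- solve(S)
      A <- rbind(cbind(W[1, 1] * XtXM, W[1, 2] * XtXMY),
                 cbind(W[1, 2] * t(XtXMY), W[2, 2] * XtXY))
      rhs <- c(W[1, 1] * crossprod(des$XM, des$yM) +
                 W[1, 2] * crossprod(des$XM, des$yY),
               W[1, 2] * crossprod(des$XY, des$yM) +
                 W[2, 2] * crossprod(des$XY, des$yY))
      bnew <- drop(solve(A, rhs))
      delta <- max(abs(bnew - c(bM, bY)))
      bM <- bnew[seq_along(bM)]; bY <- bnew[-seq_along(bM)]
      if (delta < 1e-10 * (1 + max(abs(bnew)))) break
    }
    uM <- des$yM - drop(des$XM %*% bM)
    uY <- des$yY - drop(des$XY %*% bY)
    S <- crossprod(cbind(uM, uY)) / n
    rho <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
    par <- list(betaM = bM, betaY = bY, gM = log(S[1, 1]), gY = log(S[2, 2]),
                rho = rho)
    ll <- sum(.core_loglik(par, des))
    return(c(par, list(loglik = ll, converged = it < 200L)))
  }

  # general case: quasi-Newton on (beta, log-variance coefs, atanh rho)
  kM <- ncol(des$XM); kY <- ncol(des$XY)
  vM <- ncol(des$VM); vY <- ncol(des$VY)
  start <- c(oM$beta, oY$beta, log(s2M), rep(0, vM - 1L),
             log(s2Y), rep(0, vY - 1L), if (rho_free) 0)
  unpack <- function(th) {
    i <- 0L
    betaM <- th[i + seq_len(kM)]; i <- i + kM
    betaY <- th[i + seq_len(kY)]; i <- i + kY
    gM <- th[i + seq_len(vM)]; i <- i + vM
    gY <- th[i + seq_len(vY)]; i <- i + vY
    rho <- if (rho_free) tanh(th[i + 1L]) else 0
    list(betaM = betaM, betaY = betaY, gM = gM, gY = gY, rho = rho)
  }
  nll <- function(th) {
    ll <- sum(.core_loglik(unpack(th), des))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 2000))
    if (opt2$value < opt$value) opt <- opt2
  }
  par <- unpack(opt$par)
  c(par, list(loglik = -opt$value, converged = opt$convergence == 0))
}

#' Fit the composite monotonic mediation model
#'
#' Maximum-likelihood estimation of the bivariate composite model described
#' in \code{\link{mm_spec}} on per-subject mediation data.
#'
#' @param data data frame with columns \code{x}, \code{m}, \code{y} (all
#'   strictly positive), plus any covariate/moderator columns named in the
#'   spec.
#' @param spec an \code{\link{mm_spec}} model specification.
#' @return an object of class \code{"mm_fit"} with components
#'   \code{coefficients} (named; mediation roles recoverable via
#'   \code{coef()}), \code{gamma_M}/\code{gamma_Y} (log-variance
#'   coefficients), \code{rho}, \code{loglik}, and \code{converged}.
#' @examples
#' d <- simulate_mediation(seed = 1)
#' f <- fit_composite(d, mm_spec(p = 0.4, q = 1, rho_free = FALSE))
#' coef(f)
#' @export
fit_composite <- function(data, spec) {
  stopifnot(inherits(spec, "mm_spec"), is.data.frame(data))
  check_mediation_data(data, spec)
  des <- build_design(data, spec)
  core <- .fit_core(des, spec$rho_free)
  names(core$betaM) <- design_names(des$info_M)
  names(core$betaY) <- design_names(des$info_Y)
  structure(list(
    spec = spec, data = data,
    coefficients = list(M = core$betaM, Y = core$betaY),
    gamma_M = core$gM, gamma_Y = core$gY, rho = core$rho,
    loglik = core$loglik, converged = core$converged,
    info_M = des$info_M, info_Y = des$info_Y, n = des$n
  ), class = "mm_fit")
}

design_names <- function(info) {
  nm <- ifelse(info$role == "intercept", "(Intercept)",
               paste0(info$var, "^", vapply(info$power, function(p)
                 sprintf("%g", p), "")))
  lv <- ifelse(is.na(info$level), "", paste0("[", info$level, "]"))
  paste0(info$stream, ":", nm, lv)
}

check_mediation_data <- function(data, spec = NULL) {
  need <- c("x", "m", "y")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks required columns: ", paste(miss, collapse = ", "))
  for (v in need)
    if (any(!is.finite(data[[v]])) || any(data[[v]] <= 0))
      stop("column '", v, "' must be finite and strictly positive ",
           "(shift the variable by a constant if needed)")
  if (!is.null(spec)) {
    vars <- unique(c(spec$cov_M$var, spec$cov_Y$var,
                     setdiff(c(spec$var_M$var, spec$var_Y$var), c("x", "m")),
                     spec$moderator))
    miss <- setdiff(vars, names(data))
    if (length(miss))
      stop("data lacks model columns: ", paste(miss, collapse = ", "))
  }
  invisible(data)
}

.fit_par <- function(fit)
  list(betaM = unname(fit$coefficients$M), betaY = unname(fit$coefficients$Y),
       gM = fit$gamma_M, gY = fit$gamma_Y, rho = fit$rho)

#' Per-subject log-likelihood contributions
#'
#' Evaluates the fitted model's bivariate-normal log-likelihood on a subset
#' of subjects (by default all), e.g. for deleted-likelihood computations.
#'
#' @param fit an \code{\link{fit_composite}} result.
#' @param subset integer indices of subjects (rows), default all.
#' @param data optional data frame to evaluate on (defaults to the fitting
#'   data).
#' @return sum of per-subject log-likelihood terms.
#' @export
per_subject_loglik <- function(fit, subset = NULL, data = NULL) {
  if (is.null(data)) data <- fit$data
  des <- build_design(data, fit$spec)
  sum(.core_loglik(.fit_par(fit), des, rows = subset))
}

# Per-subject 2x2 covariance matrices implied by the fitted variance model.
subject_covariances <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  des <- build_design(data, fit$spec)
  s2M <- exp(drop(des$VM %*% fit$gamma_M))
  s2Y <- exp(drop(des$VY %*% fit$gamma_Y))
  cv <- fit$rho * sqrt(s2M * s2Y)
  cbind(s2M = s2M, s2Y = s2Y, cov = cv)
}

#' Standardized (whitened) residuals of a composite fit
#'
#' Per-subject residual vectors scaled by the inverse transposed Cholesky
#' factor of the subject's fitted covariance matrix, so that a correctly
#' specified model yields (approximately) independent standard-normal
#' values.  Pooled over both streams these feed the normality assessment.
#'
#' @param fit an \code{\link{fit_composite}} result.
#' @param data optional data to evaluate on (default: fitting data).
#' @return an \code{n x 2} matrix with columns \code{M} and \code{Y}.
#' @export
standardized_residuals <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  des <- build_design(data, fit$spec)
  uM <- des$yM - drop(des$XM %*% unname(fit$coefficients$M))
  uY <- des$yY - drop(des$XY %*% unname(fit$coefficients$Y))
  sc <- subject_covariances(fit, data)
  out <- matrix(NA_real_, nrow(data), 2, dimnames = list(NULL, c("M", "Y")))
  for (s in seq_len(nrow(data))) {
    Sig <- matrix(c(sc[s, "s2M"], sc[s, "cov"], sc[s, "cov"], sc[s, "s2Y"]), 2)
    R <- tryCatch(chol(Sig), error = function(e)
      stop("covariance matrix not positive definite for subject ", s))
    out[s, ] <- forwardsolve(t(R), c(uM[s], uY[s]))
  }
  out
}

#' Normality assessment for pooled standardized residuals
#'
#' Shapiro-Wilk test plus normal-plot coordinates and the count of
#' residuals outside \eqn{\pm 3}.
#'
#' @param residuals numeric vector or matrix of standardized residuals.
#' @return a list with \code{shapiro_p}, \code{plot_points} (theoretical
#'   quantile, ordered residual), and \code{n_outliers}.
#' @export
normality_assessment <- function(residuals) {
  r <- sort(as.numeric(residuals))
  if (length(r) < 3) stop("need at least 3 residuals")
  p <- stats::shapiro.test(r)$p.value
  qq <- stats::qqnorm(r, plot.it = FALSE)
  list(shapiro_p = p,
       plot_points = data.frame(theoretical = sort(qq$x), observed = r),
       n_outliers = sum(abs(r) > 3))
}

# ---- coefficient extraction -----------------------------------------------

# Pulls a mediation-role coefficient from the fit (NA when the term is
# absent from the spec).
coef_role <- function(fit, stream, role, level = NA_character_) {
  info <- if (stream == "M") fit$info_M else fit$info_Y
  beta <- fit$coefficients[[stream]]
  hit <- info$role == role &
    (is.na(level) & is.na(info$level) |
       (!is.na(level) & !is.na(info$level) & info$level == level))
  if (!any(hit)) NA_real_ else unname(beta[which(hit)[1L]])
}

# The five mediation parameters at a level (NA entries = absent terms).
mediation_coefs <- function(fit, level = NA_character_) {
  spec <- fit$spec
  c(i_M = coef_role(fit, "M", "intercept", level),
    i_Y = coef_role(fit, "Y", "intercept", level),
    a = coef_role(fit, "M", "x", level),
    c_prime = coef_role(fit, "Y", "x", level),
    b = coef_role(fit, "Y", "m", level),
    q_prime = get_x_power(spec, "M", level),
    p_prime = get_x_power(spec, "Y", level))
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(object$coefficients$M, object$coefficients$Y)
}

#' @export
logLik.mm_fit <- function(object, ...) {
  k <- length(object$coefficients$M) + length(object$coefficients$Y) +
    length(object$gamma_M) + length(object$gamma_Y) + object$spec$rho_free
  structure(object$loglik, df = k, nobs = 2L * object$n, class = "logLik")
}

#' @export
residuals.mm_fit <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  des <- build_design(object$data, object$spec)
  if (type == "raw")
    return(cbind(M = des$yM - drop(des$XM %*% unname(object$coefficients$M)),
                 Y = des$yY - drop(des$XY %*% unname(object$coefficients$Y))))
  standardized_residuals(object)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  des <- build_design(newdata, object$spec)
  data.frame(mean_Mq = drop(des$XM %*% unname(object$coefficients$M)),
             mean_Yp = drop(des$XY %*% unname(object$coefficients$Y)))
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat("Composite monotonic mediation model fit\n")
  cat(sprintf("  n = %d subjects, log-likelihood = %.4f%s\n", x$n, x$loglik,
              if (x$converged) "" else "  (NOT converged)"))
  cat(sprintf("  powers: p = %g, q = %g", x$spec$p, x$spec$q))
  if (!is_moderated(x$spec))
    cat(sprintf(", q' = %s, p' = %s",
                format(get_x_power(x$spec, "M")), format(get_x_power(x$spec, "Y"))))
  cat("\n  mediator-stream coefficients:\n")
  print(round(x$coefficients$M, digits))
  cat("  outcome-stream coefficients:\n")
  print(round(x$coefficients$Y, digits))
  cat(sprintf("  rho = %.4f (%s)\n", x$rho,
              if (x$spec$rho_free) "estimated" else "fixed"))
  invisible(x)
}
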