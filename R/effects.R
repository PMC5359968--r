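# Instantaneous natural direct / indirect / total effect curves and
# bias-corrected bootstrap confidence intervals for the instantaneous
# natural indirect effect.

# Derivative of the X transform used in the effect formulas: d x^p / dx,
# with the log-limit convention at p = 0.
d_xpow <- function(x, p) if (p == 0) 1 / x else p * x^(p - 1)
xpow <- function(x, p) if (p == 0) log(x) else x^p

# Multiplier m(x) with nie(x) = b * a * m(x); depends on p'' (1, 2, or 3).
nie_multiplier <- function(x, q_prime, pdp, i_M, a, s2M) {
  dq <- d_xpow(x, q_prime)
  if (isTRUE(all.equal(pdp, 1))) return(dq)
  mu <- i_M + a * xpow(x, q_prime)
  if (isTRUE(all.equal(pdp, 2))) return(2 * mu * dq)
  if (isTRUE(all.equal(pdp, 3))) return(3 * (mu^2 + s2M) * dq)
  stop("instantaneous effects are available for p'' in {1, 2, 3} only ",
       "(got p'' = ", format(pdp), ")")
}

#' Instantaneous natural direct, indirect, and total effect curves
#'
#' For a fitted composite model, evaluates on a grid of predictor values
#' the instantaneous natural direct effect \eqn{c' p' x^{p'-1}}, the
#' instantaneous natural indirect effect (\eqn{b a q' x^{q'-1}} when
#' \eqn{p'' = 1}, with the stated closed forms for \eqn{p'' = 2, 3}), the
#' total effect (their sum), and the relative indirect effect nie/te.
#' Absent pathway terms give identically zero curves.
#'
#' @param fit an \code{\link{fit_composite}} result.
#' @param x_grid strictly positive predictor values.
#' @param level moderator level for moderated fits (default unmoderated).
#' @return data frame of class \code{"mm_effects"} with columns \code{x},
#'   \code{nde}, \code{nie}, \code{te}, \code{relative_nie} (NA where
#'   \code{te == 0}).
#' @examples
#' d <- simulate_mediation(seed = 1)
#' f <- fit_composite(d, mm_spec(p = 0.4, q = 1, rho_free = FALSE))
#' instantaneous_effects(f, 1:4)
#' @export
instantaneous_effects <- function(fit, x_grid, level = NA_character_) {
  stopifnot(inherits(fit, "mm_fit"))
  if (any(!is.finite(x_grid)) || any(x_grid <= 0))
    stop("x_grid must be strictly positive")
  cf <- mediation_coefs(fit, level)
  pdp <- spec_pdp(fit$spec)
  nde <- if (is.na(cf["c_prime"]) || is.na(cf["p_prime"])) rep(0, length(x_grid))
         else cf["c_prime"] * d_xpow(x_grid, cf["p_prime"])
  if (is.na(cf["a"]) || is.na(cf["b"]) || is.na(cf["q_prime"])) {
    nie <- rep(0, length(x_grid))
  } else {
    s2M <- mean(subject_covariances(fit)[, "s2M"])
    nie <- cf["b"] * cf["a"] *
      nie_multiplier(x_grid, cf["q_prime"], pdp, cf["i_M"], cf["a"], s2M)
  }
  te <- nde + nie
  rel <- ifelse(te == 0, NA_real_, nie / te)
  structure(data.frame(x = x_grid, nde = unname(nde), nie = unname(nie),
                       te = unname(te), relative_nie = unname(rel)),
            class = c("mm_effects", "data.frame"),
            level = level, pdp = pdp)
}

#' Normalized width of an indirect-effect confidence interval
#'
#' \code{W = 1 - min(|L|, |U|) / max(|L|, |U|)} applied to the interval
#' bounds for the slope product \eqn{a b}; because the x-dependence of the
#' interval enters through a common positive multiplier, \code{W} is
#' constant over the (nonzero) predictor grid.  Values near 0 indicate a
#' precise interval.
#'
#' @param L_coef,U_coef interval bounds for the \eqn{a b} product.
#' @return a value in \code{[0, 1]}.
#' @examples
#' round(normalized_width(2.28, 8.19), 2)   # 0.72
#' round(normalized_width(2.00, 11.96), 2)  # 0.83
#' @export
normalized_width <- function(L_coef, U_coef) {
  a1 <- abs(L_coef); a2 <- abs(U_coef)
  if (max(a1, a2) == 0) stop("both interval bounds are zero")
  1 - min(a1, a2) / max(a1, a2)
}

#' Bootstrap confidence intervals for the instantaneous indirect effect
#'
#' Draws subject resamples with replacement, refits the composite model
#' with every power frozen (only coefficients, variances, and the
#' correlation are re-estimated), and forms the 95\% percentile or
#' bias-corrected (BC) percentile interval for the slope product
#' \eqn{a^* b^*}.  The interval bounds are then carried to each grid value
#' through the fitted indirect-effect multiplier
#' (\eqn{q' x^{q'-1}} when \eqn{p'' = 1}), giving \code{L(x) < U(x)}, and
#' summarized by the normalized width \code{W}.
#'
#' @param data mediation data frame.
#' @param spec the selected \code{\link{mm_spec}} (powers frozen).
#' @param x_grid strictly positive predictor values.
#' @param B number of resamples (default 1000, minimum 100).
#' @param bias_correct logical; BC percentile interval (default) or plain
#'   percentile.
#' @param seed integer seed.
#' @param level moderator level for moderated specs.
#' @param max_fail_frac abort when more than this fraction of resample
#'   fits fail (default 0.05).
#' @return object of class \code{"mm_boot"}: \code{x}, \code{L}, \code{U},
#'   \code{W}, \code{ab_bounds}, \code{ab_hat}, \code{B}, \code{seed}.
#' @export
bootstrap_nie <- function(data, spec, x_grid, B = 1000L, bias_correct = TRUE,
                          seed = 1L, level = NA_character_,
                          max_fail_frac = 0.05) {
  stopifnot(B >= 100L)
  if (any(x_grid <= 0)) stop("x_grid must be strictly positive")
  full <- fit_composite(data, spec)
  cf <- mediation_coefs(full, level)
  if (is.na(cf["a"]) || is.na(cf["b"]))
    stop("no mediation pathway in the spec (a or b term absent)",
         if (!is.na(level)) paste0(" at level ", level) else "")
  ab_hat <- unname(cf["a"] * cf["b"])
  n <- nrow(data)
  # powers are frozen, so a resample's design is a row-indexed copy of the
  # full-data design
  des <- build_design(data, spec)
  find_col <- function(info, role) {
    hit <- info$role == role &
      (is.na(level) & is.na(info$level) |
         (!is.na(level) & !is.na(info$level) & info$level == level))
    which(hit)[1L]
  }
  col_a <- find_col(des$info_M, "x")
  col_b <- find_col(des$info_Y, "m")
  ab <- rep(NA_real_, B)
  with_seed(seed, {
    for (r in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      core <- tryCatch(.fit_core(des, spec$rho_free, rows = idx),
                       error = function(e) NULL)
      if (is.null(core)) next
      ab[r] <- core$betaM[col_a] * core$betaY[col_b]
    }
  })
  n_fail <- sum(is.na(ab))
  if (n_fail > max_fail_frac * B)
    stop(sprintf("%d of %d resample fits failed (> %.0f%%); aborting",
                 n_fail, B, 100 * max_fail_frac))
  ab <- ab[!is.na(ab)]
  if (stats::sd(ab) == 0)
    stop("degenerate bootstrap distribution (zero variance)")
  if (bias_correct) {
    prop <- mean(ab < ab_hat)
    prop <- min(max(prop, 1 / (length(ab) + 1)), length(ab) / (length(ab) + 1))
    z0 <- stats::qnorm(prop)
    probs <- stats::pnorm(2 * z0 + c(-1, 1) * stats::qnorm(0.975))
  } else {
    probs <- c(0.025, 0.975)
  }
  bounds <- unname(stats::quantile(ab, probs, type = 7))
  s2M <- mean(subject_covariances(full)[, "s2M"])
  mult <- nie_multiplier(x_grid, cf["q_prime"], spec_pdp(spec),
                         cf["i_M"], cf["a"], s2M)
  LU <- rbind(bounds[1] * mult, bounds[2] * mult)
  L <- pmin(LU[1, ], LU[2, ])   # a negative multiplier flips orientation
  U <- pmax(LU[1, ], LU[2, ])
  structure(list(x = x_grid, L = unname(L), U = unname(U),
                 W = normalized_width(bounds[1], bounds[2]),
                 ab_bounds = bounds, ab_hat = ab_hat, ab_samples = ab,
                 B = B, n_fail = n_fail, bias_corrected = bias_correct,
                 seed = seed, level = level),
            class = "mm_boot")
}

#' @export
print.mm_boot <- function(x, digits = 4, ...) {
  cat(sprintf("%s bootstrap 95%% CI for the instantaneous NIE (B = %d%s)\n",
              if (x$bias_corrected) "Bias-corrected" else "Percentile",
              x$B, if (is.na(x$level)) "" else paste0(", level ", x$level)))
  cat(sprintf("  slope product a*b: %.5g, interval [%.5g, %.5g]\n",
              x$ab_hat, x$ab_bounds[1], x$ab_bounds[2]))
  print(data.frame(x = x$x, L = round(x$L, digits), U = round(x$U, digits)))
  cat(sprintf("  normalized width W = %.2f\n", x$W))
  invisible(x)
}

#' @export
plot.mm_effects <- function(x, ...) {
  graphics::matplot(x$x, cbind(x$te, x$nde, x$nie), type = "l", lty = 1:3,
                    col = c("black", "blue", "red"), xlab = "x",
                    ylab = "instantaneous effect", ...)
  graphics::legend("topleft", c("total", "direct", "indirect"),
                   lty = 1:3, col = c("black", "blue", "red"), bty = "n")
  invisible(x)
}
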