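#' Composite monotonic-mediation model specification
#'
#' Describes the structure of the bivariate composite model
#' \deqn{M^q = i_M + a X^{q'} + U_M, \qquad
#'       Y^p = i_Y + c' X^{p'} + b M^{q p''} + U_Y,}
#' with bivariate-normal errors whose covariance is either CSH (stream
#' variances plus one correlation \eqn{\rho}) or independent
#' (\eqn{\rho = 0}), optionally with log-linear variance models and
#' covariate terms.  For a discrete moderator, the intercepts, the X
#' slopes and powers, and the M slope may all vary by moderator level
#' (powers \code{p} and \code{q} stay shared).
#'
#' @param p outcome power (0 = natural log).
#' @param q mediator power (0 = natural log).
#' @param q_prime power on X in the mediator stream, or \code{NULL} to omit
#'   the term (\code{a = 0}).  May be a named vector over moderator levels.
#' @param p_prime power on X in the outcome stream, or \code{NULL} to omit
#'   the term (\code{c' = 0}).  May be a named vector over moderator levels.
#' @param include_b logical: include the transformed-mediator term in the
#'   outcome stream?  May be a named logical vector over moderator levels.
#' @param m_power exponent actually applied to M in the outcome stream,
#'   \code{q * p''}; defaults to \code{q} (i.e. \code{p'' = 1}).
#' @param covariates_M,covariates_Y data frames with columns \code{var} and
#'   \code{power}: covariate mean terms for each stream.
#' @param variance_M,variance_Y data frames with columns \code{var} and
#'   \code{power}: log-variance model terms for each stream (beyond the
#'   always-present intercepts).
#' @param rho_free logical: estimate the cross-stream correlation (CSH) or
#'   fix \eqn{\rho = 0}?
#' @param moderator optional column name of a discrete moderator.
#' @param levels moderator levels (character); required when
#'   \code{moderator} is given.
#' @return an object of class \code{"mm_spec"}.
#' @export
mm_spec <- function(p = 1, q = 1, q_prime = 1, p_prime = 1,
                    include_b = TRUE, m_power = NULL,
                    covariates_M = NULL, covariates_Y = NULL,
                    variance_M = NULL, variance_Y = NULL,
                    rho_free = TRUE, moderator = NULL, levels = NULL) {
  stopifnot(length(p) == 1L, length(q) == 1L, is.finite(p), is.finite(q))
  if (!is.null(moderator) && is.null(levels))
    stop("moderator levels must be supplied with a moderator")
  lev <- if (is.null(moderator)) NA_character_ else as.character(levels)

  per_level <- function(val, what) {
    if (is.null(val)) return(stats::setNames(rep(NA_real_, length(lev)), lev))
    if (length(val) == 1L && is.null(names(val)))
      return(stats::setNames(rep(unname(val), length(lev)), lev))
    if (!all(lev %in% names(val)))
      stop("named ", what, " must cover every moderator level")
    val[as.character(lev)]
  }
  qp <- per_level(q_prime, "q_prime")
  pp <- per_level(p_prime, "p_prime")
  ib_num <- stats::setNames(as.numeric(include_b), names(include_b))
  ib <- per_level(ib_num, "include_b") > 0
  ib[is.na(ib)] <- FALSE
  mp <- if (is.null(m_power)) q else m_power

  term_df <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(var = character(), power = numeric(),
                        stringsAsFactors = FALSE))
    stopifnot(all(c("var", "power") %in% names(df)))
    data.frame(var = as.character(df$var), power = as.numeric(df$power),
               stringsAsFactors = FALSE)
  }

  structure(list(
    p = p, q = q, m_power = mp,
    xm = data.frame(level = lev, power = unname(qp), stringsAsFactors = FALSE),
    xy = data.frame(level = lev, power = unname(pp), stringsAsFactors = FALSE),
    bm = data.frame(level = lev, include = unname(ib), stringsAsFactors = FALSE),
    cov_M = term_df(covariates_M), cov_Y = term_df(covariates_Y),
    var_M = term_df(variance_M), var_Y = term_df(variance_Y),
    rho_free = isTRUE(rho_free),
    moderator = moderator, levels = lev
  ), class = "mm_spec")
}

# p'' implied by the stored mediator-term exponent.
spec_pdp <- function(spec) {
  if (spec$q != 0) spec$m_power / spec$q
  else if (spec$m_power == 0) 1 else NA_real_
}

is_moderated <- function(spec) !is.null(spec$moderator)

#' @export
print.mm_spec <- function(x, ...) {
  cat("Composite monotonic mediation model specification\n")
  cat(sprintf("  outcome power p = %g, mediator power q = %g (p'' = %g)\n",
              x$p, x$q, spec_pdp(x)))
  fmt <- function(v) ifelse(is.na(v), "absent", sprintf("%g", v))
  if (is_moderated(x)) {
    cat(sprintf("  moderator '%s' with levels: %s\n", x$moderator,
                paste(x$levels, collapse = ", ")))
    for (i in seq_along(x$levels))
      cat(sprintf("   level %s: q' = %s, p' = %s, M-term %s\n",
                  x$levels[i], fmt(x$xm$power[i]), fmt(x$xy$power[i]),
                  if (x$bm$include[i]) "present" else "absent"))
  } else {
    cat(sprintf("  q' = %s, p' = %s, M-term %s\n",
                fmt(x$xm$power[1]), fmt(x$xy$power[1]),
                if (x$bm$include[1]) "present" else "absent"))
  }
  if (nrow(x$cov_M) + nrow(x$cov_Y) > 0)
    cat(sprintf("  covariate terms: %d (M-stream), %d (Y-stream)\n",
                nrow(x$cov_M), nrow(x$cov_Y)))
  if (nrow(x$var_M) + nrow(x$var_Y) > 0)
    cat(sprintf("  variance terms: %d (M-stream), %d (Y-stream)\n",
                nrow(x$var_M), nrow(x$var_Y)))
  cat(sprintf("  covariance: %s\n",
              if (x$rho_free) "CSH (free rho)" else "independent (rho = 0)"))
  invisible(x)
}

# ---- design construction ---------------------------------------------------

# Indicator of a moderator level (all-ones when unmoderated).
level_ind <- function(data, spec, level) {
  if (!is_moderated(spec) || is.na(level)) rep(1, nrow(data))
  else as.numeric(as.character(data[[spec$moderator]]) == level)
}

# Builds transformed responses, mean/variance design matrices and column
# metadata for a spec on a data set.  Column metadata rows carry
# (stream, role, var, power, level) so coefficients can be mapped back to
# the mediation parameters i_M, a, i_Y, c', b.
build_design <- function(data, spec) {
  n <- nrow(data)
  yM <- power_transform_outcome(data$m, spec$q)
  yY <- power_transform_outcome(data$y, spec$p)

  cols_M <- list(); cols_Y <- list()
  info <- function(stream, role, var, power, level)
    data.frame(stream = stream, role = role, var = var, power = power,
               level = level, stringsAsFactors = FALSE)
  info_M <- list(); info_Y <- list()

  for (lv in spec$levels) {
    ind <- level_ind(data, spec, lv)
    cols_M[[length(cols_M) + 1L]] <- ind
    info_M[[length(info_M) + 1L]] <- info("M", "intercept", "1", NA, lv)
    cols_Y[[length(cols_Y) + 1L]] <- ind
    info_Y[[length(info_Y) + 1L]] <- info("Y", "intercept", "1", NA, lv)
  }
  for (i in seq_len(nrow(spec$xm))) {
    pw <- spec$xm$power[i]
    if (is.na(pw)) next
    lv <- spec$xm$level[i]
    cols_M[[length(cols_M) + 1L]] <-
      level_ind(data, spec, lv) * power_transform(data$x, pw)
    info_M[[length(info_M) + 1L]] <- info("M", "x", "x", pw, lv)
  }
  for (i in seq_len(nrow(spec$xy))) {
    pw <- spec$xy$power[i]
    if (is.na(pw)) next
    lv <- spec$xy$level[i]
    cols_Y[[length(cols_Y) + 1L]] <-
      level_ind(data, spec, lv) * power_transform(data$x, pw)
    info_Y[[length(info_Y) + 1L]] <- info("Y", "x", "x", pw, lv)
  }
  for (i in seq_len(nrow(spec$bm))) {
    if (!spec$bm$include[i]) next
    lv <- spec$bm$level[i]
    cols_Y[[length(cols_Y) + 1L]] <-
      level_ind(data, spec, lv) * power_transform_outcome(data$m, spec$m_power)
    info_Y[[length(info_Y) + 1L]] <- info("Y", "m", "m", spec$m_power, lv)
  }
  add_cov <- function(df, stream) {
    for (i in seq_len(nrow(df))) {
      v <- power_transform(data[[df$var[i]]], df$power[i])
      if (stream == "M") {
        cols_M[[length(cols_M) + 1L]] <<- v
        info_M[[length(info_M) + 1L]] <<-
          info("M", "cov", df$var[i], df$power[i], NA_character_)
      } else {
        cols_Y[[length(cols_Y) + 1L]] <<- v
        info_Y[[length(info_Y) + 1L]] <<-
          info("Y", "cov", df$var[i], df$power[i], NA_character_)
      }
    }
  }
  add_cov(spec$cov_M, "M"); add_cov(spec$cov_Y, "Y")

  # log-variance designs: always an intercept, plus any variance terms
  vbuild <- function(df) {
    cols <- list(rep(1, n))
    for (i in seq_len(nrow(df)))
      cols[[length(cols) + 1L]] <- power_transform(data[[df$var[i]]], df$power[i])
    do.call(cbind, cols)
  }

  list(XM = do.call(cbind, cols_M), XY = do.call(cbind, cols_Y),
       VM = vbuild(spec$var_M), VY = vbuild(spec$var_Y),
       yM = yM, yY = yY,
       info_M = do.call(rbind, info_M), info_Y = do.call(rbind, info_Y),
       n = n)
}

# ---- small spec-editing helpers used by the searches ----------------------

set_x_power <- function(spec, stream, power, level = NA_character_) {
  tab <- if (stream == "M") "xm" else "xy"
  i <- match_level(spec[[tab]]$level, level)
  spec[[tab]]$power[i] <- power
  spec
}

get_x_power <- function(spec, stream, level = NA_character_) {
  tab <- if (stream == "M") "xm" else "xy"
  spec[[tab]]$power[match_level(spec[[tab]]$level, level)]
}

set_b_term <- function(spec, include, level = NA_character_) {
  spec$bm$include[match_level(spec$bm$level, level)] <- include
  spec
}

match_level <- function(levels, level) {
  i <- if (is.na(level)) which(is.na(levels)) else which(levels == level)
  if (length(i) != 1L) stop("unknown moderator level: ", level)
  i
}

add_var_term <- function(spec, stream, var, power) {
  tab <- if (stream == "M") "var_M" else "var_Y"
  spec[[tab]] <- rbind(spec[[tab]],
                       data.frame(var = var, power = power,
                                  stringsAsFactors = FALSE))
  spec
}

drop_var_term <- function(spec, stream, i) {
  tab <- if (stream == "M") "var_M" else "var_Y"
  spec[[tab]] <- spec[[tab]][-i, , drop = FALSE]
  spec
}

add_cov_term <- function(spec, stream, var, power) {
  tab <- if (stream == "M") "cov_M" else "cov_Y"
  spec[[tab]] <- rbind(spec[[tab]],
                       data.frame(var = var, power = power,
                                  stringsAsFactors = FALSE))
  spec
}

drop_cov_term <- function(spec, stream, i) {
  tab <- if (stream == "M") "cov_M" else "cov_Y"
  spec[[tab]] <- spec[[tab]][-i, , drop = FALSE]
  spec
}
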