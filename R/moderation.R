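# Moderated monotonic mediation: per-level intercepts, slopes, and powers
# for a discrete moderator, with component ratio tests and per-level
# effect curves.

#' Fit a moderated monotonic mediation model
#'
#' For a discrete moderator, the composite model gains per-level
#' intercepts in both streams, a per-level transformed-mediator slope, and
#' per-level X transforms whose powers are searched independently; the
#' outcome and mediator powers \code{p} and \code{q} stay shared across
#' levels.  Per-level X candidates compete jointly for inclusion order by
#' LCV gain, and any level's X term may end up absent (no pathway at that
#' level).  Variance models are not moderated.
#'
#' @param data mediation data frame including the moderator column.
#' @param moderator name of the (discrete) moderator column; continuous
#'   moderators must be binned upstream.
#' @param p,q shared outcome and mediator powers.
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param rho_free covariance structure.
#' @param min_level_count minimum subjects per level (default 10).
#' @param base_spec optional starting moderated \code{\link{mm_spec}}
#'   (X terms absent).
#' @param scorer optional shared scorer.
#' @return list with \code{spec}, \code{fit}, \code{score}.
#' @export
fit_moderated <- function(data, moderator, p = 1, q = 1, folds,
                          cfg = mm_search_config(), rho_free = TRUE,
                          min_level_count = 10L, base_spec = NULL,
                          scorer = NULL) {
  zvals <- as.character(data[[moderator]])
  if (is.null(zvals[1])) stop("moderator column not found: ", moderator)
  levs <- sort(unique(zvals))
  cnt <- table(zvals)
  low <- names(cnt)[cnt < min_level_count]
  if (length(low))
    stop("moderator level(s) below the minimum count of ", min_level_count,
         ": ", paste(low, collapse = ", "))
  if (is.null(base_spec))
    base_spec <- mm_spec(p = p, q = q, q_prime = NULL, p_prime = NULL,
                         include_b = TRUE, rho_free = rho_free,
                         moderator = moderator, levels = levs)
  scorer <- scorer %||% make_scorer(data, folds)
  m <- 2L * nrow(data)
  cur <- scorer(base_spec)
  spec <- base_spec

  # joint greedy competition over (stream, level) X-term candidates
  cands <- list()
  for (lv in levs)
    for (st in c("M", "Y"))
      cands[[length(cands) + 1L]] <- list(stream = st, level = lv)
  while (length(cands)) {
    best <- NULL
    for (i in seq_along(cands)) {
      cd <- cands[[i]]
      res <- search_term_power(
        scorer, spec,
        function(s, pw) set_x_power(s, cd$stream, pw, cd$level),
        cfg, m, base_score = cur)
      if (res$added && is.finite(res$score) &&
          (is.null(best) || res$score > best$res$score))
        best <- list(i = i, cd = cd, res = res)
    }
    if (is.null(best)) break
    spec <- set_x_power(spec, best$cd$stream, best$res$power, best$cd$level)
    cur <- best$res$score
    cands <- cands[-best$i]
  }
  list(spec = spec, fit = fit_composite(data, spec), score = cur)
}

# Re-refines the X powers remaining in a moderated spec (used after a
# component is removed or shared).
.refine_moderated <- function(scorer, spec, cfg, m, cur) {
  stop_tol <- cfg$stop_tolerance %||% lcv_cutoff(m)
  for (slot in power_slots(spec, include_cov = FALSE)) {
    if (!grepl("^[pq]'", slot$label)) next
    ev <- function(pw) {
      if (abs(pw) < cfg$min_abs_power) return(NA_real_)
      scorer(slot$set(spec, round(pw, 6)))
    }
    pw <- refine_power(ev, slot$get(spec), cfg, stop_tol,
                       lo_bound = -cfg$max_abs_power,
                       hi_bound = cfg$max_abs_power)
    sc <- .finite_or(ev(pw))
    if (sc > cur) {
      spec <- slot$set(spec, pw)
      cur <- sc
    }
  }
  list(spec = spec, score = cur)
}

#' Ratio tests for the moderation components
#'
#' Three global tests replace the per-level terms by one shared term
#' (moderation of X on M, of X on Y, and of M on Y in turn; the shared
#' power is re-searched), plus per-level removal tests dropping each
#' level's individual term.  Every reduced model is compared to the full
#' moderated model by an LCV ratio test: an insubstantial decrease marks
#' the reduced model a parsimonious, competitive alternative (no distinct
#' moderation of that component).
#'
#' @param data mediation data frame.
#' @param spec the full moderated \code{\link{mm_spec}}.
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param scorer optional shared scorer.
#' @return named list of entries, each with the reduced \code{spec}, its
#'   \code{score}, and the \code{test} (\code{"mm_lcv_test"}).
#' @export
moderation_component_tests <- function(data, spec, folds,
                                       cfg = mm_search_config(),
                                       scorer = NULL) {
  stopifnot(is_moderated(spec))
  scorer <- scorer %||% make_scorer(data, folds)
  m <- 2L * nrow(data)
  full_score <- scorer(spec)
  out <- list()
  push <- function(name, red_spec, red_score) {
    if (!is.finite(red_score)) return()
    tst <- lcv_ratio_test(min(red_score, full_score),
                          max(red_score, full_score), m)
    out[[name]] <<- list(spec = red_spec, score = red_score, test = tst)
  }

  # global: shared X -> M term
  sh <- spec
  sh$xm <- data.frame(level = NA_character_, power = NA_real_,
                      stringsAsFactors = FALSE)
  res <- search_term_power(scorer, sh,
                           function(s, pw) set_x_power(s, "M", pw),
                           cfg, m, base_score = scorer(sh))
  if (res$added) sh <- set_x_power(sh, "M", res$power)
  r <- .refine_moderated(scorer, sh, cfg, m, scorer(sh))
  push("shared_X_on_M", r$spec, r$score)

  # global: shared X -> Y term
  sh <- spec
  sh$xy <- data.frame(level = NA_character_, power = NA_real_,
                      stringsAsFactors = FALSE)
  res <- search_term_power(scorer, sh,
                           function(s, pw) set_x_power(s, "Y", pw),
                           cfg, m, base_score = scorer(sh))
  if (res$added) sh <- set_x_power(sh, "Y", res$power)
  r <- .refine_moderated(scorer, sh, cfg, m, scorer(sh))
  push("shared_X_on_Y", r$spec, r$score)

  # global: shared M -> Y slope
  sh <- spec
  sh$bm <- data.frame(level = NA_character_, include = TRUE,
                      stringsAsFactors = FALSE)
  r <- .refine_moderated(scorer, sh, cfg, m, scorer(sh))
  push("shared_M_on_Y", r$spec, r$score)

  # per-level removals
  for (i in seq_len(nrow(spec$xm))) {
    if (is.na(spec$xm$power[i])) next
    red <- spec
    red$xm$power[i] <- NA_real_
    r <- .refine_moderated(scorer, red, cfg, m, scorer(red))
    push(paste0("drop_X_on_M_level_", spec$xm$level[i]), r$spec, r$score)
  }
  for (i in seq_len(nrow(spec$xy))) {
    if (is.na(spec$xy$power[i])) next
    red <- spec
    red$xy$power[i] <- NA_real_
    r <- .refine_moderated(scorer, red, cfg, m, scorer(red))
    push(paste0("drop_X_on_Y_level_", spec$xy$level[i]), r$spec, r$score)
  }
  for (i in seq_len(nrow(spec$bm))) {
    if (!spec$bm$include[i]) next
    red <- spec
    red$bm$include[i] <- FALSE
    r <- .refine_moderated(scorer, red, cfg, m, scorer(red))
    push(paste0("drop_M_on_Y_level_", spec$bm$level[i]), r$spec, r$score)
  }
  attr(out, "full_score") <- full_score
  out
}

#' Per-level effect curves and bootstrap CIs for a moderated model
#'
#' Evaluates the instantaneous effect curves at one moderator level using
#' the level-specific coefficients and powers, and (when the pathway is
#' present) the bias-corrected bootstrap CI with its level-specific
#' normalized width W(z).  Levels without a mediation pathway report
#' identically zero indirect effects with a flag and no CI.
#'
#' @param data mediation data frame.
#' @param fit fitted moderated model (\code{"mm_fit"}).
#' @param x_grid strictly positive predictor values.
#' @param level moderator level.
#' @param B,bias_correct,seed bootstrap settings (see
#'   \code{\link{bootstrap_nie}}).
#' @return list with \code{effects} (\code{"mm_effects"}), \code{ci}
#'   (\code{"mm_boot"} or \code{NULL}), and \code{mediation} flag.
#' @export
moderated_effects <- function(data, fit, x_grid, level, B = 1000L,
                              bias_correct = TRUE, seed = 1L) {
  spec <- fit$spec
  stopifnot(is_moderated(spec))
  level <- as.character(level)
  if (!level %in% spec$levels) stop("unknown moderator level: ", level)
  eff <- instantaneous_effects(fit, x_grid, level = level)
  cf <- mediation_coefs(fit, level)
  has_path <- !is.na(cf["a"]) && !is.na(cf["b"])
  ci <- NULL
  if (has_path)
    ci <- bootstrap_nie(data, spec, x_grid, B = B,
                        bias_correct = bias_correct, seed = seed,
                        level = level)
  list(effects = eff, ci = ci, mediation = has_path, level = level)
}
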