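# Heuristic LCV-guided power searches: single-transform expansion for a
# predictor, the constrained X1/X2 expansion of the composite model, the
# optional cyclic power adjustment, the two-stage (p, q) outcome-power
# search, and the greedy variance/covariate model searches.

#' Search configuration for the adaptive power searches
#'
#' @param initial_grid coarse starting powers (zero excluded by design).
#' @param refine_steps successive refinement step sizes.
#' @param min_abs_power smallest admissible absolute power for predictor
#'   transforms.
#' @param max_abs_power cap on predictor powers during boundary marching.
#' @param stop_tolerance percent-decrease tolerance ending the per-digit
#'   refinement; defaults to the LCV ratio-test cutoff for the data.
#' @param expansion_tolerance percent-decrease tolerance for admitting a
#'   transform; defaults to 2.5 times the cutoff (a generous setting, so
#'   near-ties still admit the transform).
#' @param pq_bounds interval bounding the outcome/mediator power search.
#' @return list of class \code{"mm_search_config"}.
#' @export
mm_search_config <- function(initial_grid = c(seq(-3, -0.5, by = 0.5),
                                              seq(0.5, 3, by = 0.5)),
                             refine_steps = c(0.1, 0.01, 0.001, 0.0001),
                             min_abs_power = 1e-4,
                             max_abs_power = 20,
                             stop_tolerance = NULL,
                             expansion_tolerance = NULL,
                             pq_bounds = c(-5, 5)) {
  stopifnot(!any(initial_grid == 0), all(diff(refine_steps) < 0))
  structure(list(initial_grid = initial_grid, refine_steps = refine_steps,
                 min_abs_power = min_abs_power, max_abs_power = max_abs_power,
                 stop_tolerance = stop_tolerance,
                 expansion_tolerance = expansion_tolerance,
                 pq_bounds = pq_bounds),
            class = "mm_search_config")
}

# Compact cache key for a spec (fitted-model reuse inside searches).
spec_key <- function(spec) {
  fmt <- function(x) paste(sprintf("%.6g", as.numeric(x)), collapse = ",")
  paste(fmt(c(spec$p, spec$q, spec$m_power)),
        fmt(spec$xm$power), paste(spec$xm$level, collapse = ","),
        fmt(spec$xy$power), paste(spec$xy$level, collapse = ","),
        paste(spec$bm$include, collapse = ","),
        paste(spec$cov_M$var, fmt(spec$cov_M$power), collapse = ";"),
        paste(spec$cov_Y$var, fmt(spec$cov_Y$power), collapse = ";"),
        paste(spec$var_M$var, fmt(spec$var_M$power), collapse = ";"),
        paste(spec$var_Y$var, fmt(spec$var_Y$power), collapse = ";"),
        spec$rho_free, sep = "|")
}

# Memoizing LCV scorer over specs for one (data, folds) pair; failed fits
# score NA (treated as -Inf by the searches).
make_scorer <- function(data, folds, power_adjusted = TRUE) {
  cache <- new.env(parent = emptyenv())
  function(spec) {
    key <- spec_key(spec)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    sc <- tryCatch(lcv(data, spec, folds, power_adjusted)$score,
                   error = function(e) NA_real_)
    cache[[key]] <- sc
    sc
  }
}

.finite_or <- function(x, alt = -Inf) if (length(x) && is.finite(x)) x else alt

# One-dimensional hill climb of ev() from `center` with step `step`;
# returns the final center and the three bracketing scores.
hill_climb_1d <- function(ev, center, step, lo_bound = -Inf, hi_bound = Inf) {
  s_mid <- .finite_or(ev(center))
  up_ok <- center + step <= hi_bound
  dn_ok <- center - step >= lo_bound
  s_up <- if (up_ok) .finite_or(ev(center + step)) else -Inf
  s_dn <- if (dn_ok) .finite_or(ev(center - step)) else -Inf
  if (s_mid >= s_up && s_mid >= s_dn)
    return(list(center = center, lo = s_dn, mid = s_mid, hi = s_up))
  dir <- if (s_up > s_dn) 1 else -1
  prev_s <- s_mid
  cur <- round(center + dir * step, 6)
  cur_s <- max(s_up, s_dn)
  repeat {
    nxt <- round(cur + dir * step, 6)
    if (nxt < lo_bound || nxt > hi_bound) {
      nxt_s <- -Inf
      break
    }
    nxt_s <- .finite_or(ev(nxt))
    if (nxt_s <= cur_s) break
    prev_s <- cur_s
    cur <- nxt
    cur_s <- nxt_s
  }
  list(center = cur, lo = prev_s, mid = cur_s, hi = nxt_s)
}

# Per-digit refinement around `start`: hill-climb at each step size, and
# stop once the three bracketing scores are within `stop_tol` percent of
# each other (flat surface at that resolution).
refine_power <- function(ev, start, cfg, stop_tol,
                         lo_bound = -Inf, hi_bound = Inf) {
  cur <- start
  for (step in cfg$refine_steps) {
    res <- hill_climb_1d(ev, cur, step, lo_bound, hi_bound)
    cur <- res$center
    tri <- c(res$lo, res$mid, res$hi)
    tri <- tri[is.finite(tri)]
    if (length(tri) >= 2) {
      pd <- 100 * (max(tri) - min(tri)) / max(tri)
      if (pd <= stop_tol) break
    }
  }
  cur
}

#' Search the power for a single added transform
#'
#' Expands a base model by one power transform whose exponent is chosen by
#' maximizing the LCV score: a coarse grid search, outward marching in unit
#' steps when the grid maximum sits on the boundary (until a bracketing
#' local maximum is found), then per-digit refinement with an
#' early-stopping tolerance.  The transform is admitted when its score is
#' not below the base score by more than the (generous) expansion
#' tolerance; a refused transform supports the conclusion that the
#' predictor adds nothing beyond the base model.
#'
#' @param scorer a memoizing scorer from \code{make_scorer}, or data/folds
#'   via the convenience wrapper \code{\link{search_x_power}}.
#' @param base_spec the base \code{\link{mm_spec}} (term not yet present).
#' @param add_fn function \code{(spec, power) -> spec} inserting the
#'   candidate transform.
#' @param cfg an \code{\link{mm_search_config}}.
#' @param m total number of measurements (sets default tolerances).
#' @param base_score LCV score of the base model (computed if missing).
#' @return list with \code{power}, \code{score}, \code{added},
#'   \code{base_score}.
#' @keywords internal
search_term_power <- function(scorer, base_spec, add_fn, cfg, m,
                              base_score = NULL) {
  if (is.null(base_score)) base_score <- scorer(base_spec)
  ev <- function(p) {
    if (abs(p) < cfg$min_abs_power) return(NA_real_)
    scorer(add_fn(base_spec, round(p, 6)))
  }
  grid <- cfg$initial_grid
  gs <- vapply(grid, ev, numeric(1))
  if (all(!is.finite(gs)))
    return(list(power = NA_real_, score = NA_real_, added = FALSE,
                base_score = base_score))
  best <- grid[which.max(gs)]
  best_s <- max(gs, na.rm = TRUE)
  if (best == min(grid) || best == max(grid)) {
    delta <- if (best == min(grid)) -1 else 1
    repeat {
      nxt <- best + delta
      if (abs(nxt) > cfg$max_abs_power) break
      ns <- .finite_or(ev(nxt))
      if (ns <= best_s) break
      best <- nxt
      best_s <- ns
    }
  }
  stop_tol <- cfg$stop_tolerance %||% lcv_cutoff(m)
  best <- refine_power(ev, best, cfg, stop_tol,
                       lo_bound = -cfg$max_abs_power,
                       hi_bound = cfg$max_abs_power)
  sc <- ev(best)
  exp_tol <- cfg$expansion_tolerance %||% (2.5 * lcv_cutoff(m))
  added <- is.finite(sc) &&
    (!is.finite(base_score) || 100 * (base_score - sc) / base_score < exp_tol)
  list(power = best, score = sc, added = added, base_score = base_score)
}

#' Search the power transform of X for one stream
#'
#' Convenience wrapper around the single-transform search for the
#' predictor term of the mediator stream (\code{stream = "M"}, power q')
#' or outcome stream (\code{stream = "Y"}, power p').
#'
#' @param data mediation data frame.
#' @param base_spec base \code{\link{mm_spec}} without that stream's X term.
#' @param stream \code{"M"} or \code{"Y"}.
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param level moderator level (default unmoderated).
#' @return list with \code{power}, \code{score}, \code{added}.
#' @export
search_x_power <- function(data, base_spec, stream = c("M", "Y"), folds,
                           cfg = mm_search_config(), level = NA_character_) {
  stream <- match.arg(stream)
  scorer <- make_scorer(data, folds)
  search_term_power(scorer, base_spec,
                    function(s, p) set_x_power(s, stream, p, level),
                    cfg, m = 2L * nrow(data))
}

#' Constrained expansion of the composite model in X
#'
#' For fixed outcome/mediator powers, expands the base composite model
#' (intercepts, the transformed-mediator term, the chosen covariance
#' structure) by at most one power transform of X per stream: both
#' single-term expansions are searched, the one with the larger LCV score
#' is kept first (ties go to the outcome stream), and the other stream is
#' then searched from the enlarged model.  Either transform may end up
#' absent when its expansion fails the tolerance, which is how the
#' \code{a = 0} and \code{c' = 0} assessments arise.
#'
#' @param data mediation data frame.
#' @param p,q outcome and mediator powers (ignored when \code{base_spec}
#'   is supplied).
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param rho_free covariance structure for the default base model.
#' @param base_spec optional explicit base model (X terms absent).
#' @param streams which streams to search (default both).
#' @param scorer optional shared memoizing scorer.
#' @return list with the selected \code{spec}, its LCV \code{score}, and
#'   the per-stream search results.
#' @export
constrained_expansion <- function(data, p = 1, q = 1, folds,
                                  cfg = mm_search_config(), rho_free = TRUE,
                                  base_spec = NULL, streams = c("M", "Y"),
                                  scorer = NULL) {
  if (is.null(base_spec))
    base_spec <- mm_spec(p = p, q = q, q_prime = NULL, p_prime = NULL,
                         include_b = TRUE, rho_free = rho_free)
  scorer <- scorer %||% make_scorer(data, folds)
  m <- 2L * nrow(data)
  base_score <- scorer(base_spec)
  res <- list()
  for (st in streams)
    res[[st]] <- search_term_power(
      scorer, base_spec, function(s, pw) set_x_power(s, st, pw),
      cfg, m, base_score = base_score)

  spec <- base_spec
  score <- base_score
  if (length(streams) == 1L) {
    st <- streams
    if (res[[st]]$added) {
      spec <- set_x_power(spec, st, res[[st]]$power)
      score <- res[[st]]$score
    }
  } else {
    sM <- .finite_or(res$M$score); sY <- .finite_or(res$Y$score)
    first <- if (sY >= sM) "Y" else "M"
    second <- setdiff(c("M", "Y"), first)
    if (res[[first]]$added) {
      spec <- set_x_power(spec, first, res[[first]]$power)
      score <- res[[first]]$score
      r2 <- search_term_power(
        scorer, spec, function(s, pw) set_x_power(s, second, pw),
        cfg, m, base_score = score)
      res[[paste0(second, "2")]] <- r2
      if (r2$added) {
        spec <- set_x_power(spec, second, r2$power)
        score <- r2$score
      }
    }
  }
  list(spec = spec, score = score, search = res, base_score = base_score)
}

# The adjustable power slots of a spec: X transforms per level, variance
# terms, covariate terms.
power_slots <- function(spec, include_cov = TRUE) {
  slots <- list()
  for (i in seq_len(nrow(spec$xm)))
    if (!is.na(spec$xm$power[i]))
      slots[[length(slots) + 1L]] <- list(
        label = paste0("q'[", spec$xm$level[i], "]"),
        get = local({ii <- i; function(s) s$xm$power[ii]}),
        set = local({ii <- i; function(s, p) { s$xm$power[ii] <- p; s }}))
  for (i in seq_len(nrow(spec$xy)))
    if (!is.na(spec$xy$power[i]))
      slots[[length(slots) + 1L]] <- list(
        label = paste0("p'[", spec$xy$level[i], "]"),
        get = local({ii <- i; function(s) s$xy$power[ii]}),
        set = local({ii <- i; function(s, p) { s$xy$power[ii] <- p; s }}))
  for (tab in c("var_M", "var_Y"))
    for (i in seq_len(nrow(spec[[tab]])))
      slots[[length(slots) + 1L]] <- list(
        label = paste0(tab, ":", spec[[tab]]$var[i]),
        get = local({tt <- tab; ii <- i; function(s) s[[tt]]$power[ii]}),
        set = local({tt <- tab; ii <- i
                     function(s, p) { s[[tt]]$power[ii] <- p; s }}))
  if (include_cov)
    for (tab in c("cov_M", "cov_Y"))
      for (i in seq_len(nrow(spec[[tab]])))
        slots[[length(slots) + 1L]] <- list(
          label = paste0(tab, ":", spec[[tab]]$var[i]),
          get = local({tt <- tab; ii <- i; function(s) s[[tt]]$power[ii]}),
          set = local({tt <- tab; ii <- i
                       function(s, p) { s[[tt]]$power[ii] <- p; s }}))
  slots
}

#' Cyclic power adjustment of an expanded model
#'
#' Re-runs the per-digit refinement for every included power (X transforms,
#' variance-term and covariate powers) from its current value, accepting
#' the single best-improving adjustment per cycle and stopping when no
#' adjustment improves the LCV score.  Optional in the standard pipeline.
#'
#' @param data mediation data frame.
#' @param spec current \code{\link{mm_spec}}.
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param scorer optional shared scorer.
#' @param max_cycles safety cap on adjustment cycles.
#' @return list with the adjusted \code{spec} and its \code{score}.
#' @export
adjust_powers <- function(data, spec, folds, cfg = mm_search_config(),
                          scorer = NULL, max_cycles = 20L) {
  scorer <- scorer %||% make_scorer(data, folds)
  m <- 2L * nrow(data)
  stop_tol <- cfg$stop_tolerance %||% lcv_cutoff(m)
  cur_score <- scorer(spec)
  for (cycle in seq_len(max_cycles)) {
    best <- NULL
    for (slot in power_slots(spec)) {
      ev <- function(p) {
        if (abs(p) < cfg$min_abs_power) return(NA_real_)
        scorer(slot$set(spec, round(p, 6)))
      }
      pw <- refine_power(ev, slot$get(spec), cfg, stop_tol,
                         lo_bound = -cfg$max_abs_power,
                         hi_bound = cfg$max_abs_power)
      sc <- .finite_or(ev(pw))
      if (sc > cur_score && (is.null(best) || sc > best$score))
        best <- list(slot = slot, power = pw, score = sc)
    }
    if (is.null(best)) break
    spec <- best$slot$set(spec, best$power)
    cur_score <- best$score
  }
  list(spec = spec, score = cur_score)
}

#' Two-stage search for the outcome and mediator powers
#'
#' Selects \code{(p, q)} by maximizing the power-adjusted LCV score.
#' Starting from \code{(1, 1)}, coordinate-wise hill climbs of each power
#' (the other held at 1) are run at step 0.5, the better branch is kept and
#' the other power climbed from there; the procedure repeats at step 0.1
#' and stops at one decimal.  Every candidate \code{(p, q)} is scored by
#' re-running the constrained X expansion at those powers.
#'
#' @param data mediation data frame.
#' @param folds fold assignment.
#' @param cfg search configuration (see \code{pq_bounds}).
#' @param rho_free covariance structure used throughout the search.
#' @param base_spec_fn optional function \code{(p, q) -> mm_spec} supplying
#'   the base model at each candidate (defaults to the plain composite
#'   base).
#' @return list with \code{p}, \code{q}, the selected \code{spec}, its
#'   \code{score}, and the evaluated \code{trail}.
#' @export
search_outcome_powers <- function(data, folds, cfg = mm_search_config(),
                                  rho_free = TRUE, base_spec_fn = NULL) {
  scorer <- make_scorer(data, folds)
  ce_cache <- new.env(parent = emptyenv())
  trail <- list()
  eval_pq <- function(p, q) {
    key <- sprintf("%.6g|%.6g", p, q)
    hit <- ce_cache[[key]]
    if (!is.null(hit)) return(hit)
    base <- if (is.null(base_spec_fn)) NULL else base_spec_fn(p, q)
    ce <- tryCatch(
      constrained_expansion(data, p = p, q = q, folds = folds, cfg = cfg,
                            rho_free = rho_free, base_spec = base,
                            scorer = scorer),
      error = function(e) list(spec = NULL, score = NA_real_))
    ce_cache[[key]] <- ce
    trail[[length(trail) + 1L]] <<- list(p = p, q = q, score = ce$score)
    ce
  }
  lo <- cfg$pq_bounds[1]; hi <- cfg$pq_bounds[2]
  climb <- function(p, q, which, step) {
    ev <- function(v) {
      if (which == "p") eval_pq(round(v, 6), q)$score
      else eval_pq(p, round(v, 6))$score
    }
    start <- if (which == "p") p else q
    hill_climb_1d(ev, start, step, lo_bound = lo, hi_bound = hi)$center
  }
  stage <- function(p, q, step) {
    p1 <- climb(p, q = q, which = "p", step = step)
    q1 <- climb(p = p, q, which = "q", step = step)
    sp <- .finite_or(eval_pq(p1, q)$score)
    sq <- .finite_or(eval_pq(p, q1)$score)
    if (sp >= sq) {
      q2 <- climb(p = p1, q = q, which = "q", step = step)
      c(p1, q2)
    } else {
      p2 <- climb(p = p, q = q1, which = "p", step = step)
      c(p2, q1)
    }
  }
  s1 <- stage(1, 1, 0.5)
  s2 <- stage(s1[1], s1[2], 0.1)
  final <- eval_pq(s2[1], s2[2])
  list(p = s2[1], q = s2[2], spec = final$spec, score = final$score,
       trail = trail)
}

# ---- greedy expansion / contraction for variances and covariates ----------

make_add_fn <- function(cand) {
  switch(cand$kind,
         var = function(s, p) add_var_term(s, cand$stream, cand$var, p),
         cov = function(s, p) add_cov_term(s, cand$stream, cand$var, p),
         stop("unknown candidate kind"))
}

greedy_expand <- function(scorer, spec, candidates, cfg, m,
                          cur = scorer(spec)) {
  added <- list()
  remaining <- candidates
  while (length(remaining)) {
    best <- NULL
    for (i in seq_along(remaining)) {
      res <- search_term_power(scorer, spec, make_add_fn(remaining[[i]]),
                               cfg, m, base_score = cur)
      if (res$added && is.finite(res$score) &&
          (is.null(best) || res$score > best$res$score))
        best <- list(i = i, cand = remaining[[i]], res = res)
    }
    if (is.null(best)) break
    spec <- make_add_fn(best$cand)(spec, best$res$power)
    cur <- best$res$score
    added[[length(added) + 1L]] <-
      c(best$cand, list(power = best$res$power, score = best$res$score))
    remaining <- remaining[-best$i]
  }
  list(spec = spec, score = cur, added = added)
}

# Removal candidates: variance terms and/or covariate mean terms (stream
# intercepts are protected).  Ties on LCV hurt are broken by removing the
# most recently added (last) term.
removal_candidates <- function(spec, kinds) {
  out <- list()
  if ("var" %in% kinds)
    for (tab in c("var_M", "var_Y")) {
      st <- if (tab == "var_M") "M" else "Y"
      for (i in seq_len(nrow(spec[[tab]])))
        out[[length(out) + 1L]] <- list(
          label = paste0(st, "-variance:", spec[[tab]]$var[i]),
          drop = local({s0 <- st; ii <- i
                        function(s) drop_var_term(s, s0, ii)}))
    }
  if ("cov" %in% kinds)
    for (tab in c("cov_M", "cov_Y")) {
      st <- if (tab == "cov_M") "M" else "Y"
      for (i in seq_len(nrow(spec[[tab]])))
        out[[length(out) + 1L]] <- list(
          label = paste0(st, "-mean:", spec[[tab]]$var[i]),
          drop = local({s0 <- st; ii <- i
                        function(s) drop_cov_term(s, s0, ii)}))
    }
  out
}

greedy_contract <- function(scorer, spec, kinds, cfg, m, cur,
                            refine_x_after = TRUE, data = NULL) {
  cutoff <- lcv_cutoff(m)
  stop_tol <- cfg$stop_tolerance %||% cutoff
  repeat {
    cands <- removal_candidates(spec, kinds)
    if (!length(cands)) break
    scores <- vapply(cands, function(cd)
      .finite_or(scorer(cd$drop(spec)), NA_real_), numeric(1))
    pd <- 100 * (cur - scores) / cur
    if (all(is.na(pd))) break
    mn <- min(pd, na.rm = TRUE)
    if (mn > cutoff) break
    pick <- max(which(pd == mn))          # tie -> most recently added
    spec <- cands[[pick]]$drop(spec)
    cur <- scores[pick]
    if (refine_x_after) {
      # re-adjust the mean powers p', q' after each removal
      for (slot in power_slots(spec, include_cov = FALSE)) {
        if (!grepl("^[pq]'", slot$label)) next
        ev <- function(p) {
          if (abs(p) < cfg$min_abs_power) return(NA_real_)
          scorer(slot$set(spec, round(p, 6)))
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
    }
  }
  list(spec = spec, score = cur)
}

#' Adaptive search for the variance models
#'
#' Greedy expansion of the per-stream log-variance models over
#' power-transformed candidates (by default X in each stream and the
#' mediator in the outcome stream), followed by a contraction that removes
#' variance terms whose removal costs less than the LCV ratio-test cutoff.
#' The variance-model intercepts are protected.  After each contraction
#' removal, the mean powers p' and q' are re-refined.  Homoscedastic data
#' typically see every added term contracted away, returning the
#' constant-variance base.
#'
#' @param data mediation data frame.
#' @param base_spec starting \code{\link{mm_spec}} (typically the selected
#'   mean model with constant variances).
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param candidates data frame with columns \code{stream}, \code{var};
#'   default X1, X2, M.
#' @param scorer optional shared scorer.
#' @return list with the selected \code{spec} and its \code{score}.
#' @export
search_variance_model <- function(data, base_spec, folds,
                                  cfg = mm_search_config(),
                                  candidates = NULL, scorer = NULL) {
  scorer <- scorer %||% make_scorer(data, folds)
  m <- 2L * nrow(data)
  if (is.null(candidates))
    candidates <- data.frame(stream = c("M", "Y", "Y"),
                             var = c("x", "x", "m"),
                             stringsAsFactors = FALSE)
  cands <- lapply(seq_len(nrow(candidates)), function(i)
    list(kind = "var", stream = candidates$stream[i], var = candidates$var[i]))
  exp_res <- greedy_expand(scorer, base_spec, cands, cfg, m)
  con_res <- greedy_contract(scorer, exp_res$spec, kinds = "var", cfg, m,
                             cur = exp_res$score)
  list(spec = con_res$spec, score = con_res$score, expanded = exp_res$added)
}

#' Adaptive covariate expansion and contraction
#'
#' Considers each covariate as a mean-model term in either stream and as a
#' log-variance term in either stream, expanding greedily by LCV and then
#' contracting covariate terms whose removal costs less than the cutoff.
#' X transforms are never removed here, but their powers are re-refined
#' after each contraction step; the transformed-mediator term is left
#' untouched.
#'
#' @param data mediation data frame.
#' @param base_spec starting \code{\link{mm_spec}}.
#' @param covariates character vector of covariate column names.
#' @param folds fold assignment.
#' @param cfg search configuration.
#' @param scorer optional shared scorer.
#' @return list with the selected \code{spec} and its \code{score}.
#' @export
search_covariates <- function(data, base_spec, covariates, folds,
                              cfg = mm_search_config(), scorer = NULL) {
  scorer <- scorer %||% make_scorer(data, folds)
  m <- 2L * nrow(data)
  cands <- list()
  for (z in covariates)
    for (st in c("M", "Y")) {
      cands[[length(cands) + 1L]] <- list(kind = "cov", stream = st, var = z)
      cands[[length(cands) + 1L]] <- list(kind = "var", stream = st, var = z)
    }
  exp_res <- greedy_expand(scorer, base_spec, cands, cfg, m)
  con_res <- greedy_contract(scorer, exp_res$spec, kinds = c("cov", "var"),
                             cfg, m, cur = exp_res$score)
  list(spec = con_res$spec, score = con_res$score, expanded = exp_res$added)
}
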