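# Likelihood cross-validation: fold assignment, LCV scores (standard and
# power-adjusted), the percent-decrease cutoff, ratio tests, and fold-count
# selection.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic seed splitter so folds / bootstrap / simulation streams can
# be re-run independently from one top-level seed.
derive_seed <- function(seed, tag) {
  ch <- utf8ToInt(as.character(tag))
  h <- sum(ch * seq_along(ch))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1000003 + 17) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Randomly assign subjects to cross-validation folds
#'
#' Subjects (not individual measurements) are assigned uniformly at random
#' to \code{k} folds, so both outcome-vector components of a subject always
#' share one fold.  Assignments with an empty fold are redrawn.  Fold sizes
#' are unequal by design; set \code{balanced = TRUE} for near-equal sizes.
#'
#' @param n_subjects number of subjects.
#' @param k number of folds, \code{2 <= k <= n_subjects}.
#' @param seed integer seed making the assignment reproducible.
#' @param balanced logical; default \code{FALSE} (uniform-multinomial).
#' @return an object of class \code{"mm_folds"}: list with \code{k},
#'   \code{assignment} (length-\code{n_subjects} fold index), \code{seed}.
#' @export
assign_folds <- function(n_subjects, k, seed = 1L, balanced = FALSE) {
  if (k < 2 || k > n_subjects)
    stop("k must satisfy 2 <= k <= n_subjects")
  asg <- with_seed(seed, {
    if (balanced) sample(rep_len(seq_len(k), n_subjects))
    else {
      repeat {
        a <- sample.int(k, n_subjects, replace = TRUE)
        if (length(unique(a)) == k) break
      }
      a
    }
  })
  structure(list(k = as.integer(k), assignment = asg, seed = seed,
                 balanced = balanced), class = "mm_folds")
}

#' @export
print.mm_folds <- function(x, ...) {
  cat(sprintf("%d-fold subject assignment (%d subjects, seed %s)\n",
              x$k, length(x$assignment), format(x$seed)))
  print(table(fold = x$assignment))
  invisible(x)
}

#' Cutoff for a substantial percent decrease in LCV scores
#'
#' Chi-square-based cutoff for LCV ratio tests:
#' \code{100 * (1 - exp(-qchisq(0.95, 1) / (2 * m)))}, where \code{m} is the
#' total number of outcome measurements (twice the number of subjects for
#' the bivariate composite model).  Strictly decreasing in \code{m}.
#'
#' @param m total number of outcome measurements, \code{m >= 1}.
#' @return cutoff in percent.
#' @examples
#' round(lcv_cutoff(374), 2)  # 0.51
#' round(lcv_cutoff(202), 2)  # 0.95
#' @export
lcv_cutoff <- function(m) {
  if (any(m < 1)) stop("m must be at least 1")
  100 * (1 - exp(-stats::qchisq(0.95, df = 1) / (2 * m)))
}

#' Likelihood cross-validation score of a composite model
#'
#' Geometric-mean deleted likelihood: for each fold, the model is fitted on
#' the fold's complement and the held-out subjects' joint likelihood is
#' evaluated at those estimates; the total deleted log-likelihood is
#' normalized by the number of outcome measurements (\code{2n}).  When the
#' outcome or mediator power differs from 1 and \code{power_adjusted} is
#' \code{TRUE} (default), each subject's likelihood carries the Jacobian
#' factors for \code{Y^p} and \code{M^q}, making scores comparable across
#' powers.
#'
#' @param data mediation data frame (columns \code{x}, \code{m}, \code{y},
#'   plus any covariates).
#' @param spec an \code{\link{mm_spec}}.
#' @param folds an \code{\link{assign_folds}} result (same assignment must
#'   be reused across all models compared on one data set).
#' @param power_adjusted logical, default \code{TRUE}.
#' @return object of class \code{"mm_lcv"}: \code{score}, \code{per_fold}
#'   deleted log-likelihoods, \code{m} (total measurements), \code{ok}.
#' @export
lcv <- function(data, spec, folds, power_adjusted = TRUE) {
  stopifnot(inherits(folds, "mm_folds"))
  check_mediation_data(data, spec)
  des <- build_design(data, spec)
  n <- des$n
  if (length(folds$assignment) != n)
    stop("fold assignment length does not match the data")
  per_fold <- rep(NA_real_, folds$k)
  ok <- TRUE
  for (h in seq_len(folds$k)) {
    test <- which(folds$assignment == h)
    train <- which(folds$assignment != h)
    core <- tryCatch(.fit_core(des, spec$rho_free, rows = train),
                     error = function(e) NULL)
    if (is.null(core) || !all(is.finite(c(core$betaM, core$betaY)))) {
      ok <- FALSE
      next
    }
    per_fold[h] <- sum(.core_loglik(core, des, rows = test))
  }
  jac <- 0
  if (power_adjusted)
    jac <- log_jacobian(data$y, spec$p) + log_jacobian(data$m, spec$q)
  total <- sum(per_fold) + jac
  score <- if (ok && is.finite(total)) exp(total / (2 * n)) else NA_real_
  structure(list(score = score, per_fold = per_fold, m = 2L * n,
                 power_adjusted = power_adjusted, p = spec$p, q = spec$q,
                 ok = ok && is.finite(total)),
            class = "mm_lcv")
}

#' @export
print.mm_lcv <- function(x, ...) {
  cat(sprintf("LCV%s score: %s  (%d measurements, %d folds%s)\n",
              if (x$power_adjusted) sprintf("(%g, %g)", x$p, x$q) else "",
              format(x$score, digits = 6), x$m, length(x$per_fold),
              if (x$ok) "" else ", FAILED FOLDS"))
  invisible(x)
}

#' LCV ratio test
#'
#' Compares two LCV scores by the percent decrease of the smaller relative
#' to the larger, against the sample-size-dependent cutoff
#' \code{\link{lcv_cutoff}(m)}.  A decrease above the cutoff means the
#' larger-score model substantially improves on the other; otherwise the
#' smaller-score model is a competitive alternative.
#'
#' @param lcv_smaller,lcv_larger LCV scores (numbers or \code{"mm_lcv"}
#'   objects).  If given in the wrong order they are swapped with a warning.
#' @param m total number of outcome measurements (taken from an
#'   \code{"mm_lcv"} argument when omitted).
#' @return object of class \code{"mm_lcv_test"} with \code{percent_decrease},
#'   \code{cutoff}, \code{substantial}, \code{m}.
#' @examples
#' lcv_ratio_test(0.015024, 0.015776, 374)  # 4.77%, substantial
#' @export
lcv_ratio_test <- function(lcv_smaller, lcv_larger, m = NULL) {
  grab <- function(z) if (inherits(z, "mm_lcv")) z$score else as.numeric(z)
  if (is.null(m)) {
    for (z in list(lcv_smaller, lcv_larger))
      if (inherits(z, "mm_lcv")) m <- z$m
    if (is.null(m)) stop("m (total measurements) must be supplied")
  }
  s <- grab(lcv_smaller); l <- grab(lcv_larger)
  if (!is.finite(s) || !is.finite(l) || s <= 0 || l <= 0)
    stop("LCV scores must be positive and finite")
  if (s > l) {
    warning("LCV scores given in the wrong order; swapping")
    tmp <- s; s <- l; l <- tmp
  }
  pd <- 100 * (l - s) / l
  cut <- lcv_cutoff(m)
  structure(list(percent_decrease = pd, cutoff = cut,
                 substantial = pd > cut, m = m,
                 lcv_smaller = s, lcv_larger = l),
            class = "mm_lcv_test")
}

#' @export
print.mm_lcv_test <- function(x, ...) {
  cat(sprintf("LCV ratio test: percent decrease %.2f%% vs cutoff %.2f%% -> %s\n",
              x$percent_decrease, x$cutoff,
              if (x$substantial) "substantial" else "insubstantial"))
  invisible(x)
}

#' Select the number of cross-validation folds
#'
#' Runs the benchmark analysis (constrained expansion of the composite
#' model with \code{p = q = 1} under the chosen covariance structure) for
#' successive fold counts and returns the first local maximum of the LCV
#' score over the candidate list (multiples of 5 by default).  If the
#' scores are monotone over the candidates, the best-scoring candidate is
#' returned with a warning.
#'
#' @param data mediation data frame.
#' @param seed integer seed; per-\code{k} fold assignments are derived from
#'   it deterministically.
#' @param k_candidates ascending candidate fold counts (capped at the
#'   number of subjects).
#' @param rho_free covariance structure of the benchmark (CSH by default).
#' @param cfg a \code{\link{mm_search_config}}.
#' @return list with \code{k}, the cached \code{folds} assignment for the
#'   chosen \code{k}, and the per-candidate \code{scores}.
#' @export
select_folds <- function(data, seed = 1L, k_candidates = seq(5L, 30L, 5L),
                         rho_free = TRUE, cfg = mm_search_config()) {
  n <- nrow(data)
  k_candidates <- k_candidates[k_candidates <= n]
  if (!length(k_candidates)) stop("no usable fold-count candidates")
  if (is.unsorted(k_candidates)) stop("k_candidates must be ascending")
  scores <- rep(NA_real_, length(k_candidates))
  fold_cache <- vector("list", length(k_candidates))
  score_at <- function(i) {
    if (is.na(scores[i])) {
      f <- assign_folds(n, k_candidates[i],
                        derive_seed(seed, paste0("folds", k_candidates[i])))
      fold_cache[[i]] <<- f
      ce <- constrained_expansion(data, p = 1, q = 1, folds = f,
                                  cfg = cfg, rho_free = rho_free)
      scores[i] <<- ce$score
    }
    scores[i]
  }
  chosen <- NA_integer_
  for (i in seq_along(k_candidates)) {
    score_at(i)
    if (i >= 2 && is.na(chosen)) {
      left_ok <- i == 2 || scores[i - 1] > scores[i - 2]
      if (left_ok && scores[i - 1] > scores[i]) {
        chosen <- i - 1L
        break
      }
    }
  }
  if (is.na(chosen)) {
    chosen <- which.max(scores)
    warning("no first local maximum within the candidate fold counts; ",
            "returning the best-scoring candidate k = ", k_candidates[chosen])
  }
  list(k = k_candidates[chosen], folds = fold_cache[[chosen]],
       scores = stats::setNames(scores, k_candidates),
       candidates = k_candidates)
}
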