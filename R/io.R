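# Reading mediation data and serializing analysis reports.

#' Read per-subject mediation data from a CSV file
#'
#' Maps the named columns to the canonical \code{x}, \code{m}, \code{y}
#' layout, drops rows with missing required values (with a message),
#' optionally shifts variables by user-supplied constants to make them
#' positive, and validates positivity.
#'
#' @param path CSV file path.
#' @param x,m,y column names of predictor, mediator, outcome.
#' @param covariates,moderator optional extra column names to carry over.
#' @param shift named numeric vector of additive shifts, e.g.
#'   \code{c(y = 10)}; applied (and logged) before validation.
#' @return validated data frame with columns \code{subject_id}, \code{x},
#'   \code{m}, \code{y}, plus any covariate/moderator columns.
#' @export
read_mediation_data <- function(path, x = "x", m = "m", y = "y",
                                covariates = NULL, moderator = NULL,
                                shift = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(x, m, y, covariates, moderator)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  out <- data.frame(x = as.numeric(raw[[x]]), m = as.numeric(raw[[m]]),
                    y = as.numeric(raw[[y]]))
  for (z in c(covariates, moderator)) out[[z]] <- raw[[z]]
  keep <- stats::complete.cases(out[, c("x", "m", "y")])
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with missing x/m/y values")
    out <- out[keep, , drop = FALSE]
  }
  if (!nrow(out)) stop("no complete rows left after dropping missing values")
  for (v in names(shift)) {
    out[[v]] <- out[[v]] + shift[[v]]
    message("shifted column '", v, "' by ", shift[[v]])
  }
  check_mediation_data(out)
  out <- cbind(subject_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

spec_as_list <- function(spec) {
  list(p = spec$p, q = spec$q, m_power = spec$m_power,
       pdp = spec_pdp(spec),
       x_to_m = spec$xm, x_to_y = spec$xy, m_term = spec$bm,
       covariates_M = spec$cov_M, covariates_Y = spec$cov_Y,
       variance_M = spec$var_M, variance_Y = spec$var_Y,
       rho_free = spec$rho_free, moderator = spec$moderator,
       levels = spec$levels)
}

#' Build a serializable report from a fitted analysis
#'
#' @param object a \code{"monomed"} fit.
#' @return a plain list mirroring the analysis: data summary, fold
#'   metadata, per-model specs and LCV scores, every ratio test, effect
#'   tables, bootstrap CI bounds and normalized width, diagnostics, seeds.
#' @export
as_report <- function(object) {
  stopifnot(inherits(object, "monomed"))
  tests <- lapply(object$tests, function(t)
    list(percent_decrease = t$percent_decrease, cutoff = t$cutoff,
         substantial = t$substantial, m = t$m))
  models <- lapply(object$models, function(mo)
    list(spec = spec_as_list(mo$spec), lcv = mo$score))
  rep_list <- list(
    package = "monomed",
    version = as.character(utils::packageVersion("monomed")),
    seed = object$seed,
    data = list(n = object$n, columns = as.list(object$columns)),
    folds = list(k = object$k, seed = object$folds$seed,
                 sizes = as.integer(table(object$folds$assignment))),
    models = models,
    tests = tests,
    final = list(spec = spec_as_list(object$spec), lcv = object$score,
                 coefficients = as.list(coef(object$fit)),
                 rho = object$fit$rho, loglik = object$fit$loglik))
  if (!is.null(object$diagnostics))
    rep_list$diagnostics <- list(
      shapiro_p = object$diagnostics$shapiro_p,
      n_outliers = object$diagnostics$n_outliers)
  if (!is.null(object$effects))
    rep_list$effects <- object$effects
  if (!is.null(object$ci))
    rep_list$bootstrap_ci <- list(
      x = object$ci$x, L = object$ci$L, U = object$ci$U,
      W = object$ci$W, ab_bounds = object$ci$ab_bounds,
      ab_hat = object$ci$ab_hat, B = object$ci$B,
      bias_corrected = object$ci$bias_corrected, seed = object$ci$seed)
  if (!is.null(object$moderated)) {
    md <- object$moderated
    rep_list$moderated <- list(
      spec = spec_as_list(md$spec), lcv = md$score,
      versus_unmoderated = if (!is.null(md$versus_unmoderated))
        list(percent_decrease = md$versus_unmoderated$percent_decrease,
             cutoff = md$versus_unmoderated$cutoff,
             substantial = md$versus_unmoderated$substantial),
      component_tests = lapply(md$component_tests, function(ct)
        list(lcv = ct$score,
             percent_decrease = ct$test$percent_decrease,
             cutoff = ct$test$cutoff,
             substantial = ct$test$substantial)))
  }
  rep_list
}

#' Write an analysis report to JSON (and optionally Markdown)
#'
#' @param object a \code{"monomed"} fit.
#' @param path output JSON path.
#' @param md_path optional Markdown summary path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(object, path, md_path = NULL) {
  rep_list <- as_report(object)
  jsonlite::write_json(rep_list, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(md_path)) {
    con <- file(md_path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("# Monotonic mediation analysis report")
    w("")
    w("* subjects: %d, folds: %d, seed: %s", object$n, object$k,
      format(object$seed))
    w("* selected powers: p = %g, q = %g", object$spec$p, object$spec$q)
    w("* LCV score of the selected model: %s",
      format(object$score, digits = 6))
    if (length(object$tests)) {
      w("")
      w("## LCV ratio tests")
      w("")
      w("| test | %% decrease | cutoff | verdict |")
      w("|---|---|---|---|")
      for (nm in names(object$tests)) {
        t <- object$tests[[nm]]
        w("| %s | %.2f | %.2f | %s |", nm, t$percent_decrease, t$cutoff,
          if (t$substantial) "substantial" else "insubstantial")
      }
    }
    if (!is.null(object$effects)) {
      w("")
      w("## Instantaneous effects")
      w("")
      w("| x | total | direct | indirect | relative indirect |")
      w("|---|---|---|---|---|")
      for (i in seq_len(nrow(object$effects)))
        w("| %g | %.4g | %.4g | %.4g | %.3g |", object$effects$x[i],
          object$effects$te[i], object$effects$nde[i],
          object$effects$nie[i], object$effects$relative_nie[i])
    }
    if (!is.null(object$ci)) {
      w("")
      w("## Bootstrap 95%% CI for the instantaneous NIE")
      w("")
      w("| x | L(x) | U(x) | W |")
      w("|---|---|---|---|")
      for (i in seq_along(object$ci$x))
        w("| %g | %.4g | %.4g | %.2f |", object$ci$x[i], object$ci$L[i],
          object$ci$U[i], object$ci$W)
    }
  }
  invisible(path)
}
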