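# Data generators: the 101-observation benchmark simulation design and a
# generic monotonic-mediation generator (possibly moderated).

#' Simulate monotonic mediation data
#'
#' Generates per-subject \code{(x, m, y)} triples from
#' \deqn{M^q = i_M + a X^{q'} + \sigma_M U_M, \qquad
#'       Y^p = i_Y + c' X^{p'} + b M^q + \sigma_Y U_Y,}
#' with \code{(U_M, U_Y)} standard bivariate normal with correlation
#' \code{rho}, inverting the outcome/mediator transforms exactly.  Draws
#' whose transformed values cannot be inverted on the positive domain
#' (non-positive \code{M^q} with \code{q != 0}, or \code{Y^p} with
#' \code{p != 0}) are redrawn; a rejection rate above
#' \code{max_reject} is an error advising rescaling.
#'
#' The defaults reproduce the benchmark design used throughout the
#' package's evaluation: 101 subjects, X equally spaced on [1, 10]
#' (0.09 apart), \code{M = 1 + X + U_M},
#' \code{Y^{0.4} = (5 + X + M + U_Y) / 25} (so \code{Y = (Y^{0.4})^{2.5}}),
#' with true powers \code{p = 0.4, q = p' = q' = 1} and true constant
#' instantaneous natural indirect effect \code{a * b = 1/25 = 0.04}.  The
#' normalizer 25 is a fixed constant of the design, so the true
#' coefficients remain 1/25.
#'
#' @param n number of subjects.
#' @param seed integer seed (same seed, same data set).
#' @param x predictor values (default equally spaced over \code{x_range}).
#' @param x_range range for the default equally spaced predictor.
#' @param p,q,p_prime,q_prime true powers.
#' @param i_M,a,i_Y,c_prime,b true coefficients.
#' @param sigma_M,sigma_Y noise scales (0 allowed, suppressing noise).
#' @param rho correlation of the two error streams.
#' @param max_reject maximal tolerated rejection rate (default 0.2).
#' @return data frame with columns \code{subject_id}, \code{x}, \code{m},
#'   \code{y}.
#' @examples
#' d <- simulate_mediation(seed = 1)
#' range(diff(d$x))  # 0.09
#' @export
simulate_mediation <- function(n = 101L, seed = NULL, x = NULL,
                               x_range = c(1, 10),
                               p = 0.4, q = 1, p_prime = 1, q_prime = 1,
                               i_M = 1, a = 1, i_Y = 0.2, c_prime = 0.04,
                               b = 0.04, sigma_M = 1, sigma_Y = 0.04,
                               rho = 0, max_reject = 0.2) {
  if (is.null(x)) x <- seq(x_range[1], x_range[2], length.out = n)
  stopifnot(length(x) == n, all(x > 0), abs(rho) < 1)
  with_seed(seed, {
    xqp <- power_transform(x, q_prime)
    xpp <- power_transform(x, p_prime)
    inv_out <- function(v, pw) if (pw == 0) exp(v) else v^(1 / pw)
    m <- y <- rep(NA_real_, n)
    todo <- seq_len(n)
    rejected <- 0L
    for (round in seq_len(50L)) {
      if (!length(todo)) break
      uM <- stats::rnorm(length(todo))
      uY <- rho * uM + sqrt(1 - rho^2) * stats::rnorm(length(todo))
      Mq <- i_M + a * xqp[todo] + sigma_M * uM
      Yp <- i_Y + c_prime * xpp[todo] + b * Mq + sigma_Y * uY
      bad <- (q != 0 & Mq <= 0) | (p != 0 & Yp <= 0)
      ok <- todo[!bad]
      m[ok] <- inv_out(Mq[!bad], q)
      y[ok] <- inv_out(Yp[!bad], p)
      rejected <- rejected + sum(bad)
      todo <- todo[bad]
    }
    if (length(todo))
      stop("could not generate positive mediation data; rescale the design")
    if (rejected / (n + rejected) > max_reject)
      stop(sprintf(paste("rejection rate %.1f%% exceeds %.0f%%;",
                         "rescale the simulation design"),
                   100 * rejected / (n + rejected), 100 * max_reject))
    data.frame(subject_id = seq_len(n), x = x, m = m, y = y)
  })
}

#' Simulate moderated monotonic mediation data
#'
#' Generates one \code{\link{simulate_mediation}} data set per moderator
#' level and stacks them with a moderator column \code{z}.
#'
#' @param levels named list: one list of \code{simulate_mediation}
#'   arguments per moderator level (list names become the level values).
#' @param n_per_level subjects per level (overridable inside each level's
#'   argument list).
#' @param seed integer seed; per-level seeds are derived from it.
#' @return data frame with columns \code{subject_id}, \code{x}, \code{m},
#'   \code{y}, \code{z}.
#' @export
simulate_moderated_mediation <- function(levels, n_per_level = 101L,
                                         seed = 1L) {
  stopifnot(is.list(levels), !is.null(names(levels)))
  out <- list()
  for (lv in names(levels)) {
    args <- levels[[lv]]
    args$n <- args$n %||% n_per_level
    args$seed <- args$seed %||% derive_seed(seed, paste0("level", lv))
    d <- do.call(simulate_mediation, args)
    d$z <- lv
    out[[lv]] <- d
  }
  d <- do.call(rbind, out)
  d$subject_id <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}
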