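#' Indirect effect point estimate
#'
#' The product-of-coefficients estimate: the path from shared appraisal into
#' the shared-coping mediator times the mediator's path into the outcome.
#'
#' @param a,b path estimates.
#' @return `a * b`.
#' @export
#' @examples
#' indirect_point(4.78, 0.07)  # 0.3346
indirect_point <- function(a, b) a * b

#' Monte Carlo confidence interval for an indirect effect
#'
#' Draws `(a*, b*)` from a bivariate normal centered at the estimates with
#' the joint sampling covariance `V_ab`, and takes empirical percentiles of
#' the products `a* b*`. The delta-method standard error
#' `sqrt(b^2 V_aa + a^2 V_bb + 2 a b V_ab)` is reported alongside.
#'
#' @param a,b path estimates.
#' @param V_ab 2x2 symmetric positive semi-definite covariance of `(a, b)`.
#' @param reps number of Monte Carlo draws (>= 1000, default 20000).
#' @param seed integer seed (mandatory; the interval is deterministic given
#'   the seed).
#' @param conf_level confidence level, default 0.95.
#' @return an object of class `cfm_mediation` with `a_hat`, `b_hat`, `est`,
#'   `se`, `ci_lower`, `ci_upper`, `reps`, `seed`, `conf_level`.
#' @export
monte_carlo_ci <- function(a, b, V_ab, reps = 20000, seed, conf_level = 0.95) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (reps < 1000) stop("reps must be >= 1000")
  V_ab <- as.matrix(V_ab)
  if (!isTRUE(all.equal(V_ab, t(V_ab), tolerance = 1e-8))) {
    stop("V_ab must be symmetric")
  }
  ev <- eigen((V_ab + t(V_ab)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop("V_ab must be positive semi-definite")
  }
  draws <- with_seed(seed, {
    MASS::mvrnorm(reps, mu = c(a, b),
                  Sigma = (V_ab + t(V_ab)) / 2, tol = 1e-8)
  })
  prod <- draws[, 1] * draws[, 2]
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(prod, c(alpha, 1 - alpha)))
  se <- sqrt(b^2 * V_ab[1, 1] + a^2 * V_ab[2, 2] + 2 * a * b * V_ab[1, 2])
  structure(class = "cfm_mediation", list(
    a_hat = a, b_hat = b, est = indirect_point(a, b), se = se,
    ci_lower = ci[1], ci_upper = ci[2], reps = reps, seed = seed,
    conf_level = conf_level))
}

#' Mediation inference from a fitted model
#'
#' Extracts the `a` path (shared appraisal to shared coping) and the `b`
#' path (shared coping to the requested outcome) at the requested level,
#' together with their joint asymptotic covariance from the fitted
#' observed-information inverse, and delegates to [monte_carlo_ci()].
#'
#' @param fit a converged [cfm_fit()].
#' @param level `"within"` or `"between"`.
#' @param outcome outcome name as it appears in the model graph (e.g.
#'   `"qol_PLWH"`, `"rs_shared"`, `"adherent"`); defaults to the single
#'   outcome when the model has only one at that level.
#' @param reps,seed,conf_level passed to [monte_carlo_ci()].
#' @return a `cfm_mediation` object with `level` and `outcome` fields added.
#' @export
mediate <- function(fit, level = c("within", "between"), outcome = NULL,
                    reps = 20000, seed, conf_level = 0.95) {
  stopifnot(inherits(fit, "cfm_fit"))
  level <- match.arg(level)
  if (!fit$converged) {
    warning("mediation computed from a fit flagged as not converged")
  }
  tag <- if (level == "within") "w" else "b"
  a_lab <- paste0("a_", tag)
  pt <- fit$partable
  b_cands <- pt$label[pt$free & pt$level == level &
                        startsWith(pt$label, paste0("b_", tag, "."))]
  if (!(a_lab %in% pt$label) || length(b_cands) == 0) {
    stop("no mediation pathway exists at the ", level,
         " level of model '", fit$model$outcome, "'")
  }
  if (is.null(outcome)) {
    if (length(b_cands) > 1) {
      stop("multiple outcomes at this level; specify one of: ",
           paste(sub(paste0("^b_", tag, "\\."), "", b_cands), collapse = ", "))
    }
    b_lab <- b_cands
  } else {
    b_lab <- paste0("b_", tag, ".", outcome)
    if (!(b_lab %in% b_cands)) {
      stop("no path from the mediator to outcome '", outcome,
           "' at the ", level, " level")
    }
  }
  if (is.null(fit$vcov)) stop("fit has no parameter covariance (se = FALSE?)")
  a <- fit$theta[[a_lab]]
  b <- fit$theta[[b_lab]]
  V <- fit$vcov[c(a_lab, b_lab), c(a_lab, b_lab)]
  out <- monte_carlo_ci(a, b, V, reps = reps, seed = seed,
                        conf_level = conf_level)
  out$level <- level
  out$outcome <- sub(paste0("^b_", tag, "\\."), "", b_lab)
  out
}

#' @export
print.cfm_mediation <- function(x, ...) {
  cat(sprintf(
    "indirect effect%s%s: est = %.3f (a = %.3f, b = %.3f), SE = %.3f, %d%% MC CI [%.3f, %.3f]\n",
    if (!is.null(x$level)) paste0(" (", x$level) else "",
    if (!is.null(x$outcome)) paste0(" -> ", x$outcome, ")") else
      if (!is.null(x$level)) ")" else "",
    x$est, x$a_hat, x$b_hat, x$se, round(100 * x$conf_level),
    x$ci_lower, x$ci_upper))
  invisible(x)
}
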