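#' @export
print.msm_trend <- function(x, ...) {
  cat("Three-state hidden-Markov dementia trend model\n")
  cat("  subjects:", x$n_subj, " intervals:", x$n_obs,
      " (deaths:", unname(x$counts["death"]), ")\n")
  cat("  calendar form:", x$spec$calendar, " age form:", x$spec$age,
      " emission:", x$spec$emission, "\n")
  cat("  log-likelihood:", format(x$logLik, digits = 8),
      " convergence code:", x$convergence, "\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.msm_trend <- function(object, ...) object$theta

#' @export
vcov.msm_trend <- function(object, ...) object$vcov

#' @export
logLik.msm_trend <- function(object, ...) {
  structure(object$logLik, df = length(object$theta), class = "logLik")
}

#' @export
confint.msm_trend <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$vcov)) stop("fit has no covariance (hessian = FALSE)")
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$theta - z * se, object$theta + z * se)
  colnames(ci) <- paste(100 * c((1 - level) / 2, 1 - (1 - level) / 2), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.msm_trend <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, length(object$theta)) else
    sqrt(pmax(diag(object$vcov), 0))
  tab <- data.frame(estimate = object$theta, se = se,
                    z = object$theta / se,
                    p = 2 * stats::pnorm(-abs(object$theta / se)))
  out <- list(coefficients = tab, logLik = object$logLik,
              n_subj = object$n_subj, spec = object$spec,
              convergence = object$convergence)
  class(out) <- "summary.msm_trend"
  out
}

#' @export
print.summary.msm_trend <- function(x, ...) {
  cat("Three-state hidden-Markov dementia trend model\n")
  cat("subjects:", x$n_subj, " logLik:", format(x$logLik, digits = 8), "\n\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' Predicted onset intensity
#'
#' @param object an [fit_msm()] fit.
#' @param newdata data.frame with `age`, `female`, `year` (and `group` for
#'   grouped fits); default a small illustrative grid.
#' @param per rate scale per person-years (default 1000).
#' @param ... unused.
#' @return `newdata` with a `rate` column (dementia-onset intensity).
#' @export
predict.msm_trend <- function(object, newdata = NULL, per = 1000, ...) {
  if (is.null(newdata))
    newdata <- expand.grid(age = c(70, 80, 90), female = c(0, 1),
                           year = c(2002, 2008, 2016))
  if (!is.null(object$spec$group) && is.null(newdata$group))
    newdata$group <- object$group_levels[1]
  X <- design_q01(newdata, object$spec, object$group_levels)
  newdata$rate <- exp(drop(X %*% object$theta[object$par_index$q01])) * per
  newdata
}

#' @export
plot.msm_trend <- function(x, years = NULL, ref = 2002, ...) {
  if (is.null(years)) {
    years <- switch(x$spec$calendar,
                    rcs = seq(min(x$spec$cal_knots), max(x$spec$cal_knots), 0.25),
                    seq(x$spec$cal_ref, x$spec$cal_ref + 16, 0.25))
  }
  cv <- irr_curve(x, years, ref)
  graphics::plot(cv$year, cv$irr, type = "l", log = "y",
                 xlab = "calendar year", ylab = paste0("IRR vs ", ref), ...)
  graphics::lines(cv$year, cv$lo, lty = 2)
  graphics::lines(cv$year, cv$hi, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(cv)
}
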