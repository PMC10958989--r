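#' Fit the calendar-trend Cox model on pooled subcohorts
#'
#' Proportional-hazards model for incident dementia over the pooled 4-year
#' subcohorts, on the follow-up time scale, with terms for baseline age, age
#' squared, sex, an age-by-sex interaction, and calendar time as a restricted
#' cubic spline. The calendar covariate is updated continuously along
#' follow-up (baseline year + elapsed time, evaluated at the start of short
#' episodes), or held at baseline via `calendar = "baseline"`. Variance is
#' the cluster-robust sandwich on person id, so people contributing to
#' several overlapping subcohorts do not masquerade as independent.
#'
#' Estimation is by `survival::coxph` (Newton-Raphson partial likelihood);
#' this function owns the design (episode splitting, spline basis, centring)
#' and the downstream trend summaries ([hr_curve()], [ph_check()]).
#'
#' @param records subcohort records from [build_subcohorts()].
#' @param knots calendar-year knots of the restricted cubic spline; default
#'   `c(2002, 2006, 2010, 2016)` (internal knots 2006 and 2010).
#' @param ties tie handling, "breslow" (default) or "efron".
#' @param calendar "continuous" (default) or "baseline".
#' @param split episode length in years for the time-varying calendar
#'   covariate (default 0.5).
#' @return object of class `"cox_trend"`: the `coxph` fit plus the spline
#'   specification.
#' @export
fit_cox_trend <- function(records, knots = c(2002, 2006, 2010, 2016),
                          ties = c("breslow", "efron"),
                          calendar = c("continuous", "baseline"),
                          split = 0.5) {
  ties <- match.arg(ties)
  calendar <- match.arg(calendar)
  if (!sum(records$event == "dementia")) stop("no dementia events in records")
  d <- data.frame(id = records$id,
                  time = records$time,
                  status = as.integer(records$event == "dementia"),
                  age = records$age - 70,
                  female = records$female,
                  byear = records$baseline_year)
  if (calendar == "continuous") {
    cuts <- seq(split, max(d$time), by = split)
    ds <- survSplit(Surv(time, status) ~ ., data = d,
                              cut = cuts, episode = "ep")
    ds$cal <- ds$byear + ds$tstart
  } else {
    ds <- d
    ds$tstart <- 0
    ds$cal <- ds$byear
  }
  B <- rcs_basis(ds$cal, knots)
  colnames(B) <- paste0("cal", seq_len(ncol(B)))
  ds <- cbind(ds, as.data.frame(B))
  fml <- stats::as.formula(paste(
    "Surv(tstart, time, status) ~ age + I(age^2) + female + age:female +",
    paste(colnames(B), collapse = " + ")))
  if (calendar == "baseline")
    fml <- stats::as.formula(paste(
      "Surv(time, status) ~ age + I(age^2) + female + age:female +",
      paste(colnames(B), collapse = " + ")))
  fit <- coxph(fml, data = ds, ties = ties, cluster = id,
                         model = FALSE, x = FALSE, y = FALSE)
  out <- list(fit = fit, knots = knots, ties = ties, calendar = calendar,
              split = split, n_events = sum(d$status),
              spline_terms = colnames(B), data = ds)
  class(out) <- "cox_trend"
  out
}

#' @export
print.cox_trend <- function(x, ...) {
  cat("Cox calendar-trend model (", x$ties, " ties, calendar ", x$calendar,
      ")\n", sep = "")
  cat("RCS knots:", paste(x$knots, collapse = ", "), "  events:",
      x$n_events, "\n")
  print(coef(x$fit))
  invisible(x)
}

#' @export
coef.cox_trend <- function(object, ...) coef(object$fit)

#' @export
vcov.cox_trend <- function(object, robust = TRUE, ...) {
  V <- if (robust) object$fit$var else object$fit$naive.var
  dimnames(V) <- list(names(coef(object$fit)), names(coef(object$fit)))
  V
}

#' @export
logLik.cox_trend <- function(object, ...) {
  structure(object$fit$loglik[2], df = length(coef(object$fit)),
            class = "logLik")
}

#' Hazard-ratio trend curve
#'
#' HR of dementia incidence at each calendar year versus a reference year,
#' from the fitted calendar spline: `HR(y) = exp(s(y) - s(ref))`, with
#' delta-method 95% CIs using the cluster-robust covariance. Years outside
#' the boundary knots extrapolate linearly (the restricted basis is linear
#' there) with a warning.
#'
#' @param fit a [fit_cox_trend()] object.
#' @param years calendar years to evaluate.
#' @param ref_year reference year (default 2002).
#' @param level confidence level.
#' @return data.frame: year, hr, lo, hi.
#' @export
hr_curve <- function(fit, years, ref_year = 2002, level = 0.95) {
  stopifnot(inherits(fit, "cox_trend"))
  if (any(years < min(fit$knots) | years > max(fit$knots)))
    warning("years outside the knot span: linear extrapolation")
  C <- rcs_basis(years, fit$knots) -
    rcs_basis(rep(ref_year, length(years)), fit$knots)
  b <- coef(fit$fit)
  V <- vcov(fit)
  idx <- match(fit$spline_terms, names(b))
  est <- drop(C %*% b[idx])
  se <- sqrt(pmax(rowSums((C %*% V[idx, idx]) * C), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(year = years, hr = exp(est),
             lo = exp(est - z * se), hi = exp(est + z * se))
}

#' @export
plot.cox_trend <- function(x, years = NULL, ref_year = 2002, ...) {
  if (is.null(years)) years <- seq(min(x$knots), max(x$knots), by = 0.25)
  cv <- hr_curve(x, years, ref_year)
  graphics::plot(cv$year, cv$hr, type = "l", log = "y", xlab = "calendar year",
                 ylab = paste0("HR vs ", ref_year), ...)
  graphics::lines(cv$year, cv$lo, lty = 2)
  graphics::lines(cv$year, cv$hi, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(cv)
}

#' Annualise an incidence/hazard ratio
#'
#' Converts a ratio spanning several years into the constant annual relative
#' change (percent per year): `(irr^(1/(y1-y0)) - 1) * 100`. For example an
#' IRR of 1.25 across 2008-2016 corresponds to a 2.8% annual increase.
#'
#' @param irr the rate ratio.
#' @param y0,y1 the two calendar years spanned.
#' @return percent annual change.
#' @export
annualise_irr <- function(irr, y0, y1) {
  stopifnot(y1 > y0, irr > 0)
  (irr^(1 / (y1 - y0)) - 1) * 100
}

#' Proportional-hazards check for the calendar trend
#'
#' Augments the fitted model with a follow-up-time by calendar-year
#' interaction and reports the robust Wald test of the interaction term. A
#' small p-value signals that the calendar effect varies along follow-up,
#' i.e. non-proportional hazards.
#'
#' @param fit a [fit_cox_trend()] object.
#' @return list: statistic (chi-square), df, p_value, coefficient.
#' @export
ph_check <- function(fit) {
  stopifnot(inherits(fit, "cox_trend"))
  ds <- fit$data
  ds$tt_cal <- ds$tstart * (ds$cal - fit$knots[1])
  fml <- stats::as.formula(paste(
    "Surv(tstart, time, status) ~ age + I(age^2) + female + age:female +",
    paste(fit$spline_terms, collapse = " + "), "+ tt_cal"))
  if (fit$calendar == "baseline")
    stop("ph_check requires the continuous-calendar fit (episode-split data)")
  f2 <- coxph(fml, data = ds, ties = fit$ties, cluster = id)
  k <- match("tt_cal", names(coef(f2)))
  se <- sqrt(f2$var[k, k])
  stat <- (coef(f2)[k] / se)^2
  list(statistic = unname(stat), df = 1,
       p_value = unname(stats::pchisq(stat, 1, lower.tail = FALSE)),
       coefficient = unname(coef(f2)[k]))
}
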