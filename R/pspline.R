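## B-spline basis over a regular grid, knots spaced `dx`, degree `deg`
bspline_basis <- function(x, xmin, xmax, dx, deg = 3) {
  ## upper knots extend one interval past xmax so the last cell is covered
  knots <- seq(xmin - deg * dx, xmax + (deg + 1) * dx, by = dx)
  splines::splineDesign(knots, x, ord = deg + 1, outer.ok = TRUE)
}

diff_penalty <- function(k, order = 2) {
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

#' Two-dimensional P-spline mortality forecast
#'
#' Penalised Poisson smoothing of a deaths/exposures surface over age and
#' calendar year, per cause, with a tensor-product B-spline basis and
#' second-order difference penalties on each dimension. The year basis
#' extends beyond the data to `forecast_to`; cells there carry zero weight,
#' so the difference penalty propagates the fitted trend (linearly in the
#' penalty null space), which is what turns the smoother into a forecaster.
#' Smoothing parameters are selected on a BIC grid.
#'
#' @param mort data.frame with columns age, year, cause, deaths, exposure
#'   (as produced by [simulate_mortality_surface()]).
#' @param forecast_to last calendar year of the forecast (default 2040).
#' @param dx_age,dx_year knot spacing in years (defaults 5).
#' @param degree B-spline degree (default cubic).
#' @param penalty_order difference-penalty order (default 2).
#' @param lambda_grid candidate smoothing parameters per dimension; BIC
#'   selects a pair.
#' @param lambda optional fixed c(lambda_age, lambda_year), skipping
#'   selection.
#' @param max_iter,tol IRLS control.
#' @return object of class `"mort_forecast"`: per cause the coefficient
#'   vector, fitted log-rate matrix (age by year over data + forecast),
#'   chosen lambdas, deviance and effective dimension; plus the grids.
#' @export
fit_pspline_mortality <- function(mort, forecast_to = 2040,
                                  dx_age = 5, dx_year = 5, degree = 3,
                                  penalty_order = 2,
                                  lambda_grid = 10^seq(0, 4, by = 1),
                                  lambda = NULL,
                                  max_iter = 50, tol = 1e-8) {
  stopifnot(all(c("age", "year", "cause", "deaths", "exposure") %in% names(mort)))
  if (any(mort$exposure < 0)) stop("negative exposures")
  if (any(mort$deaths > 0 & mort$exposure == 0))
    stop("deaths with zero exposure")
  ages <- sort(unique(mort$age))
  data_years <- sort(unique(mort$year))
  years <- seq(min(data_years), max(max(data_years), forecast_to))
  Ba <- bspline_basis(ages, min(ages), max(ages), dx_age, degree)
  By <- bspline_basis(years, min(years), max(years), dx_year, degree)
  ka <- ncol(Ba); ky <- ncol(By)
  ## cells ordered age-fastest: row index = (iy - 1) * na + ia
  B <- kronecker(By, Ba)              # rows: year slow, age fast
  Pa <- kronecker(diag(ky), diff_penalty(ka, penalty_order))
  Py <- kronecker(diff_penalty(ky, penalty_order), diag(ka))

  na <- length(ages); ny <- length(years)
  cell <- function(a, y) (match(y, years) - 1L) * na + match(a, ages)

  fits <- list()
  for (cs in unique(mort$cause)) {
    m <- mort[mort$cause == cs, ]
    y <- numeric(na * ny); e <- rep(1e-12, na * ny); w <- numeric(na * ny)
    i <- cell(m$age, m$year)
    y[i] <- m$deaths; e[i] <- pmax(m$exposure, 1e-12); w[i] <- 1
    w[i][m$exposure == 0] <- 0
    irls <- function(la, ly) {
      P <- la * Pa + ly * Py
      eta <- log((y + 0.5) / e)
      beta <- NULL
      for (it in seq_len(max_iter)) {
        mu <- e * exp(eta)
        W <- w * mu
        z <- eta + (y - mu) / pmax(mu, 1e-12)
        A <- crossprod(B, W * B) + P
        b <- crossprod(B, W * z)
        beta_new <- tryCatch(solve(A, b), error = function(err)
          solve(A + diag(1e-8, ncol(A)), b))
        eta_new <- drop(B %*% beta_new)
        if (!is.null(beta) && max(abs(eta_new - eta)) < tol) {
          beta <- beta_new; eta <- eta_new; break
        }
        beta <- beta_new; eta <- eta_new
      }
      mu <- e * exp(eta)
      dev_terms <- ifelse(y > 0, y * log(y / mu) - (y - mu), mu)
      dev <- 2 * sum(w * dev_terms)
      ed <- sum(diag(solve(crossprod(B, (w * e * exp(eta)) * B) + P,
                           crossprod(B, (w * e * exp(eta)) * B))))
      list(beta = beta, eta = eta, dev = dev, ed = ed)
    }
    if (is.null(lambda)) {
      best <- NULL
      n_data <- sum(w > 0)
      for (la in lambda_grid) for (ly in lambda_grid) {
        f <- irls(la, ly)
        bic <- f$dev + log(n_data) * f$ed
        if (is.null(best) || bic < best$bic)
          best <- c(f, list(bic = bic, lambda = c(age = la, year = ly)))
      }
      f <- best
    } else {
      f <- irls(lambda[1], lambda[2])
      f$lambda <- c(age = lambda[1], year = lambda[2])
    }
    log_rate <- matrix(f$eta, na, ny, dimnames = list(ages, years))
    fits[[cs]] <- list(beta = f$beta, log_rate = log_rate,
                       lambda = f$lambda, deviance = f$dev, ed = f$ed)
  }
  out <- list(fits = fits, ages = ages, years = years,
              data_years = data_years, degree = degree,
              penalty_order = penalty_order)
  class(out) <- "mort_forecast"
  out
}

#' @export
print.mort_forecast <- function(x, ...) {
  cat("Two-dimensional P-spline mortality forecast\n")
  cat("  ages", min(x$ages), "-", max(x$ages), "; data years",
      min(x$data_years), "-", max(x$data_years), "; forecast to",
      max(x$years), "\n")
  for (cs in names(x$fits))
    cat(sprintf("  %s: lambda = (%g, %g), deviance %.1f, ED %.1f\n", cs,
                x$fits[[cs]]$lambda[1], x$fits[[cs]]$lambda[2],
                x$fits[[cs]]$deviance, x$fits[[cs]]$ed))
  invisible(x)
}

#' Mortality rates from a forecast object
#'
#' @param object a `"mort_forecast"` (or the output of
#'   [forecast_mortality()]).
#' @param cause cause label.
#' @return matrix of rates (age by year).
#' @export
mortality_rates <- function(object, cause) {
  exp(object$fits[[cause]]$log_rate)
}

#' Alternative mortality-trend forecasts
#'
#' The two sensitivity-analysis variants around the P-spline forecaster:
#' `"constant"` carries the last data year's (smoothed, age-profile) rates
#' unchanged to the horizon; `"loglinear"` fits, per cause, a Poisson
#' regression with an age factor and a log-linear calendar slope and
#' extrapolates it. `"pspline"` dispatches to [fit_pspline_mortality()].
#'
#' @param mort deaths/exposures data.frame (age, year, cause, deaths,
#'   exposure).
#' @param method "pspline", "constant" or "loglinear".
#' @param forecast_to horizon year.
#' @param ... passed to [fit_pspline_mortality()].
#' @return object of class `"mort_forecast"`.
#' @export
forecast_mortality <- function(mort, method = c("pspline", "constant",
                                                "loglinear"),
                               forecast_to = 2040, ...) {
  method <- match.arg(method)
  if (method == "pspline")
    return(fit_pspline_mortality(mort, forecast_to = forecast_to, ...))
  ages <- sort(unique(mort$age))
  data_years <- sort(unique(mort$year))
  years <- seq(min(data_years), max(max(data_years), forecast_to))
  fits <- list()
  for (cs in unique(mort$cause)) {
    m <- mort[mort$cause == cs, ]
    if (method == "constant") {
      last <- max(data_years)
      ml <- m[m$year == last, ]
      r_obs <- log(pmax(ml$deaths, 0.5) / pmax(ml$exposure, 1e-12))
      r <- r_obs[match(ages, ml$age)]
      log_rate <- matrix(r, length(ages), length(years),
                         dimnames = list(ages, years))
      ## before the last data year, keep the observed rates
      for (yy in data_years) {
        my <- m[m$year == yy, ]
        log_rate[, as.character(yy)] <-
          log(pmax(my$deaths, 0.5) / pmax(my$exposure, 1e-12))[match(ages, my$age)]
      }
    } else {
      f <- stats::glm(deaths ~ factor(age) + I(year - min(year)),
                      offset = log(pmax(exposure, 1e-12)),
                      family = stats::poisson(), data = m)
      nd <- expand.grid(age = ages, year = years)
      nd$exposure <- 1
      eta <- stats::predict(f, newdata = nd)
      log_rate <- matrix(eta, length(ages), length(years),
                         dimnames = list(ages, years))
    }
    fits[[cs]] <- list(beta = NULL, log_rate = log_rate,
                       lambda = NULL, deviance = NA_real_, ed = NA_real_)
  }
  out <- list(fits = fits, ages = ages, years = years,
              data_years = data_years, method = method)
  class(out) <- "mort_forecast"
  out
}
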