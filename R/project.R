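#' The ten health states of the burden-projection model
#'
#' Eight alive states are the combinations of cardiovascular disease (CVD),
#' cognitive impairment (CI) and functional impairment (FI); the two
#' absorbing death states split by cause (CVD vs non-CVD), which is how
#' competing risk from non-CVD causes is accounted for. Dementia is defined
#' as the alive states with both cognitive and functional impairment.
#'
#' @return data.frame: state index, cvd, ci, fi (NA for death states),
#'   label.
#' @export
health_states <- function() {
  g <- expand.grid(fi = 0:1, ci = 0:1, cvd = 0:1)
  g <- g[, c("cvd", "ci", "fi")]
  g$state <- 1 + g$cvd * 4 + g$ci * 2 + g$fi
  g <- g[order(g$state), ]
  alive <- data.frame(state = g$state, cvd = g$cvd, ci = g$ci, fi = g$fi,
                      label = paste0("cvd", g$cvd, "_ci", g$ci, "_fi", g$fi))
  rbind(alive,
        data.frame(state = 9:10, cvd = NA, ci = NA, fi = NA,
                   label = c("death_cvd", "death_noncvd")))
}

#' @rdname health_states
#' @export
dementia_states <- function() {
  hs <- health_states()
  hs$state[!is.na(hs$ci) & hs$ci == 1 & hs$fi == 1]
}

#' Scenario specification for the burden projection
#'
#' @param incidence one of "upward" (multiplier 1.028, the estimated post-2008
#'   relative annual increase), "downward" (0.973, the previously estimated
#'   2.7% annual decrease), "constant" (1.0), or a numeric multiplier.
#' @param mortality mortality-forecast variant: "pspline", "constant",
#'   "loglinear".
#' @param from_year incidence multiplier compounds from this year (default
#'   2018).
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(incidence = c("constant", "upward", "downward"),
                          mortality = c("pspline", "constant", "loglinear"),
                          from_year = 2018) {
  mult <- if (is.numeric(incidence)) incidence else
    switch(match.arg(incidence), upward = 1.028, downward = 0.973,
           constant = 1.0)
  if (mult <= 0) stop("incidence multiplier must be positive")
  structure(list(multiplier = mult, mortality = match.arg(mortality),
                 from_year = from_year), class = "scenario_spec")
}

#' Baseline transition-rate inputs for the projection
#'
#' Synthetic age-sex-year transition intensities feeding
#' [build_transition_array()]: Gompertz-type onset rates for cognitive
#' impairment, functional impairment and CVD, state multipliers, and
#' relative mortality by state. The cognitive-impairment onset rate can
#' embed a calendar trend taken from a fitted multistate model
#' (`irr_fun`). These are fixtures shaped like national inputs, not
#' estimates; real tables drop in through the same interface.
#'
#' @param irr_fun optional function(year) giving the incidence rate ratio
#'   vs 2011 applied to the CI onset rate (e.g. built from [irr_curve()]).
#' @return list of rate functions used by [build_transition_array()].
#' @export
default_transition_rates <- function(irr_fun = NULL) {
  if (is.null(irr_fun)) irr_fun <- function(year) rep(1, length(year))
  list(
    ## onset intensities per year at (age, female, year)
    h_ci = function(age, female, year)
      0.004 * exp(0.105 * (age - 75)) * (1 - 0.1 * female) * irr_fun(year),
    h_fi = function(age, female, year, ci)
      0.012 * exp(0.085 * (age - 75)) * (1 + 1.5 * ci),
    h_cvd = function(age, female, year)
      0.008 * exp(0.055 * (age - 75)) * (1 - 0.3 * female),
    ## relative mortality by state attributes (applies to both causes)
    rel_mort = function(cvd, ci, fi)
      (1 + 1.0 * cvd) * (1 + 0.6 * ci) * (1 + 0.8 * fi),
    ## share of the CVD-cause death rate felt by non-CVD states
    cvd_death_discount = 0.35)
}

#' Build the age-sex-year array of ten-state transition matrices
#'
#' One-year transition probability matrices for every age, sex and year.
#' Within a cycle, death competes first (cause-specific rates from the
#' mortality forecast, scaled by the state's relative mortality); conditional
#' on survival each absent attribute (CVD, CI, FI) is gained independently
#' with probability `1 - exp(-h)`; impairments and CVD never revert
#' (structural zeros). Under an incidence scenario, transitions into the two
#' dementia states are scaled on the rate scale,
#' `p -> 1 - exp(-m^(year - from_year) * (-log(1 - p)))` for years beyond
#' `from_year`, and the freed/extra mass is absorbed into the residual
#' staying probability; a negative residual is an error.
#'
#' @param mortality a `"mort_forecast"` covering the projection years with
#'   causes "cvd" and "noncvd".
#' @param scenario a [scenario_spec()].
#' @param rates rate functions from [default_transition_rates()].
#' @param ages,years projection grids (defaults 35:100, 2011:2040).
#' @return array `[10, 10, n_age, 2, n_year]` of row-stochastic matrices
#'   (dims: from-state, to-state, age, sex, year).
#' @export
build_transition_array <- function(mortality, scenario = scenario_spec(),
                                   rates = default_transition_rates(),
                                   ages = 35:100, years = 2011:2040) {
  hs <- health_states()
  alive <- hs[!is.na(hs$cvd), ]
  n_age <- length(ages); n_year <- length(years)
  A <- array(0, dim = c(10, 10, n_age, 2, n_year))
  mr_cvd <- mortality_rates(mortality, "cvd")
  mr_non <- mortality_rates(mortality, "noncvd")
  ag <- as.character(pmin(ages, max(as.integer(rownames(mr_cvd)))))
  yr <- as.character(pmin(pmax(years, min(as.integer(colnames(mr_cvd)))),
                          max(as.integer(colnames(mr_cvd)))))
  dem <- dementia_states()
  for (iy in seq_len(n_year)) for (sx in 1:2) for (ia in seq_len(n_age)) {
    age <- ages[ia]; female <- sx - 1; year <- years[iy]
    m_cvd0 <- mr_cvd[ag[ia], yr[iy]]
    m_non0 <- mr_non[ag[ia], yr[iy]]
    P <- matrix(0, 10, 10)
    P[9, 9] <- 1; P[10, 10] <- 1
    for (s in alive$state) {
      cvd <- alive$cvd[s]; ci <- alive$ci[s]; fi <- alive$fi[s]
      rel <- rates$rel_mort(cvd, ci, fi)
      h_dc <- m_cvd0 * rel * if (cvd == 1) 1 else rates$cvd_death_discount
      h_dn <- m_non0 * rel
      h_tot <- h_dc + h_dn
      p_die <- 1 - exp(-h_tot)
      p_dc <- if (h_tot > 0) p_die * h_dc / h_tot else 0
      p_dn <- p_die - p_dc
      pi_ci <- if (ci == 0) 1 - exp(-rates$h_ci(age, female, year)) else 0
      pi_fi <- if (fi == 0) 1 - exp(-rates$h_fi(age, female, year, ci)) else 0
      pi_cv <- if (cvd == 0) 1 - exp(-rates$h_cvd(age, female, year)) else 0
      for (gc in unique(c(0, 1 - cvd))) for (gi in unique(c(0, 1 - ci)))
        for (gf in unique(c(0, 1 - fi))) {
          s2 <- 1 + (cvd | gc) * 4 + (ci | gi) * 2 + (fi | gf)
          pr <- (if (cvd == 0) (if (gc) pi_cv else 1 - pi_cv) else 1) *
                (if (ci == 0) (if (gi) pi_ci else 1 - pi_ci) else 1) *
                (if (fi == 0) (if (gf) pi_fi else 1 - pi_fi) else 1)
          P[s, s2] <- P[s, s2] + (1 - p_die) * pr
        }
      P[s, 9] <- p_dc; P[s, 10] <- p_dn
    }
    ## incidence scenario: scale entries into dementia states on the rate scale
    if (year > scenario$from_year && scenario$multiplier != 1) {
      m <- scenario$multiplier^(year - scenario$from_year)
      for (s in setdiff(alive$state, dem)) {
        for (s2 in dem) {
          p <- P[s, s2]
          if (p > 0) {
            p_new <- 1 - exp(-m * (-log(1 - p)))
            P[s, s] <- P[s, s] + (p - p_new)
            P[s, s2] <- p_new
          }
        }
        if (P[s, s] < 0)
          stop("scenario multiplier too large: residual staying probability negative")
      }
    }
    A[, , ia, sx, iy] <- P
  }
  dimnames(A) <- list(hs$label, hs$label, ages, c("men", "women"), years)
  A
}

#' Synthetic initial state grid
#'
#' Age-sex-state occupancy counts at the projection start, shaped like a
#' national age pyramid with age-increasing prevalence of CVD, cognitive and
#' functional impairment (attributes assigned independently). A synthetic
#' fixture: real census/prevalence tables with the same layout drop in.
#'
#' @param ages age grid (default 35:100).
#' @param base_count population count at age 35 per sex.
#' @param decline exponential decline of the pyramid per year of age.
#' @return array `[n_age, 2, 10]` of counts (age, sex, state).
#' @export
initial_state_grid <- function(ages = 35:100, base_count = 350000,
                               decline = 0.025) {
  hs <- health_states()
  alive <- hs[!is.na(hs$cvd), ]
  n_age <- length(ages)
  G <- array(0, dim = c(n_age, 2, 10),
             dimnames = list(ages, c("men", "women"), hs$label))
  for (sx in 1:2) {
    female <- sx - 1
    pop <- base_count * exp(-decline * (ages - 35) * (1 - 0.15 * female))
    p_ci <- pmin(0.0015 * exp(0.105 * pmax(ages - 50, 0)), 0.8)
    p_fi <- pmin(0.004 * exp(0.085 * pmax(ages - 50, 0)), 0.8)
    p_cvd <- pmin(0.01 * exp(0.05 * pmax(ages - 40, 0)), 0.6)
    for (s in alive$state) {
      pr <- (if (alive$cvd[s]) p_cvd else 1 - p_cvd) *
            (if (alive$ci[s]) p_ci else 1 - p_ci) *
            (if (alive$fi[s]) p_fi else 1 - p_fi)
      G[, sx, s] <- pop * pr
    }
  }
  G
}

#' Run the ten-state Markov cohort projection
#'
#' Annual cycles from the initial year: apply the year's transition matrices,
#' advance everyone one year of age (the top age is an open band that
#' accumulates), and inject new entrants at the youngest age into the
#' fully-healthy state.
#'
#' @param init initial occupancy array `[n_age, 2, 10]` (see
#'   [initial_state_grid()]).
#' @param trans transition array from [build_transition_array()].
#' @param entrants entrants per year per sex at the youngest age (scalar or
#'   `[n_year, 2]` matrix).
#' @param years projection years (must match `dim(trans)[5] + 1` grid; the
#'   first year is the initial occupancy).
#' @return object of class `"state_grid"`: array `[n_age, 2, 10, n_year]`
#'   plus the year grid.
#' @export
run_projection <- function(init, trans, entrants = 350000,
                           years = NULL) {
  n_age <- dim(init)[1]
  n_year <- dim(trans)[5] + 1L
  if (is.null(years)) years <- as.integer(dimnames(trans)[[5]][1]) + 0:(n_year - 1L)
  if (dim(trans)[3] != n_age) stop("age dimension mismatch")
  if (length(entrants) == 1L) entrants <- matrix(entrants, n_year, 2)
  G <- array(0, dim = c(n_age, 2, 10, n_year),
             dimnames = c(dimnames(init)[1:2],
                          list(dimnames(trans)[[1]], years)))
  G[, , , 1] <- init
  for (t in seq_len(n_year - 1L)) {
    cur <- G[, , , t]
    nxt <- array(0, dim = c(n_age, 2, 10))
    for (sx in 1:2) {
      moved <- matrix(0, n_age, 10)
      for (ia in seq_len(n_age))
        moved[ia, ] <- cur[ia, sx, ] %*% trans[, , ia, sx, t]
      ## age advance; open top band accumulates
      nxt[2:n_age, sx, ] <- moved[1:(n_age - 1L), ]
      nxt[n_age, sx, ] <- nxt[n_age, sx, ] + moved[n_age, ]
      nxt[1, sx, 1] <- entrants[t + 1L, sx]
    }
    G[, , , t + 1L] <- nxt
  }
  structure(list(grid = G, years = years), class = "state_grid")
}

#' @export
print.state_grid <- function(x, ...) {
  dc <- dementia_counts(x)
  cat("Ten-state projection,", min(x$years), "-", max(x$years), "\n")
  cat("Dementia cases (millions):",
      paste(sprintf("%d: %.2f", x$years[c(1, length(x$years))],
                    dc[c(1, length(dc))] / 1e6), collapse = "  "), "\n")
  invisible(x)
}

#' Dementia prevalence counts per projection year
#'
#' Occupancy of the two dementia states (cognitive plus functional
#' impairment, with and without CVD) summed over ages and sexes.
#'
#' @param proj a `"state_grid"` from [run_projection()].
#' @return named numeric vector of counts per year.
#' @export
dementia_counts <- function(proj) {
  ds <- dementia_states()
  out <- apply(proj$grid[, , ds, , drop = FALSE], 4, sum)
  stats::setNames(out, proj$years)
}

#' Compare projection scenarios
#'
#' Per-year dementia counts for each scenario, pairwise ratios against the
#' first scenario, and (when parameter draws are supplied) percentile
#' uncertainty intervals.
#'
#' @param projections named list of `"state_grid"` objects on a common year
#'   grid.
#' @param draws optional named list (same names) of matrices
#'   `[n_draw, n_year]` of dementia counts from Monte-Carlo parameter draws.
#' @param level interval level (default 0.95).
#' @return data.frame: year, scenario, cases, ratio_vs_first, and lo/hi when
#'   draws are given.
#' @export
scenario_report <- function(projections, draws = NULL, level = 0.95) {
  if (length(projections) < 2L) stop("need at least two scenarios")
  yrs <- projections[[1]]$years
  for (p in projections)
    if (!identical(p$years, yrs)) stop("mismatched year grids")
  cc <- lapply(projections, dementia_counts)
  ref <- cc[[1]]
  out <- do.call(rbind, lapply(names(cc), function(nm) {
    d <- data.frame(year = yrs, scenario = nm, cases = unname(cc[[nm]]),
                    ratio_vs_first = unname(cc[[nm]] / ref))
    if (!is.null(draws) && nm %in% names(draws)) {
      a <- (1 - level) / 2
      q <- apply(draws[[nm]], 2, stats::quantile, probs = c(a, 1 - a))
      d$lo <- q[1, ]; d$hi <- q[2, ]
    }
    d
  }))
  rownames(out) <- NULL
  out
}

#' Project dementia burden under an incidence scenario with uncertainty
#'
#' Convenience wrapper: builds the transition array for a scenario, runs the
#' projection, and optionally repeats it with the annual incidence
#' multiplier drawn from a lognormal distribution (seeded) to produce
#' parametric uncertainty bands.
#'
#' @param mortality a `"mort_forecast"`.
#' @param scenario a [scenario_spec()].
#' @param init initial grid, default [initial_state_grid()].
#' @param rates rate functions, default [default_transition_rates()].
#' @param ages,years grids.
#' @param entrants entrants per year per sex.
#' @param n_draws Monte-Carlo draws of the multiplier (0 = none).
#' @param log_mult_se standard error of the log annual multiplier.
#' @param seed seed for the draws.
#' @return list: `projection` (a `"state_grid"`), `draws` (matrix of
#'   dementia counts per draw, or NULL).
#' @export
project_scenario <- function(mortality, scenario,
                             init = initial_state_grid(),
                             rates = default_transition_rates(),
                             ages = 35:100, years = 2011:2040,
                             entrants = 350000,
                             n_draws = 0, log_mult_se = 0.01, seed = 1L) {
  trans <- build_transition_array(mortality, scenario, rates, ages,
                                  years[-length(years)])
  proj <- run_projection(init, trans, entrants, years = years)
  draws <- NULL
  if (n_draws > 0) {
    set.seed(seed)
    ms <- exp(stats::rnorm(n_draws, log(scenario$multiplier), log_mult_se))
    draws <- t(vapply(ms, function(m) {
      sc <- scenario; sc$multiplier <- m
      tr <- build_transition_array(mortality, sc, rates, ages,
                                   years[-length(years)])
      dementia_counts(run_projection(init, tr, entrants, years = years))
    }, numeric(length(years))))
  }
  list(projection = proj, draws = draws)
}
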