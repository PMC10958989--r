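#' Configuration for the synthetic ageing-panel generator
#'
#' Builds the configuration object consumed by [simulate_panel()] and
#' [simulate_latent()]. The generator emulates a biennial ageing panel
#' (default nine waves, mid-2002 to mid-2018) with refreshment samples at
#' later waves, a latent no-dementia / dementia / death process whose
#' dementia-onset intensity follows a piecewise log-linear calendar trend
#' (decline to a break year, rise thereafter), state-dependent cognitive and
#' functional measurements, informant (proxy) assessments, self/carer-reported
#' doctor diagnoses, and exactly observed death dates between waves.
#'
#' Transition intensities (per person-year) are log-linear in age (Gompertz
#' form), sex and, for dementia onset, education and calendar time:
#' \deqn{q_{01}(t) = q_{01}^0 \exp\{a_{01}(age-75) + s_{01} female + e_{edu} + g(t)\}}
#' with \eqn{g(t)} the piecewise-linear calendar log-trend, and similarly for
#' the two mortality intensities. Post-onset mortality is
#' `rel_mort_dementia` times the no-dementia mortality at the same
#' covariates.
#'
#' @param n_core number of wave-1 entrants.
#' @param refresh_waves named integer vector: entrant counts by wave index
#'   (names are wave numbers). Default waves 3, 4, 6, 7 and 9, each 10% of
#'   `n_core`.
#' @param wave_dates calendar dates (decimal years) of the waves; default
#'   biennial mid-year 2002.5, 2004.5, ..., 2018.5.
#' @param age_entry list with `mean`, `sd`, `min`, `max` of the truncated
#'   normal entry-age distribution (ages 50+).
#' @param sex_ratio proportion women.
#' @param education_probs probabilities over education levels
#'   (low, middle, high).
#' @param trend_spec list with `ref_year`, `break_year`, `slope_pre`,
#'   `slope_post`: log-linear annual slopes of the dementia-onset intensity
#'   before and after the break. Default: 5% annual decline 2002-2008
#'   (`log(0.95)`), 2.8% annual increase after 2008 (`log(1.028)`). Either
#'   slope may be a named length-3 vector (low/middle/high) for
#'   education-specific trends.
#' @param base_intensities list `q01`, `q02`, `q12` per person-year at the
#'   reference covariates (age 75, male, middle education, ref_year). `q12`
#'   defaults to `rel_mort_dementia * q02`.
#' @param rel_mort_dementia multiplier of mortality after dementia onset.
#' @param age_coefs,sex_coefs per-transition log-intensity slopes for age
#'   (per year) and female sex.
#' @param edu_coefs dementia-onset log-intensity shifts by education level.
#' @param measurement_spec list controlling the observation layer; see
#'   Details. Missing entries take defaults.
#' @param cvd_death_prob probability a death is attributed to cardiovascular
#'   disease (used only to flag causes for projection fixtures).
#' @param seed integer seed; every simulation call is reproducible given the
#'   config.
#'
#' @details `measurement_spec` entries: `n_domains` (cognitive domains,
#' default 5), `domain_mean` (healthy domain-score means by education),
#' `domain_sd` (score SD), `dementia_shift` (additive score shift under
#' dementia, default -2.5), `adl_items`/`adl_p_healthy`/`adl_p_dementia`
#' (activities-of-daily-living dependency counts), `dx_sens`/`dx_spec`
#' (doctor-diagnosis report sensitivity/specificity), `dx_persist` (reports
#' persist to later waves), `proxy_p_healthy`/`proxy_p_dementia` (probability
#' a wave is answered by a proxy informant), and the proxy (IQCODE-like)
#' score means/SDs by latent state.
#'
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_core = 2000,
                          refresh_waves = NULL,
                          wave_dates = seq(2002.5, 2018.5, by = 2),
                          age_entry = list(mean = 65, sd = 10, min = 50, max = 95),
                          sex_ratio = 0.55,
                          education_probs = c(low = 0.45, middle = 0.30, high = 0.25),
                          trend_spec = list(ref_year = 2002, break_year = 2008,
                                            slope_pre = log(0.95),
                                            slope_post = log(1.028)),
                          base_intensities = list(q01 = 0.012, q02 = 0.022, q12 = NULL),
                          rel_mort_dementia = 5,
                          age_coefs = c(q01 = 0.11, q02 = 0.09, q12 = 0.09),
                          sex_coefs = c(q01 = 0.0, q02 = -0.35, q12 = -0.35),
                          edu_coefs = c(low = 0.25, middle = 0, high = -0.25),
                          measurement_spec = list(),
                          cvd_death_prob = 0.25,
                          seed = 1L) {
  if (is.null(refresh_waves)) {
    refresh_waves <- stats::setNames(rep(round(0.10 * n_core), 5L),
                                     c("3", "4", "6", "7", "9"))
    refresh_waves <- refresh_waves[as.integer(names(refresh_waves)) <= length(wave_dates)]
  }
  if (is.null(base_intensities$q12))
    base_intensities$q12 <- rel_mort_dementia * base_intensities$q02
  ms_default <- list(
    n_domains = 5L,
    domain_mean = c(low = -0.5, middle = 0, high = 0.5),
    domain_sd = 1,
    dementia_shift = -2.5,
    adl_items = 7L, adl_p_healthy = 0.04, adl_p_dementia = 0.65,
    dx_sens = 0.35, dx_spec = 0.998, dx_persist = TRUE,
    proxy_p_healthy = 0.01, proxy_p_dementia = 0.30,
    proxy_mean_healthy = 3.1, proxy_sd_healthy = 0.3,
    proxy_mean_dementia = 4.3, proxy_sd_dementia = 0.4)
  measurement_spec <- utils::modifyList(ms_default, measurement_spec)

  cfg <- list(n_core = n_core, refresh_waves = refresh_waves,
              wave_dates = wave_dates, age_entry = age_entry,
              sex_ratio = sex_ratio, education_probs = education_probs,
              trend_spec = trend_spec, base_intensities = base_intensities,
              rel_mort_dementia = rel_mort_dementia, age_coefs = age_coefs,
              sex_coefs = sex_coefs, edu_coefs = edu_coefs,
              measurement_spec = measurement_spec,
              cvd_death_prob = cvd_death_prob, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_core >= 0,
            all(diff(cfg$wave_dates) > 0),
            cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            all(cfg$education_probs >= 0),
            abs(sum(cfg$education_probs) - 1) < 1e-8,
            cfg$base_intensities$q01 >= 0,
            cfg$base_intensities$q02 >= 0,
            cfg$base_intensities$q12 >= 0)
  rw <- as.integer(names(cfg$refresh_waves))
  if (length(rw) && (any(rw < 1) || any(rw > length(cfg$wave_dates))))
    stop("refresh waves must be a subset of the declared waves")
  ms <- cfg$measurement_spec
  probs <- c(ms$adl_p_healthy, ms$adl_p_dementia, ms$dx_sens, ms$dx_spec,
             ms$proxy_p_healthy, ms$proxy_p_dementia)
  if (any(probs < 0 | probs > 1)) stop("measurement probabilities must lie in [0, 1]")
  invisible(cfg)
}

#' Piecewise log-linear calendar trend
#'
#' Cumulative log-effect of calendar time on the dementia-onset intensity:
#' `slope_pre` per year from `ref_year` to `break_year`, `slope_post` per
#' year thereafter; zero at `ref_year`.
#'
#' @param year calendar years (decimal).
#' @param trend_spec list as in [cohort_config()].
#' @return numeric vector of log intensity ratios vs `ref_year`.
#' @export
calendar_log_trend <- function(year, trend_spec) {
  trend_spec$slope_pre * (pmin(year, trend_spec$break_year) - trend_spec$ref_year) +
    trend_spec$slope_post * pmax(year - trend_spec$break_year, 0)
}

## education-specific variant: slopes may be named length-3 vectors
## (low/middle/high), enabling subgroup-divergent trends
edu_trend <- function(trend_spec, year, edu) {
  pick <- function(s) if (length(s) > 1L) unname(s[edu]) else s
  pick(trend_spec$slope_pre) *
    (pmin(year, trend_spec$break_year) - trend_spec$ref_year) +
    pick(trend_spec$slope_post) * pmax(year - trend_spec$break_year, 0)
}

edu_levels <- c("low", "middle", "high")

## log intensities at calendar time u for persons with given attributes.
## who: character among "q01","q02","q12"
log_intensity <- function(cfg, who, age, female, edu, year) {
  base <- log(cfg$base_intensities[[who]])
  out <- base + cfg$age_coefs[[who]] * (age - 75) + cfg$sex_coefs[[who]] * female
  if (who == "q01") {
    out <- out + cfg$edu_coefs[edu] + edu_trend(cfg$trend_spec, year, edu)
  }
  unname(out)
}

## Vectorised exact simulation of the time-inhomogeneous three-state process
## by thinning against a dominating constant rate per person. Intensities are
## non-decreasing in age; the calendar trend is piecewise monotone, so its
## maximum over [t, horizon] is attained at t, the break year, or the horizon.
simulate_latent_many <- function(cfg, entry) {
  n <- nrow(entry)
  horizon <- max(cfg$wave_dates)
  onset <- rep(NA_real_, n)
  death <- rep(NA_real_, n)
  if (n == 0L) {
    return(data.frame(id = integer(), entry_date = numeric(), entry_age = numeric(),
                      onset = numeric(), death = numeric(), cvd_death = logical()))
  }
  female <- entry$female
  edu <- entry$education
  trend_max <- function(t0, ed) {
    pmax(edu_trend(cfg$trend_spec, t0, ed),
         edu_trend(cfg$trend_spec, cfg$trend_spec$break_year, ed),
         edu_trend(cfg$trend_spec, horizon, ed))
  }
  age_at <- function(u) entry$entry_age + (u - entry$entry_date)

  ## phase 1: from state 0 (no dementia)
  t <- entry$entry_date
  active <- rep(TRUE, n)
  exited_to <- rep(0L, n)           # 0 none, 1 dementia, 2 death
  exit_time <- rep(NA_real_, n)
  while (any(active)) {
    i <- which(active)
    ## dominating rate over [t_i, horizon]: age at horizon, max of the
    ## piecewise-monotone calendar trend over the remaining window
    age_h <- entry$entry_age[i] + (horizon - entry$entry_date[i])
    M <- exp(log_intensity(cfg, "q01", age_h, female[i], edu[i], t[i]) -
               edu_trend(cfg$trend_spec, t[i], edu[i]) + trend_max(t[i], edu[i])) +
         exp(log_intensity(cfg, "q02", age_h, female[i], edu[i], t[i]))
    M <- pmax(M, 1e-12)
    t[i] <- t[i] + stats::rexp(length(i), rate = M)
    keep <- t[i] <= horizon
    active[i[!keep]] <- FALSE
    i <- i[keep]; M <- M[keep]
    if (!length(i)) break
    age_now <- entry$entry_age[i] + (t[i] - entry$entry_date[i])
    q01 <- exp(log_intensity(cfg, "q01", age_now, female[i], edu[i], t[i]))
    q02 <- exp(log_intensity(cfg, "q02", age_now, female[i], edu[i], t[i]))
    acc <- stats::runif(length(i)) < (q01 + q02) / M
    hit <- i[acc]
    if (length(hit)) {
      to_dem <- stats::runif(length(hit)) < (q01[acc] / (q01[acc] + q02[acc]))
      exited_to[hit] <- ifelse(to_dem, 1L, 2L)
      exit_time[hit] <- t[hit]
      active[hit] <- FALSE
    }
  }
  onset[exited_to == 1L] <- exit_time[exited_to == 1L]
  death[exited_to == 2L] <- exit_time[exited_to == 2L]

  ## phase 2: from dementia, death intensity q12
  i2 <- which(exited_to == 1L)
  if (length(i2)) {
    t <- onset[i2]
    active2 <- rep(TRUE, length(i2))
    while (any(active2)) {
      j <- which(active2)
      idx <- i2[j]
      age_h <- entry$entry_age[idx] + (horizon - entry$entry_date[idx])
      M <- pmax(exp(log_intensity(cfg, "q12", age_h, female[idx], edu[idx], t[j])), 1e-12)
      t[j] <- t[j] + stats::rexp(length(j), rate = M)
      over <- t[j] > horizon
      active2[j[over]] <- FALSE
      j <- which(active2)
      if (!length(j)) break
      idx <- i2[j]
      age_now <- entry$entry_age[idx] + (t[j] - entry$entry_date[idx])
      q12 <- exp(log_intensity(cfg, "q12", age_now, female[idx], edu[idx], t[j]))
      age_h <- entry$entry_age[idx] + (horizon - entry$entry_date[idx])
      Mj <- pmax(exp(log_intensity(cfg, "q12", age_h, female[idx], edu[idx], t[j])), 1e-12)
      acc <- stats::runif(length(j)) < q12 / Mj
      hit <- j[acc]
      if (length(hit)) {
        death[i2[hit]] <- t[hit]
        active2[hit] <- FALSE
      }
    }
  }
  cvd <- !is.na(death) & stats::runif(n) < cvd_death_prob_vec(cfg, n)
  data.frame(id = entry$id, entry_date = entry$entry_date,
             entry_age = entry$entry_age, onset = onset, death = death,
             cvd_death = cvd)
}

cvd_death_prob_vec <- function(cfg, n) rep(cfg$cvd_death_prob, n)

#' Simulate one latent three-state trajectory
#'
#' Samples the unobserved no-dementia / dementia / death trajectory for a
#' single person from the time-inhomogeneous three-state process: dementia
#' onset, death without dementia, and death after dementia, with intensities
#' varying continuously with current age and calendar time. Simulation is
#' exact (thinning against a dominating constant rate), not Euler-discretised.
#'
#' @param config a [cohort_config()].
#' @param person_spec list or one-row data.frame with `id`, `entry_date`,
#'   `entry_age`, `female` (0/1), `education` ("low"/"middle"/"high").
#' @param seed optional seed overriding `config$seed`.
#' @return one-row data.frame: id, entry date/age, `onset` and `death`
#'   (decimal years, `NA` if not occurred before the last wave), `cvd_death`.
#' @export
simulate_latent <- function(config, person_spec, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  ps <- as.data.frame(person_spec)
  if (ps$entry_date > max(config$wave_dates))
    stop("entry date beyond the simulation horizon")
  if (!is.null(seed)) set.seed(seed)
  simulate_latent_many(config, ps)
}

#' Simulate a synthetic ageing panel
#'
#' Generates the full observed dataset: latent trajectories for core and
#' refreshment entrants, then wave-by-wave measurements (cognitive domain
#' scores, proxy informant scores, ADL dependency counts, doctor-diagnosis
#' reports) conditional on latent state, plus an exact death-date table.
#' Both the observed panel and the latent truth are returned so that
#' estimators can be scored against the generating process.
#'
#' @param config a [cohort_config()].
#' @return list of class `"panel_dataset"`:
#'   \item{panel}{data.frame, one row per alive person-wave: `id`, `wave`,
#'     `date`, `age`, `female`, `education`, domain scores `d1..dK` (NA when
#'     a proxy answered), `proxy` score (NA otherwise), `adl`, `dx`.}
#'   \item{deaths}{data.frame `id`, `death_date`, `cvd_death`.}
#'   \item{entry}{data.frame `id`, `first_wave`.}
#'   \item{truth}{latent trajectories as from [simulate_latent()].}
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  ms <- cfg$measurement_spec
  wd <- cfg$wave_dates

  ## entrants
  counts <- c(cfg$n_core, unname(cfg$refresh_waves))
  waves_in <- c(1L, as.integer(names(cfg$refresh_waves)))
  n <- sum(counts)
  first_wave <- rep(waves_in, counts)
  id <- seq_len(n)
  entry_date <- wd[first_wave]
  ae <- cfg$age_entry
  entry_age <- pmin(pmax(stats::rnorm(n, ae$mean, ae$sd), ae$min), ae$max)
  female <- as.integer(stats::runif(n) < cfg$sex_ratio)
  education <- sample(edu_levels, n, replace = TRUE, prob = cfg$education_probs)
  entry <- data.frame(id = id, entry_date = entry_date, entry_age = entry_age,
                      female = female, education = education,
                      stringsAsFactors = FALSE)

  truth <- simulate_latent_many(cfg, entry)
  truth$female <- female
  truth$education <- education

  ## person-wave grid: entry wave onward, strictly before death
  rows <- do.call(rbind, lapply(seq_along(wd), function(w) {
    alive <- first_wave <= w & (is.na(truth$death) | truth$death > wd[w])
    if (!any(alive)) return(NULL)
    i <- which(alive)
    data.frame(id = id[i], wave = w, date = wd[w],
               age = entry_age[i] + (wd[w] - entry_date[i]),
               female = female[i], education = education[i],
               state = as.integer(!is.na(truth$onset[i]) & truth$onset[i] <= wd[w]),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$id, rows$wave), , drop = FALSE]
  m <- nrow(rows)
  st <- rows$state

  ## proxy informant indicator
  p_proxy <- ifelse(st == 1L, ms$proxy_p_dementia, ms$proxy_p_healthy)
  proxy_resp <- stats::runif(m) < p_proxy

  K <- ms$n_domains
  mu <- ms$domain_mean[rows$education] + ms$dementia_shift * st
  scores <- matrix(NA_real_, m, K, dimnames = list(NULL, paste0("d", seq_len(K))))
  nself <- sum(!proxy_resp)
  if (nself > 0) {
    scores[!proxy_resp, ] <- stats::rnorm(nself * K, mean = mu[!proxy_resp],
                                          sd = ms$domain_sd)
  }
  proxy_score <- rep(NA_real_, m)
  if (any(proxy_resp)) {
    proxy_score[proxy_resp] <- stats::rnorm(sum(proxy_resp),
      ifelse(st[proxy_resp] == 1L, ms$proxy_mean_dementia, ms$proxy_mean_healthy),
      ifelse(st[proxy_resp] == 1L, ms$proxy_sd_dementia, ms$proxy_sd_healthy))
  }
  adl <- stats::rbinom(m, ms$adl_items,
                       ifelse(st == 1L, ms$adl_p_dementia, ms$adl_p_healthy))
  dx <- stats::rbinom(m, 1L, ifelse(st == 1L, ms$dx_sens, 1 - ms$dx_spec))
  if (isTRUE(ms$dx_persist)) {
    dx <- as.integer(unlist(tapply(dx, rows$id, cummax), use.names = FALSE))
  }

  panel <- cbind(rows[c("id", "wave", "date", "age", "female", "education")],
                 as.data.frame(scores))
  panel$proxy <- proxy_score
  panel$adl <- adl
  panel$dx <- dx

  deaths <- truth[!is.na(truth$death), c("id", "death", "cvd_death")]
  names(deaths)[2] <- "death_date"
  out <- list(panel = panel,
              deaths = deaths[order(deaths$id), , drop = FALSE],
              entry = data.frame(id = id, first_wave = first_wave),
              truth = truth)
  class(out) <- "panel_dataset"
  out
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Synthetic ageing panel:", length(unique(x$panel$id)), "participants,",
      nrow(x$panel), "person-wave rows,", nrow(x$deaths), "linked deaths\n")
  cat("Waves:", paste(sort(unique(x$panel$wave)), collapse = " "),
      " dates", min(x$panel$date), "-", max(x$panel$date), "\n")
  invisible(x)
}

#' Simulate a synthetic deaths/exposures surface
#'
#' Poisson death counts on an age-by-year grid, split into cardiovascular and
#' non-cardiovascular causes, from a Gompertz-in-age log-rate surface with a
#' log-linear calendar trend and a (logit-linear) CVD share. Serves as the
#' input fixture for the two-dimensional P-spline mortality forecaster.
#'
#' @param age_range integer vector of ages (e.g. `35:100`).
#' @param year_range integer vector of calendar years.
#' @param baseline_spec list: `log_rate0` (log all-cause rate at `age_ref`),
#'   `age_ref` (default 70), `gompertz_slope` (per year of age), `year_slope`
#'   (log-linear calendar slope), `cvd_share0` (CVD share of deaths at
#'   reference, logit scale applies), `cvd_year_slope` (logit-linear calendar
#'   change of the CVD share), `exposure` (person-years per cell, scalar or
#'   matrix).
#' @param seed integer seed.
#' @return data.frame with columns age, year, cause ("cvd"/"noncvd"),
#'   deaths, exposure, true_rate (cause-specific).
#' @export
simulate_mortality_surface <- function(age_range, year_range,
                                       baseline_spec = list(), seed = 1L) {
  bs <- utils::modifyList(list(log_rate0 = log(0.02), age_ref = 70,
                               gompertz_slope = 0.095, year_slope = -0.015,
                               cvd_share0 = 0.35, cvd_year_slope = -0.03,
                               exposure = 1e4), baseline_spec)
  grid <- expand.grid(age = age_range, year = year_range)
  expo <- bs$exposure
  if (length(expo) == 1L) expo <- rep(expo, nrow(grid))
  if (any(expo < 0)) stop("negative exposures")
  rate <- exp(bs$log_rate0 + bs$gompertz_slope * (grid$age - bs$age_ref) +
                bs$year_slope * (grid$year - min(year_range)))
  share <- stats::plogis(stats::qlogis(bs$cvd_share0) +
                           bs$cvd_year_slope * (grid$year - min(year_range)))
  set.seed(seed)
  d_cvd <- stats::rpois(nrow(grid), expo * rate * share)
  d_non <- stats::rpois(nrow(grid), expo * rate * (1 - share))
  rbind(
    data.frame(grid, cause = "cvd", deaths = d_cvd, exposure = expo,
               true_rate = rate * share),
    data.frame(grid, cause = "noncvd", deaths = d_non, exposure = expo,
               true_rate = rate * (1 - share)))
}
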