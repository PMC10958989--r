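#' Build overlapping 4-year dementia-free subcohorts
#'
#' From a panel and its dementia ascertainment, constructs one subcohort per
#' eligible baseline wave: participants aged `min_age` or older and
#' dementia-free at baseline, followed from baseline to dementia onset, death
#' or `followup` years, whichever comes first. Onset dates are
#' midpoint-imputed between the wave at which dementia is first ascertained
#' and the person's previous observed wave, using actual interview dates.
#' The final wave yields no subcohort (no follow-up available to ascertain
#' cases); with the default nine-wave biennial design this gives the seven
#' overlapping subcohorts 2002-06 ... 2014-18.
#'
#' A death between waves with no intervening dementia observation counts as a
#' death, not a dementia case: this is exactly the missing-cases-due-to-death
#' bias that the multistate model corrects, and the contrast between the two
#' estimates is a deliverable of the package.
#'
#' @param panel a `panel_dataset` or its `panel` data.frame (then supply
#'   `deaths`).
#' @param status a `dementia_status` from [ascertain_dementia()].
#' @param baseline_waves integer vector of baseline wave indices; default all
#'   waves whose baseline + `followup` lies within the observed wave span.
#' @param followup follow-up horizon in years (default 4).
#' @param min_age baseline age floor (default 50).
#' @param deaths death table (`id`, `death_date`) if `panel` is a bare
#'   data.frame.
#' @return data.frame of subcohort records: subcohort (baseline wave),
#'   baseline_year, id, age, female, education, event
#'   ("dementia"/"death"/"censored"), time (person-years), onset_date.
#' @export
build_subcohorts <- function(panel, status, baseline_waves = NULL,
                             followup = 4, min_age = 50, deaths = NULL) {
  if (inherits(panel, "panel_dataset")) {
    deaths <- panel$deaths
    panel <- panel$panel
  }
  if (is.null(deaths)) deaths <- data.frame(id = integer(), death_date = numeric())
  st <- status$status
  wave_dates <- tapply(panel$date, panel$wave, function(d) d[1])
  waves <- as.integer(names(wave_dates))
  if (is.null(baseline_waves)) {
    last_date <- max(wave_dates)
    baseline_waves <- waves[wave_dates + followup <= last_date]
  }
  key <- paste(panel$id, panel$wave)
  stkey <- paste(st$id, st$wave)
  dem_at <- st$dementia_abs[match(key, stkey)]

  death_date <- deaths$death_date[match(panel$id, deaths$id)]

  out <- vector("list", length(baseline_waves))
  for (k in seq_along(baseline_waves)) {
    b <- baseline_waves[k]
    b_date <- wave_dates[as.character(b)]
    in_b <- panel$wave == b & panel$age >= min_age & !is.na(dem_at) & !dem_at
    ids <- panel$id[in_b]
    if (!length(ids)) next
    rec <- data.frame(subcohort = b, baseline_year = as.numeric(b_date),
                      id = ids, age = panel$age[in_b],
                      female = panel$female[in_b],
                      education = panel$education[in_b])
    ## first ascertained dementia wave strictly after baseline
    fw <- status$first_wave$first_wave[match(ids, status$first_wave$id)]
    onset <- rep(NA_real_, length(ids))
    has <- !is.na(fw) & fw > b
    if (any(has)) {
      ## midpoint between the first-dementia wave and the person's previous
      ## observed wave, by actual interview dates
      dem_date <- panel$date[match(paste(ids[has], fw[has]), key)]
      prev <- mapply(function(pid, w) {
        dts <- panel$date[panel$id == pid & panel$wave < w]
        if (length(dts)) max(dts) else NA_real_
      }, ids[has], fw[has])
      onset[has] <- (dem_date + prev) / 2
    }
    ddate <- deaths$death_date[match(ids, deaths$id)]
    end_admin <- as.numeric(b_date) + followup
    t_dem <- ifelse(!is.na(onset) & onset <= end_admin, onset, Inf)
    t_die <- ifelse(!is.na(ddate) & ddate <= end_admin, ddate, Inf)
    event <- ifelse(t_dem <= t_die & is.finite(t_dem), "dementia",
                    ifelse(is.finite(t_die), "death", "censored"))
    exit <- pmin(t_dem, t_die, end_admin)
    rec$event <- event
    rec$time <- pmax(as.numeric(exit) - as.numeric(b_date), 1e-8)
    rec$onset_date <- ifelse(event == "dementia", as.numeric(t_dem), NA_real_)
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Crude incidence rate
#'
#' Incident cases divided by person-years, scaled to `per` person-years.
#'
#' @param records subcohort records from [build_subcohorts()].
#' @param per scale (default per 1000 person-years).
#' @return numeric rate.
#' @export
crude_rate <- function(records, per = 1000) {
  py <- sum(records$time)
  if (py <= 0) stop("zero person-years")
  sum(records$event == "dementia") / py * per
}

#' Standard population table
#'
#' Age-band by sex weight counts for direct standardisation. The packaged
#' default (`standard_population()`) is a census-shaped synthetic table
#' approximating the England and Wales 2011 age 50+ population in 5-year
#' bands (thousands); any table with columns `age_lo`, `age_hi`, `female`,
#' `weight` is accepted by [standardised_rate()].
#'
#' @return data.frame with columns age_lo, age_hi, female (0/1), weight.
#' @export
standard_population <- function() {
  f <- system.file("extdata", "standard_pop_2011_synthetic.csv",
                   package = "demtrend")
  utils::read.csv(f)
}

#' Directly standardised incidence rate
#'
#' Weighted mean of stratum-specific crude rates, weights from a standard
#' population: \eqn{\sum_s w_s r_s / \sum_s w_s}. Strata are age bands by
#' sex. Strata with positive weight but no person-years are dropped and the
#' weights renormalised, with a warning.
#'
#' @param records subcohort records from [build_subcohorts()].
#' @param std standard population data.frame (see [standard_population()]).
#' @param per rate scale (default 1000).
#' @return numeric standardised rate.
#' @export
standardised_rate <- function(records, std = standard_population(), per = 1000) {
  num <- 0; den <- 0; dropped <- 0
  for (r in seq_len(nrow(std))) {
    w <- std$weight[r]
    if (w <= 0) next
    in_s <- records$age >= std$age_lo[r] & records$age <= std$age_hi[r] &
      records$female == std$female[r]
    py <- sum(records$time[in_s])
    if (py <= 0) { dropped <- dropped + w; next }
    rate <- sum(records$event[in_s] == "dementia") / py * per
    num <- num + w * rate
    den <- den + w
  }
  if (dropped > 0)
    warning("strata with positive weight but no person-years dropped; weights renormalised")
  if (den <= 0) stop("no overlapping strata between records and standard population")
  num / den
}

#' Subgroup crude incidence rates
#'
#' Crude rates within subgroups defined by baseline age (&lt;75 vs &gt;=75),
#' sex, or education.
#'
#' @param records subcohort records from [build_subcohorts()].
#' @param by one of "age", "sex", "education".
#' @param per rate scale.
#' @param age_cut age split (default 75).
#' @return data.frame: group, cases, person_years, rate.
#' @export
subgroup_rates <- function(records, by = c("age", "sex", "education"),
                           per = 1000, age_cut = 75) {
  by <- match.arg(by)
  g <- switch(by,
              age = ifelse(records$age < age_cut,
                           paste0("<", age_cut), paste0(">=", age_cut)),
              sex = ifelse(records$female == 1, "women", "men"),
              education = records$education)
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), g), function(i) {
    data.frame(group = g[i[1]],
               cases = sum(records$event[i] == "dementia"),
               person_years = sum(records$time[i]))
  }))
  out$rate <- out$cases / out$person_years * per
  rownames(out) <- NULL
  out
}

#' Incidence rate table across subcohorts
#'
#' Crude, standardised and subgroup rates per subcohort, mirroring the usual
#' presentation of subcohort incidence analyses.
#'
#' @param records subcohort records from [build_subcohorts()].
#' @param std standard population.
#' @param per rate scale.
#' @return data.frame, one row per subcohort.
#' @export
incidence_table <- function(records, std = standard_population(), per = 1000) {
  do.call(rbind, lapply(split(records, records$subcohort), function(r) {
    sg <- function(by) {
      t <- subgroup_rates(r, by, per)
      stats::setNames(t$rate, paste0(by, "_", t$group))
    }
    row <- c(crude = crude_rate(r, per),
             standardised = suppressWarnings(standardised_rate(r, std, per)),
             sg("age"), sg("sex"), sg("education"))
    out <- data.frame(subcohort = r$subcohort[1],
                      baseline_year = r$baseline_year[1])
    out[names(row)] <- unname(row)
    out
  }))
}
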