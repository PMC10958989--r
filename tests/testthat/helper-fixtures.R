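## shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

## high-separation measurement layer: dementia shifts scores far below any
## education-stratified threshold, ADL and diagnosis are deterministic/off,
## so ascertainment is (up to interval censoring) the latent truth
noiseless_measurement <- function() {
  list(dementia_shift = -6, adl_p_healthy = 0, adl_p_dementia = 1,
       dx_sens = 0, dx_spec = 1, proxy_p_healthy = 0, proxy_p_dementia = 0)
}

no_refresh <- function() stats::setNames(integer(0), character(0))

## default-condition panel: the generator's own defaults (V-shaped calendar
## trend, misclassification-prone measurements, refreshment samples)
shared_cfg <- function() cohort_config(n_core = 1500, seed = 42)

shared_panel <- function() memo("panel", simulate_panel(shared_cfg()))

shared_status <- function() memo("status", ascertain_dementia(shared_panel()))

shared_records <- function()
  memo("records", build_subcohorts(shared_panel(), shared_status()))

## noiseless panel with no education effects: estimators can be scored
## directly against the generating intensities
clean_cfg <- function(n_core = 2000, seed = 11, ...)
  cohort_config(n_core = n_core, refresh_waves = no_refresh(),
                edu_coefs = c(low = 0, middle = 0, high = 0),
                measurement_spec = noiseless_measurement(), seed = seed, ...)

clean_panel <- function() memo("clean_panel", simulate_panel(clean_cfg()))

clean_status <- function() memo("clean_status", ascertain_dementia(clean_panel()))

clean_msm_fit <- function()
  memo("clean_msm_fit",
       fit_msm(clean_panel(), clean_status(),
               msm_spec(calendar = "piecewise", emission = "none",
                        cal_eval = "midpoint"),
               status_col = "dementia_abs"))

## build a dementia_status object directly from known wave-level states
## (bypasses the case-definition layer; used to feed the multistate model
## with hand-controlled observations)
make_status <- function(id, wave, state) {
  st <- list(status = data.frame(id = id, wave = wave,
                                 dementia = as.logical(state),
                                 dementia_abs = as.logical(state)),
             first_wave = data.frame(id = integer(), first_wave = integer()))
  class(st) <- "dementia_status"
  st
}

## minimal panel data.frame for hand-built multistate fixtures
make_panel <- function(id, wave, date, state, age = 75, female = 0,
                       education = "middle") {
  data.frame(id = id, wave = wave, date = date, age = age, female = female,
             education = education, state = state)
}
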