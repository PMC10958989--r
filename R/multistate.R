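#' Three-state interval transition probabilities
#'
#' Closed-form transition probability matrix of the progressive illness-death
#' process (1 = no dementia, 2 = dementia, 3 = dead; no recovery) with
#' intensities held constant over the interval:
#' \deqn{P_{11} = e^{-(q_{01}+q_{02})\Delta t},\quad P_{22} = e^{-q_{12}\Delta t},}
#' \deqn{P_{12} = q_{01}\,\frac{e^{-(q_{01}+q_{02})\Delta t} - e^{-q_{12}\Delta t}}
#'   {q_{12} - q_{01} - q_{02}},}
#' with the removable singularity at \eqn{q_{12} = q_{01}+q_{02}} handled by a
#' series expansion. Equals the matrix exponential `expm(Q * dt)` of the
#' intensity matrix. All arguments recycle, so vectorised use over many
#' intervals returns the component probabilities.
#'
#' @param q01,q02,q12 transition intensities (per year), non-negative.
#' @param dt interval length in years, `dt >= 0`.
#' @param components if `TRUE`, return a data.frame of the distinct entries
#'   (vectorised); otherwise a single 3x3 matrix (scalar inputs only).
#' @return 3x3 row-stochastic matrix, or data.frame p00, p01, p02, p11, p12.
#' @export
transition_matrix <- function(q01, q02, q12, dt, components = FALSE) {
  if (any(!is.finite(c(q01, q02, q12))) || any(c(q01, q02, q12) < 0))
    stop("intensities must be finite and non-negative")
  if (any(dt < 0)) stop("dt must be non-negative")
  a <- q01 + q02
  p00 <- exp(-a * dt)
  p11 <- exp(-q12 * dt)
  d <- q12 - a
  x <- d * dt
  ratio <- ifelse(abs(x) < 1e-8, dt * (1 - x / 2 + x^2 / 6), -expm1(-x) / d)
  p01 <- q01 * p00 * ratio
  p02 <- pmax(1 - p00 - p01, 0)
  p12 <- pmax(1 - p11, 0)
  if (components || length(p00) > 1L)
    return(data.frame(p00 = p00, p01 = p01, p02 = p02, p11 = p11, p12 = p12))
  matrix(c(p00, p01, p02, 0, p11, p12, 0, 0, 1), 3, 3, byrow = TRUE,
         dimnames = rep(list(c("nodem", "dem", "dead")), 2))
}

#' Specification of the multistate trend model
#'
#' Defines the parametric form of the three transition intensities. Each
#' intensity is log-linear in its covariates: dementia onset (0 to 1) gets
#' age (linear or restricted cubic spline), sex, optionally an age-by-sex
#' interaction, and a calendar-time term; the two mortality intensities get
#' linear age, sex, and optionally a linear calendar term. The calendar form
#' for dementia onset is the estimand of interest:
#' * `"linear"`: one slope (log-linear trend);
#' * `"piecewise"`: linear spline with a break at `cal_break` (two slopes,
#'   before/after the break);
#' * `"rcs"`: restricted cubic spline with knots `cal_knots`;
#' * `"none"`: no calendar effect.
#'
#' A misclassification (emission) layer links true and observed dementia
#' status: `e01 = P(observe dementia | no dementia)` and
#' `e10 = P(observe no dementia | dementia)`, estimated on the logit scale;
#' death is observed without error.
#'
#' @param age `"linear"`, `"rcs"` or `"none"`: age form on the onset
#'   intensity (`"none"` also drops age from the mortality intensities, for
#'   intercept-only models).
#' @param age_knots knots for the age spline (default 60, 70, 80).
#' @param calendar calendar form on the onset intensity.
#' @param cal_knots RCS knots for calendar time.
#' @param cal_break break year of the piecewise form (default 2008).
#' @param cal_ref reference year (default 2002).
#' @param calendar_mort `"none"` or `"linear"` calendar effect on the two
#'   mortality intensities.
#' @param sex include sex on all transitions.
#' @param age_sex include age-by-sex interaction on the onset intensity.
#' @param emission `"none"`, `"both"`, `"e01"` or `"e10"`.
#' @param group optional subgroup variable name (`"education"`, `"sex"`,
#'   `"agegrp"`) for group main effects on the onset intensity.
#' @param group_interaction interact the calendar term with the subgroup
#'   (group-specific calendar trends); requires `group`.
#' @param cal_eval evaluate interval covariates at the interval `"start"`
#'   (default) or `"midpoint"`.
#' @return object of class `"msm_spec"`.
#' @export
msm_spec <- function(age = c("linear", "rcs", "none"), age_knots = c(60, 70, 80),
                     calendar = c("piecewise", "linear", "rcs", "none"),
                     cal_knots = c(2002, 2006, 2010, 2016), cal_break = 2008,
                     cal_ref = 2002,
                     calendar_mort = c("none", "linear"),
                     sex = TRUE, age_sex = FALSE,
                     emission = c("none", "both", "e01", "e10"),
                     group = NULL, group_interaction = FALSE,
                     cal_eval = c("start", "midpoint")) {
  out <- list(age = match.arg(age), age_knots = age_knots,
              calendar = match.arg(calendar), cal_knots = cal_knots,
              cal_break = cal_break, cal_ref = cal_ref,
              calendar_mort = match.arg(calendar_mort),
              sex = sex, age_sex = age_sex, emission = match.arg(emission),
              group = group, group_interaction = group_interaction,
              cal_eval = match.arg(cal_eval))
  if (out$group_interaction && is.null(out$group))
    stop("group_interaction requires a group variable")
  class(out) <- "msm_spec"
  out
}

## calendar-term columns (no intercept); names stable for contrasts
cal_columns <- function(year, spec) {
  switch(spec$calendar,
         none = NULL,
         linear = {
           m <- cbind(cal = year - spec$cal_ref); m
         },
         piecewise = cbind(cal_pre = pmin(year, spec$cal_break) - spec$cal_ref,
                           cal_post = pmax(year - spec$cal_break, 0)),
         rcs = {
           B <- rcs_basis(year, spec$cal_knots)
           colnames(B) <- paste0("cal_", colnames(B))
           B
         })
}

age_columns <- function(age, spec) {
  if (spec$age == "none") return(NULL)
  if (spec$age == "linear") return(cbind(age = age - 75))
  B <- rcs_basis(age, spec$age_knots)
  colnames(B) <- paste0("age_", colnames(B))
  B
}

## design matrix for the onset intensity at given covariates
design_q01 <- function(df, spec, group_levels = NULL) {
  X <- cbind(`(b0)` = rep(1, nrow(df)), age_columns(df$age, spec))
  if (spec$sex) X <- cbind(X, female = df$female)
  if (spec$age_sex) X <- cbind(X, age_female = (df$age - 75) * df$female)
  CC <- cal_columns(df$year, spec)
  if (!is.null(spec$group)) {
    g <- factor(df$group, levels = group_levels)
    L <- levels(g)
    if (length(L) > 1L) {
      D <- vapply(L[-1], function(l) as.numeric(g == l), numeric(nrow(df)))
      if (is.null(dim(D))) D <- matrix(D, nrow = nrow(df))
      colnames(D) <- paste0("g_", L[-1])
      X <- cbind(X, D)
    }
    if (spec$group_interaction && !is.null(CC)) {
      for (l in L) {
        Xi <- CC * as.numeric(g == l)
        colnames(Xi) <- paste0(colnames(CC), "_", l)
        X <- cbind(X, Xi)
      }
      CC <- NULL
    }
  }
  if (!is.null(CC)) X <- cbind(X, CC)
  X
}

design_mort <- function(df, spec) {
  X <- cbind(`(b0)` = rep(1, nrow(df)))
  if (spec$age != "none") X <- cbind(X, age = df$age - 75)
  if (spec$sex) X <- cbind(X, female = df$female)
  if (spec$calendar_mort == "linear")
    X <- cbind(X, cal = df$year - spec$cal_ref)
  X
}

## Assemble interval data for the hidden-Markov likelihood from a panel and
## its wave-level dementia status.
msm_data <- function(panel, status, deaths = NULL,
                     status_col = "dementia", group = NULL) {
  if (inherits(panel, "panel_dataset")) {
    deaths <- panel$deaths
    panel <- panel$panel
  }
  st <- status$status
  key <- paste(panel$id, panel$wave)
  obs_state <- st[[status_col]][match(key, paste(st$id, st$wave))]
  d <- data.frame(id = panel$id, date = panel$date, age = panel$age,
                  female = panel$female, education = panel$education,
                  state = as.integer(obs_state))
  d <- d[!is.na(d$state), ]
  d <- d[order(d$id, d$date), ]
  ## entry characteristics per subject
  first <- !duplicated(d$id)
  entry_age <- d$age[first][match(d$id, d$id[first])]
  if (!is.null(group)) {
    d$group <- switch(group,
                      education = d$education,
                      sex = ifelse(d$female == 1, "women", "men"),
                      agegrp = ifelse(entry_age < 75, "lt75", "ge75"),
                      stop("unknown group variable"))
  }
  dd <- if (!is.null(deaths)) deaths else data.frame(id = integer(), death_date = numeric())

  ids <- unique(d$id)
  sid <- match(d$id, ids)
  ## intervals between consecutive observations of one subject
  i0 <- which(c(diff(sid) == 0, FALSE))          # row of interval start
  i1 <- i0 + 1L
  iv <- data.frame(subj = sid[i0], t0 = d$date[i0], t1 = d$date[i1],
                   age = d$age[i0], female = d$female[i0],
                   year = d$date[i0], end_state = d$state[i1],
                   type = 1L)
  if (!is.null(group)) iv$group <- d$group[i0]
  ## death intervals: from each subject's last observation to the death date
  last <- rev(!duplicated(rev(sid)))
  ld <- d[last, ]
  ddate <- dd$death_date[match(ld$id, dd$id)]
  has_death <- !is.na(ddate) & ddate > ld$date
  if (any(has_death)) {
    dv <- data.frame(subj = match(ld$id[has_death], ids),
                     t0 = ld$date[has_death], t1 = ddate[has_death],
                     age = ld$age[has_death], female = ld$female[has_death],
                     year = ld$date[has_death], end_state = NA_integer_,
                     type = 2L)
    if (!is.null(group)) dv$group <- ld$group[has_death]
    iv <- rbind(iv, dv)
  }
  iv <- iv[order(iv$subj, iv$t0, iv$type), ]
  iv$dt <- iv$t1 - iv$t0
  if (any(iv$dt < 0)) stop("observation after recorded death")
  iv$k <- stats::ave(iv$subj, iv$subj, FUN = seq_along)
  ## covariates at the interval midpoint if requested happens in fit (shift)
  entry_state <- d$state[first]
  list(intervals = iv, n_subj = length(ids), entry_state = entry_state,
       ids = ids,
       group_levels = if (!is.null(group)) sort(unique(d$group)) else NULL)
}

## Vectorised hidden-Markov forward log-likelihood over all subjects.
## q01, q02, q12: per-interval-row intensities; eps on probability scale.
msm_engine <- function(md, q01, q02, q12, eps01, eps10) {
  iv <- md$intervals
  P <- transition_matrix(q01, q02, q12, iv$dt, components = TRUE)
  f0 <- as.numeric(md$entry_state == 0L)
  f1 <- 1 - f0
  ll <- numeric(md$n_subj)
  maxk <- max(iv$k)
  rows_k <- split(seq_len(nrow(iv)), iv$k)
  for (k in seq_len(maxk)) {
    r <- rows_k[[as.character(k)]]
    if (is.null(r)) next
    s <- iv$subj[r]
    wave <- iv$type[r] == 1L
    if (any(wave)) {
      rw <- r[wave]; sw <- s[wave]
      g0 <- f0[sw] * P$p00[rw]
      g1 <- f0[sw] * P$p01[rw] + f1[sw] * P$p11[rw]
      obs <- iv$end_state[rw]
      e0 <- ifelse(obs == 1L, eps01, 1 - eps01)
      e1 <- ifelse(obs == 1L, 1 - eps10, eps10)
      g0 <- g0 * e0; g1 <- g1 * e1
      tot <- g0 + g1
      if (any(!is.finite(tot)) || any(tot <= 0)) return(NA_real_)
      ll[sw] <- ll[sw] + log(tot)
      f0[sw] <- g0 / tot; f1[sw] <- g1 / tot
    }
    if (any(!wave)) {
      rd <- r[!wave]; sd_ <- s[!wave]
      dens <- f0[sd_] * (P$p00[rd] * q02[rd] + P$p01[rd] * q12[rd]) +
        f1[sd_] * P$p11[rd] * q12[rd]
      if (any(!is.finite(dens)) || any(dens <= 0)) return(NA_real_)
      ll[sd_] <- ll[sd_] + log(dens)
    }
  }
  sum(ll)
}

#' Hidden-Markov log-likelihood of one observation sequence
#'
#' Forward recursion over the latent living states for a single subject:
#' starts from a point mass at the observed entry state, propagates through
#' each inter-observation interval with the closed-form transition matrix
#' (intensities fixed within the interval), multiplies by the emission
#' probability of the observed status at each wave, and, if the subject died,
#' terminates with the exact-death-time contribution
#' \eqn{\sum_s f_s(t_d^-) q_{s,dead}} summed over the unknown living state at
#' death.
#'
#' @param times observation dates (increasing), the waves at which status was
#'   observed.
#' @param states observed status at each time (0 no dementia, 1 dementia).
#' @param q01,q02,q12 per-interval intensity vectors (length
#'   `length(times) - 1`, plus one more element for the death interval when
#'   `death_time` is given).
#' @param death_time exact death date (`NULL` if alive/censored).
#' @param eps01,eps10 misclassification probabilities.
#' @return log-likelihood (scalar).
#' @export
msm_subject_loglik <- function(times, states, q01, q02, q12,
                               death_time = NULL, eps01 = 0, eps10 = 0) {
  stopifnot(length(times) == length(states), all(diff(times) > 0))
  n_iv <- length(times) - 1L + as.integer(!is.null(death_time))
  stopifnot(length(q01) == n_iv, length(q02) == n_iv, length(q12) == n_iv)
  f <- if (states[1] == 0L) c(1, 0) else c(0, 1)
  ll <- 0
  if (length(times) > 1L) for (i in seq_len(length(times) - 1L)) {
    P <- transition_matrix(q01[i], q02[i], q12[i], times[i + 1L] - times[i])
    g <- c(f[1] * P[1, 1], f[1] * P[1, 2] + f[2] * P[2, 2])
    e <- if (states[i + 1L] == 1L) c(eps01, 1 - eps10) else c(1 - eps01, eps10)
    g <- g * e
    if (sum(g) <= 0) return(-Inf)
    ll <- ll + log(sum(g))
    f <- g / sum(g)
  }
  if (!is.null(death_time)) {
    i <- n_iv
    if (death_time <= times[length(times)]) stop("observation after death")
    P <- transition_matrix(q01[i], q02[i], q12[i], death_time - times[length(times)])
    dens <- f[1] * (P[1, 1] * q02[i] + P[1, 2] * q12[i]) + f[2] * P[2, 2] * q12[i]
    if (dens <= 0) return(-Inf)
    ll <- ll + log(dens)
  }
  ll
}

#' Fit the three-state hidden-Markov trend model
#'
#' Maximum-likelihood fit of the illness-death model with panel-observed
#' dementia status, exactly observed death dates, and an optional
#' misclassification layer. This is the bias-corrected trend estimator: by
#' modelling the no-dementia to dementia and dementia to death intensities
#' jointly, people who develop dementia and die before the next wave
#' contribute correctly to the onset intensity, which naive wave-to-wave
#' analyses miss.
#'
#' Covariates are piecewise-constant per inter-wave interval, evaluated at
#' the interval start (age and calendar year at the last wave). Optimisation
#' is quasi-Newton (BFGS) from crude-rate starting values, optionally with
#' seeded multi-start; standard errors come from the observed information
#' (numerical Hessian).
#'
#' @param panel a `panel_dataset` or panel data.frame.
#' @param status a `dementia_status` from [ascertain_dementia()].
#' @param spec an [msm_spec()].
#' @param deaths death table if `panel` is a bare data.frame.
#' @param status_col which status column feeds the observed states:
#'   `"dementia"` (wave-level, may revert; default) or `"dementia_abs"`.
#' @param inits optional starting parameter vector.
#' @param n_starts number of optimisation starts (first from crude rates,
#'   others jittered; seeded).
#' @param seed seed for the multi-start jitter.
#' @param hessian compute the observed-information covariance.
#' @param control passed to [stats::optim()].
#' @return object of class `"msm_trend"` with elements `theta`, `vcov`,
#'   `logLik`, `spec`, `par_index`, `convergence`, `n_subj`, `n_obs`.
#' @export
fit_msm <- function(panel, status, spec = msm_spec(), deaths = NULL,
                    status_col = "dementia", inits = NULL, n_starts = 1L,
                    seed = 1L, hessian = TRUE,
                    control = list(maxit = 500, reltol = 1e-10)) {
  md <- msm_data(panel, status, deaths, status_col = status_col,
                 group = spec$group)
  iv <- md$intervals
  if (spec$cal_eval == "midpoint") {
    iv$age <- iv$age + iv$dt / 2
    iv$year <- iv$year + iv$dt / 2
    md$intervals <- iv
  }
  df <- data.frame(age = iv$age, female = iv$female, year = iv$year)
  if (!is.null(spec$group)) df$group <- iv$group
  X01 <- design_q01(df, spec, md$group_levels)
  X02 <- design_mort(df, spec)
  X12 <- design_mort(df, spec)
  p01 <- ncol(X01); p02 <- ncol(X02); p12 <- ncol(X12)
  n_eps <- switch(spec$emission, none = 0L, both = 2L, e01 = 1L, e10 = 1L)
  idx <- list(q01 = seq_len(p01), q02 = p01 + seq_len(p02),
              q12 = p01 + p02 + seq_len(p12),
              eps = if (n_eps) p01 + p02 + p12 + seq_len(n_eps) else integer())
  names_theta <- c(paste0("q01:", colnames(X01)), paste0("q02:", colnames(X02)),
                   paste0("q12:", colnames(X12)),
                   switch(spec$emission, none = character(),
                          both = c("logit_e01", "logit_e10"),
                          e01 = "logit_e01", e10 = "logit_e10"))

  eps_fun <- function(theta) {
    e01 <- 0; e10 <- 0
    if (spec$emission %in% c("both", "e01"))
      e01 <- stats::plogis(theta[idx$eps[1]])
    if (spec$emission == "both") e10 <- stats::plogis(theta[idx$eps[2]])
    if (spec$emission == "e10") e10 <- stats::plogis(theta[idx$eps[1]])
    c(e01, e10)
  }
  nll <- function(theta) {
    q01 <- exp(drop(X01 %*% theta[idx$q01]))
    q02 <- exp(drop(X02 %*% theta[idx$q02]))
    q12 <- exp(drop(X12 %*% theta[idx$q12]))
    if (any(!is.finite(c(q01, q02, q12)))) return(1e10)
    e <- eps_fun(theta)
    ll <- msm_engine(md, q01, q02, q12, e[1], e[2])
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (is.null(inits)) inits <- msm_crude_inits(md, idx, spec)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) inits else inits + stats::rnorm(length(inits), 0, 0.3)
    opt <- stats::optim(th0, nll, method = "BFGS", control = control)
    ## polish: restart once from the optimum (helps boundary emissions)
    opt2 <- stats::optim(opt$par, nll, method = "BFGS", control = control)
    if (opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$convergence != 0)
    warning("optimiser did not report convergence (code ",
            best$convergence, ")")
  V <- NULL; H <- NULL; hess_pd <- NA
  if (hessian) {
    H <- stats::optimHess(best$par, nll)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    hess_pd <- all(ev > 0)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || !hess_pd) {
      warning("observed information not positive definite; pseudo-inverse CIs")
      sv <- svd(H)
      pos <- sv$d > max(sv$d) * 1e-10
      V <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    }
    V <- (V + t(V)) / 2
    dimnames(V) <- list(names_theta, names_theta)
  }
  theta <- stats::setNames(best$par, names_theta)
  out <- list(theta = theta, vcov = V, logLik = -best$value,
              spec = spec, par_index = idx, convergence = best$convergence,
              hessian_pd = hess_pd, n_subj = md$n_subj, n_obs = nrow(iv),
              group_levels = md$group_levels,
              counts = table(factor(iv$type, 1:2, c("wave", "death"))))
  class(out) <- "msm_trend"
  out
}

## crude transition-rate starting values from the observed state table
msm_crude_inits <- function(md, idx, spec) {
  iv <- md$intervals
  ## reconstruct start-state guess: forward observed states
  ## approximate person-years and transition counts from observed sequences
  wave <- iv$type == 1L
  start_state <- numeric(nrow(iv))
  ## observed state at interval start: entry state for k=1, else previous end
  prev <- c(NA, iv$end_state[-nrow(iv)])
  prev[iv$k == 1L] <- md$entry_state[iv$subj[iv$k == 1L]]
  ## death intervals: start state is the last observed state
  prev[is.na(prev) & iv$type == 2L] <-
    md$entry_state[iv$subj[is.na(prev) & iv$type == 2L]]
  prev[is.na(prev)] <- 0L
  py0 <- sum(iv$dt[prev == 0L]); py1 <- sum(iv$dt[prev == 1L])
  n01 <- sum(wave & prev == 0L & iv$end_state == 1L, na.rm = TRUE)
  n02 <- sum(!wave & prev == 0L)
  n12 <- sum(!wave & prev == 1L)
  r <- function(n, py) log(pmax(n, 0.5) / max(py, 1))
  th <- numeric(max(unlist(idx)))
  th[idx$q01[1]] <- r(n01, py0)
  th[idx$q02[1]] <- r(n02, py0)
  th[idx$q12[1]] <- r(n12, py1)
  if (length(idx$eps)) th[idx$eps] <- stats::qlogis(0.02)
  th
}

#' Model log-likelihood at arbitrary parameter values
#'
#' Evaluates the full hidden-Markov panel log-likelihood for a given
#' parameter vector, without optimising. Mainly for diagnostics and
#' cross-checking the likelihood against independent implementations.
#'
#' @inheritParams fit_msm
#' @param theta parameter vector in the same layout as a [fit_msm()] fit
#'   (onset, no-dementia mortality, dementia mortality blocks, then logit
#'   emissions).
#' @return scalar log-likelihood.
#' @export
msm_loglik <- function(theta, panel, status, spec = msm_spec(), deaths = NULL,
                       status_col = "dementia") {
  md <- msm_data(panel, status, deaths, status_col = status_col,
                 group = spec$group)
  iv <- md$intervals
  if (spec$cal_eval == "midpoint") {
    iv$age <- iv$age + iv$dt / 2
    iv$year <- iv$year + iv$dt / 2
    md$intervals <- iv
  }
  df <- data.frame(age = iv$age, female = iv$female, year = iv$year)
  if (!is.null(spec$group)) df$group <- iv$group
  X01 <- design_q01(df, spec, md$group_levels)
  X02 <- design_mort(df, spec)
  X12 <- design_mort(df, spec)
  p01 <- ncol(X01); p02 <- ncol(X02); p12 <- ncol(X12)
  n_eps <- switch(spec$emission, none = 0L, both = 2L, e01 = 1L, e10 = 1L)
  stopifnot(length(theta) == p01 + p02 + p12 + n_eps)
  q01 <- exp(drop(X01 %*% theta[seq_len(p01)]))
  q02 <- exp(drop(X02 %*% theta[p01 + seq_len(p02)]))
  q12 <- exp(drop(X12 %*% theta[p01 + p02 + seq_len(p12)]))
  e01 <- 0; e10 <- 0
  if (spec$emission %in% c("both", "e01"))
    e01 <- stats::plogis(theta[p01 + p02 + p12 + 1])
  if (spec$emission == "both") e10 <- stats::plogis(theta[p01 + p02 + p12 + 2])
  if (spec$emission == "e10") e10 <- stats::plogis(theta[p01 + p02 + p12 + 1])
  msm_engine(md, q01, q02, q12, e01, e10)
}

#' Likelihood-ratio test of nested multistate fits
#'
#' @param nested,full two [fit_msm()] fits on the same data, the first nested
#'   in the second.
#' @return list: statistic, df, p_value.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "msm_trend"), inherits(full, "msm_trend"))
  df <- length(full$theta) - length(nested$theta)
  if (df <= 0) stop("models are not nested (no extra parameters in `full`)")
  if (nested$n_obs != full$n_obs)
    stop("fits are not on the same data")
  stat <- max(2 * (full$logLik - nested$logLik), 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

## calendar contrast vector(s) in full-parameter space
cal_contrast <- function(fit, years, ref, group_level = NULL) {
  spec <- fit$spec
  CC <- cal_columns(years, spec) - cal_columns(rep(ref, length(years)), spec)
  if (is.null(CC)) stop("the fit has no calendar term")
  nm <- colnames(CC)
  if (!is.null(spec$group) && spec$group_interaction) {
    if (is.null(group_level)) group_level <- fit$group_levels[1]
    nm <- paste0(nm, "_", group_level)
  }
  pos <- match(paste0("q01:", nm), names(fit$theta))
  if (any(is.na(pos))) stop("calendar columns not found in fit")
  G <- matrix(0, length(years), length(fit$theta))
  G[, pos] <- CC
  G
}

#' Incidence rate ratio curve from the multistate fit
#'
#' IRR of the dementia-onset intensity at each calendar year versus a
#' reference year, at fixed age and sex (the proportional model makes the
#' ratio covariate-free): `IRR(y) = exp(f(y) - f(ref))` with delta-method
#' CIs from the observed-information covariance.
#'
#' @param fit an [fit_msm()] object.
#' @param years calendar years.
#' @param ref reference year (default 2002).
#' @param level confidence level.
#' @param group_level for group-interaction fits, which subgroup's trend.
#' @return data.frame: year, irr, lo, hi.
#' @export
irr_curve <- function(fit, years, ref = 2002, level = 0.95,
                      group_level = NULL) {
  stopifnot(inherits(fit, "msm_trend"))
  if (fit$spec$calendar == "rcs" &&
      any(years < min(fit$spec$cal_knots) | years > max(fit$spec$cal_knots)))
    warning("years beyond the calendar knot span: linear extrapolation")
  G <- cal_contrast(fit, years, ref, group_level)
  est <- drop(G %*% fit$theta)
  se <- if (is.null(fit$vcov)) rep(NA_real_, length(years)) else
    sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(year = years, irr = exp(est),
             lo = exp(est - z * se), hi = exp(est + z * se))
}

#' Fitted dementia incidence surface
#'
#' Dementia-onset intensity per 1000 person-years evaluated on an
#' age-by-sex-by-year grid.
#'
#' @param fit an [fit_msm()] object.
#' @param ages,years numeric grids; `sexes` 0 (men) and/or 1 (women).
#' @param group_level subgroup level for grouped fits (default reference).
#' @param per rate scale (default 1000).
#' @return data.frame: age, female, year, rate.
#' @export
incidence_surface <- function(fit, ages, sexes = c(0, 1), years, per = 1000,
                              group_level = NULL) {
  stopifnot(inherits(fit, "msm_trend"))
  g <- expand.grid(age = ages, female = sexes, year = years)
  if (!is.null(fit$spec$group)) {
    if (is.null(group_level)) group_level <- fit$group_levels[1]
    g$group <- group_level
  }
  X <- design_q01(g, fit$spec, fit$group_levels)
  b <- fit$theta[fit$par_index$q01]
  g$rate <- exp(drop(X %*% b)) * per
  g
}

#' Subgroup calendar-trend interaction test
#'
#' Fits the multistate model with a common calendar trend (plus subgroup
#' main effects on the onset intensity) and with subgroup-specific calendar
#' trends, and reports the likelihood-ratio test of the calendar-by-subgroup
#' interaction.
#'
#' @param panel a `panel_dataset` or panel data.frame.
#' @param status a `dementia_status`.
#' @param by `"education"`, `"sex"` or `"agegrp"` (entry age under/over 75).
#' @param spec base [msm_spec()]; its calendar form is kept.
#' @param ... passed to [fit_msm()].
#' @return list: statistic, df, p_value, fit_common, fit_interaction.
#' @export
subgroup_trend_test <- function(panel, status, by = "education",
                                spec = msm_spec(), ...) {
  sp0 <- spec; sp0$group <- by; sp0$group_interaction <- FALSE
  sp1 <- sp0; sp1$group_interaction <- TRUE
  f0 <- fit_msm(panel, status, sp0, hessian = FALSE, ...)
  ## single-level subgroup: interaction not estimable
  if (length(f0$group_levels) < 2L)
    stop("subgroup variable has a single level")
  f1 <- fit_msm(panel, status, sp1, hessian = FALSE, ...)
  t <- lrt(f0, f1)
  c(t, list(fit_common = f0, fit_interaction = f1))
}
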