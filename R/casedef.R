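#' Case-definition configuration
#'
#' Thresholds and rules of the algorithmic dementia case definition:
#' dementia at a wave is the coexistence of cognitive impairment (two or more
#' cognitive domains at or below an education-stratified threshold of
#' `sd_multiplier` SD below the reference mean, or an informant IQCODE-type
#' score strictly above `proxy_cutoff`) and functional impairment
#' (`min_adl` or more ADL dependencies), or a reported doctor's diagnosis.
#' A cognitive-impairment flag is rescinded as transient decline when the
#' consecutive wave improves by `improvement_sd` reference SDs or more.
#'
#' @param sd_multiplier threshold depth in reference SDs (default 1.5).
#' @param min_impaired_domains minimum impaired domains (default 2).
#' @param improvement_sd transient-decline reversal threshold in SD units
#'   (default 1).
#' @param proxy_cutoff informant-score threshold, strict inequality
#'   (default 3.6).
#' @param min_adl ADL-dependency count defining functional impairment
#'   (default 1).
#' @param reference_age_window ages defining the threshold reference
#'   population (default c(50, 80)).
#' @param include_doctor_diagnosis if `FALSE`, the algorithmic-only
#'   sensitivity variant (doctor reports ignored).
#' @param dx_persist doctor-diagnosis reports persist to later waves
#'   (absorbing; default `TRUE`).
#' @return object of class `"casedef_config"`.
#' @export
casedef_config <- function(sd_multiplier = 1.5, min_impaired_domains = 2L,
                           improvement_sd = 1, proxy_cutoff = 3.6,
                           min_adl = 1L, reference_age_window = c(50, 80),
                           include_doctor_diagnosis = TRUE,
                           dx_persist = TRUE) {
  stopifnot(sd_multiplier > 0, min_impaired_domains >= 1,
            diff(reference_age_window) > 0)
  structure(list(sd_multiplier = sd_multiplier,
                 min_impaired_domains = as.integer(min_impaired_domains),
                 improvement_sd = improvement_sd, proxy_cutoff = proxy_cutoff,
                 min_adl = as.integer(min_adl),
                 reference_age_window = reference_age_window,
                 include_doctor_diagnosis = include_doctor_diagnosis,
                 dx_persist = dx_persist),
            class = "casedef_config")
}

domain_cols <- function(panel) grep("^d[0-9]+$", names(panel), value = TRUE)

#' Education-stratified cognitive impairment thresholds
#'
#' For each cognitive domain and education stratum, the impairment threshold
#' is `mean - sd_multiplier * SD` of the scores among person-waves of the
#' reference population: ages within `reference_age_window` (default 50-80),
#' pooled over waves.
#'
#' @param panel person-wave data.frame with `age`, `education` and domain
#'   score columns `d1..dK`.
#' @param cfg a [casedef_config()].
#' @return data.frame with columns domain, education, mean, sd, threshold.
#' @export
domain_thresholds <- function(panel, cfg = casedef_config()) {
  dc <- domain_cols(panel)
  if (!length(dc)) stop("no domain score columns (d1..dK) in panel")
  w <- panel$age >= cfg$reference_age_window[1] &
       panel$age <= cfg$reference_age_window[2]
  ref <- panel[w, , drop = FALSE]
  out <- expand.grid(domain = dc, education = unique(panel$education),
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    x <- ref[ref$education == out$education[r], out$domain[r]]
    x <- x[!is.na(x)]
    if (length(x) < 2L)
      stop(sprintf("reference stratum (%s, %s) has fewer than 2 scores",
                   out$domain[r], out$education[r]))
    out$mean[r] <- mean(x); out$sd[r] <- stats::sd(x)
  }
  out$threshold <- out$mean - cfg$sd_multiplier * out$sd
  out
}

## per-row matrix of thresholds / means / sds aligned with panel rows
threshold_lookup <- function(panel, thresholds, what = "threshold") {
  dc <- domain_cols(panel)
  sapply(dc, function(d) {
    th <- thresholds[thresholds$domain == d, ]
    th[[what]][match(panel$education, th$education)]
  })
}

#' Flag cognitive impairment per person-wave
#'
#' A wave is flagged when `min_impaired_domains` or more domain scores lie at
#' or below their stratum threshold; missing domains never count as impaired.
#' Waves answered by a proxy informant are flagged when the proxy score is
#' strictly above `proxy_cutoff`. Waves with neither domain scores nor a
#' proxy score get `NA` (unknown), not `FALSE`.
#'
#' @param panel person-wave data.frame (see [simulate_panel()] layout).
#' @param thresholds output of [domain_thresholds()].
#' @param cfg a [casedef_config()].
#' @return logical vector along rows of `panel` (with `NA` for unassessable
#'   waves).
#' @export
flag_cognitive_impairment <- function(panel, thresholds, cfg = casedef_config()) {
  dc <- domain_cols(panel)
  sc <- as.matrix(panel[dc])
  th <- threshold_lookup(panel, thresholds, "threshold")
  imp <- sc <= th
  n_imp <- rowSums(imp, na.rm = TRUE)
  n_obs <- rowSums(!is.na(sc))
  flag <- n_imp >= cfg$min_impaired_domains
  has_proxy <- !is.na(panel$proxy)
  flag[n_obs == 0L & has_proxy] <- panel$proxy[n_obs == 0L & has_proxy] > cfg$proxy_cutoff
  flag[n_obs == 0L & !has_proxy] <- NA
  flag
}

#' Rescind transient cognitive decline
#'
#' A cognitive-impairment flag at wave t is rescinded (marked transient) when
#' the person's consecutive observed wave improves by `improvement_sd`
#' reference-population SDs or more, measured as the mean standardised score
#' change across the domains that were impaired at t. Flags from proxy
#' assessments, and flags at a person's last observed wave, cannot be
#' rescinded.
#'
#' @param flags logical vector from [flag_cognitive_impairment()].
#' @param panel person-wave data.frame, with thresholds computable.
#' @param thresholds output of [domain_thresholds()].
#' @param cfg a [casedef_config()].
#' @return data.frame with logical columns `cognitive` (corrected flag) and
#'   `transient`.
#' @export
apply_transient_rule <- function(flags, panel, thresholds,
                                 cfg = casedef_config()) {
  dc <- domain_cols(panel)
  sc <- as.matrix(panel[dc])
  th <- threshold_lookup(panel, thresholds, "threshold")
  mu <- threshold_lookup(panel, thresholds, "mean")
  sdm <- threshold_lookup(panel, thresholds, "sd")
  z <- (sc - mu) / sdm
  imp <- sc <= th
  ord <- order(panel$id, panel$wave)
  transient <- rep(FALSE, nrow(panel))
  pos <- ord
  idv <- panel$id[pos]
  nxt <- c(pos[-1], NA)
  same <- c(idv[-1] == idv[-length(idv)], FALSE)
  for (k in seq_along(pos)) {
    i <- pos[k]
    if (!isTRUE(flags[i]) || !same[k]) next
    j <- nxt[k]
    which_imp <- which(!is.na(imp[i, ]) & imp[i, ])
    if (!length(which_imp)) next      # proxy-derived flag: no domain scores
    dz <- z[j, which_imp] - z[i, which_imp]
    dz <- dz[!is.na(dz)]
    if (length(dz) && mean(dz) >= cfg$improvement_sd) transient[i] <- TRUE
  }
  data.frame(cognitive = flags & !transient, transient = transient)
}

#' Ascertain dementia wave-by-wave
#'
#' Applies the full algorithmic case definition to a panel: dementia at a
#' wave is (cognitive impairment after the transient-decline correction AND
#' functional impairment) OR a doctor-diagnosis report (unless the
#' algorithmic-only variant is requested). Ascertainment is absorbing: the
#' per-person `first_wave` is the first wave flagged, and `dementia_abs`
#' carries the absorbing status; `dementia` keeps the raw wave-level flag
#' (which may revert, feeding the misclassification layer of the multistate
#' model).
#'
#' @param panel person-wave data.frame; needs `id`, `wave`, `age`,
#'   `education`, domain scores, `proxy`, `adl`, `dx`.
#' @param cfg a [casedef_config()].
#' @param thresholds optional precomputed [domain_thresholds()] table (e.g.
#'   from a designated reference dataset); default computed from `panel`.
#' @return list of class `"dementia_status"`: `status` data.frame (per
#'   person-wave: id, wave, cognitive, transient, functional, proxy_used,
#'   doctor, dementia, dementia_abs) and `first_wave` data.frame (id,
#'   first_wave, `NA` when never ascertained).
#' @export
ascertain_dementia <- function(panel, cfg = casedef_config(),
                               thresholds = NULL) {
  if (inherits(panel, "panel_dataset")) panel <- panel$panel
  if (is.null(thresholds)) thresholds <- domain_thresholds(panel, cfg)
  raw <- flag_cognitive_impairment(panel, thresholds, cfg)
  tc <- apply_transient_rule(raw, panel, thresholds, cfg)
  functional <- panel$adl >= cfg$min_adl
  doctor <- as.logical(panel$dx)
  if (cfg$dx_persist) {
    ord <- order(panel$id, panel$wave)
    doctor[ord] <- as.logical(unlist(tapply(doctor[ord], panel$id[ord], cummax),
                                     use.names = FALSE))
  }
  core <- tc$cognitive & functional
  dementia <- if (cfg$include_doctor_diagnosis) core | doctor else core
  ## missing cognitive status only matters when the doctor path cannot decide
  dementia[is.na(core) & cfg$include_doctor_diagnosis & doctor] <- TRUE

  status <- data.frame(id = panel$id, wave = panel$wave,
                       cognitive = tc$cognitive, transient = tc$transient,
                       functional = functional,
                       proxy_used = !is.na(panel$proxy), doctor = doctor,
                       dementia = dementia)
  ord <- order(status$id, status$wave)
  s <- status[ord, ]
  first <- tapply(ifelse(!is.na(s$dementia) & s$dementia, s$wave, NA_integer_),
                  s$id, function(w) if (all(is.na(w))) NA_integer_ else min(w, na.rm = TRUE))
  fw <- data.frame(id = as.integer(names(first)),
                   first_wave = as.integer(unname(first)))
  ## absorbing status
  status$dementia_abs <- status$dementia
  m <- match(status$id, fw$id)
  has <- !is.na(fw$first_wave[m])
  status$dementia_abs[has & status$wave >= fw$first_wave[m]] <- TRUE
  out <- list(status = status, first_wave = fw, thresholds = thresholds,
              config = cfg)
  class(out) <- "dementia_status"
  out
}

#' @export
print.dementia_status <- function(x, ...) {
  n <- length(unique(x$status$id))
  nc <- sum(!is.na(x$first_wave$first_wave))
  cat("Dementia ascertainment:", n, "participants,", nc, "ever ascertained (",
      sprintf("%.1f%%", 100 * nc / n), ")\n")
  cat("Transient cognitive decline rescinded at",
      sum(x$status$transient, na.rm = TRUE), "person-waves\n")
  invisible(x)
}
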