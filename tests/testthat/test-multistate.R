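test_that("interval transition matrix: identity at dt = 0, two-state closed form, row-stochastic", {
  expect_equal(transition_matrix(0.3, 0.2, 0.5, 0),
               diag(3), ignore_attr = TRUE)
  P <- transition_matrix(1, 0, 0, 1)
  expect_equal(P[1, 1], exp(-1))
  expect_equal(P[1, 2], 1 - exp(-1))
  set.seed(2)
  for (k in 1:20) {
    q <- runif(3, 0, 2); dt <- runif(1, 0, 5)
    P <- transition_matrix(q[1], q[2], q[3], dt)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(P >= 0))
    expect_equal(P[3, ], c(0, 0, 1), ignore_attr = TRUE)  # death absorbing
  }
  expect_error(transition_matrix(-1, 0, 0, 1), "non-negative")
  expect_error(transition_matrix(1, 0, 0, -1), "non-negative")
})

test_that("closed-form interval probabilities equal the matrix exponential, including near-degenerate rates", {
  skip_if_not_installed("Matrix")
  sets <- list(c(0.1, 0.05, 0.3, 2), c(1, 1, 2.0000001, 0.5),
               c(0.015, 0.03, 0.15, 2), c(2, 0.1, 2.1, 3),
               c(0.5, 0.5, 1.0, 1), c(1e-9, 1e-9, 1e-9, 2))
  for (s in sets) {
    Q <- matrix(c(-(s[1] + s[2]), s[1], s[2], 0, -s[3], s[3], 0, 0, 0),
                3, 3, byrow = TRUE)
    E <- as.matrix(Matrix::expm(Q * s[4]))
    P <- transition_matrix(s[1], s[2], s[3], s[4])
    expect_equal(unname(P), unname(E), tolerance = 1e-10)
  }
})

test_that("single-interval hidden-Markov likelihood matches the hand-expanded two-term sum", {
  ## healthy at both waves, dt = 2, with misclassification:
  ## L = P00 (1 - e01) + P01 e10, expanded by hand from the exponentials
  q01 <- 0.2; q02 <- 0.1; q12 <- 0.4; dt <- 2; e01 <- 0.02; e10 <- 0.1
  a <- q01 + q02
  P00 <- exp(-a * dt)
  P01 <- q01 * (exp(-a * dt) - exp(-q12 * dt)) / (q12 - a)
  hand <- log(P00 * (1 - e01) + P01 * e10)
  got <- msm_subject_loglik(c(0, 2), c(0, 0), q01, q02, q12,
                            eps01 = e01, eps10 = e10)
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("an apparent recovery has positive likelihood only with misclassification", {
  t <- c(0, 2, 4); s <- c(0, 1, 0)
  q <- rep(0.2, 2)
  expect_equal(msm_subject_loglik(t, s, q, q, q, eps01 = 0, eps10 = 0), -Inf)
  expect_gt(msm_subject_loglik(t, s, q, q, q, eps01 = 0, eps10 = 0.05), -Inf)
  expect_error(msm_subject_loglik(c(0, 2), c(0, 0), q, q, q, death_time = 1.5),
               "death")
})

test_that("with emissions fixed at zero the engine reduces to the interval-censored Markov likelihood (independent implementation)", {
  skip_if_not_installed("Matrix")
  set.seed(6)
  ## small simulated panel with exact deaths
  n <- 60
  waves <- seq(2002.5, 2010.5, 2)
  q01 <- 0.1; q02 <- 0.05; q12 <- 0.3
  t0 <- rexp(n, q01 + q02); dem <- runif(n) < q01 / (q01 + q02)
  onset <- ifelse(dem, t0, Inf) + 2002.5
  death <- ifelse(dem, t0 + rexp(n, q12), t0) + 2002.5
  rows <- do.call(rbind, lapply(seq_along(waves), function(w) {
    alive <- death > waves[w]
    data.frame(id = which(alive), wave = w, date = waves[w],
               state = as.integer(onset[alive] <= waves[w]))
  }))
  panel <- make_panel(rows$id, rows$wave, rows$date, rows$state)
  st <- make_status(rows$id, rows$wave, rows$state)
  deaths <- data.frame(id = which(death <= max(waves)),
                       death_date = death[death <= max(waves)])
  sp <- msm_spec(age = "none", calendar = "none", sex = FALSE,
                 emission = "none")
  theta <- log(c(0.12, 0.06, 0.25))
  got <- msm_loglik(theta, panel, st, sp, deaths = deaths,
                    status_col = "dementia_abs")
  ## independent per-subject implementation via the matrix exponential
  Q <- matrix(c(-sum(exp(theta[1:2])), exp(theta[1]), exp(theta[2]),
                0, -exp(theta[3]), exp(theta[3]), 0, 0, 0), 3, 3, byrow = TRUE)
  ll <- 0
  for (i in unique(panel$id)) {
    d <- panel[panel$id == i, ]
    f <- if (d$state[1] == 0) c(1, 0, 0) else c(0, 1, 0)
    if (nrow(d) > 1) for (k in 2:nrow(d)) {
      P <- as.matrix(Matrix::expm(Q * (d$date[k] - d$date[k - 1])))
      f <- drop(f %*% P)
      f[3] <- 0                                   # observed alive
      obs <- d$state[k] + 1
      f[-obs][f[-obs] != 0] <- 0                  # observed without error
    }
    dd <- deaths$death_date[deaths$id == i]
    if (length(dd)) {
      P <- as.matrix(Matrix::expm(Q * (dd - max(d$date))))
      f <- drop(f %*% P)
      ll <- ll + log(f[1] * exp(theta[2]) + f[2] * exp(theta[3]))
    } else ll <- ll + log(sum(f[1:2]))
  }
  expect_equal(got, ll, tolerance = 1e-8)
})

test_that("likelihood-ratio machinery: zero for identical models, correct df, config check", {
  pd <- clean_panel(); st <- clean_status()
  f1 <- clean_msm_fit()
  t0 <- lrt_same <- tryCatch(lrt(f1, f1), error = function(e) e)
  expect_s3_class(lrt_same, "error")   # same dimension: not nested
  sp_lin <- msm_spec(calendar = "linear", emission = "none",
                     cal_eval = "midpoint")
  f_lin <- fit_msm(pd, st, sp_lin, status_col = "dementia_abs",
                   hessian = FALSE)
  t <- lrt(f_lin, f1)
  expect_equal(t$df, 1)
  expect_gte(t$statistic, 0)
  expect_true(t$p_value >= 0 && t$p_value <= 1)
})

test_that("freeing the age spline on a log-linear-age truth does not spuriously reject", {
  pd <- clean_panel(); st <- clean_status()
  sp_rcs <- msm_spec(age = "rcs", calendar = "piecewise", emission = "none",
                     cal_eval = "midpoint")
  f_rcs <- fit_msm(pd, st, sp_rcs, status_col = "dementia_abs",
                   hessian = FALSE)
  t <- lrt(clean_msm_fit(), f_rcs)
  expect_equal(t$df, 1)   # a 3-knot spline adds one nonlinear age column
  expect_gt(t$p_value, 0.005)
})

test_that("freeing emissions never lowers the likelihood; estimated emissions shrink to the boundary on clean data", {
  pd <- clean_panel(); st <- clean_status()
  f0 <- clean_msm_fit()
  sp_e <- msm_spec(calendar = "piecewise", emission = "both",
                   cal_eval = "midpoint")
  fe <- fit_msm(pd, st, sp_e, status_col = "dementia_abs", hessian = FALSE)
  ## the true optimum sits on the open boundary (logit -> -Inf); the freed
  ## fit may sit a hair below the constrained one, by at most ~N * eps
  expect_gte(fe$logLik, f0$logLik - 0.05)
  eps <- plogis(coef(fe)[c("logit_e01", "logit_e10")])
  expect_lt(max(eps), 0.001)
})

test_that("irr_curve is exactly 1 at the reference and the incidence surface behaves", {
  fit <- clean_msm_fit()
  cv <- irr_curve(fit, c(2002, 2008, 2016), ref = 2002)
  expect_equal(cv$irr[1], 1)
  expect_equal(cv$lo[1], 1)
  surf <- incidence_surface(fit, ages = c(70, 80, 90), years = c(2002, 2016))
  expect_true(all(surf$rate > 0))
  ## zeroing the age coefficient flattens the surface in age
  fit0 <- fit
  fit0$theta["q01:age"] <- 0
  s0 <- incidence_surface(fit0, ages = c(70, 80, 90), sexes = 0, years = 2002)
  expect_equal(length(unique(round(s0$rate, 10))), 1L)
  ## Gompertz-like age slope recovered within its CI
  b <- coef(fit)["q01:age"]
  se <- sqrt(vcov(fit)["q01:age", "q01:age"])
  expect_lt(abs(b - 0.11) / se, 3)
})

test_that("subgroup trend machinery: single-level groups error; divergent education trends are detected and ordered", {
  pd1 <- shared_panel()
  men <- pd1$panel[pd1$panel$female == 0, ]
  stm <- ascertain_dementia(men)
  expect_error(subgroup_trend_test(men, stm, by = "sex",
                                   spec = msm_spec(calendar = "piecewise",
                                                   emission = "none")),
               "single level")
  ## education-specific post-break slopes: low rises, high keeps declining
  cfg <- cohort_config(n_core = 4000, refresh_waves = no_refresh(),
                       trend_spec = list(ref_year = 2002, break_year = 2008,
                                         slope_pre = log(0.95),
                                         slope_post = c(low = log(1.08),
                                                        middle = 0,
                                                        high = log(0.93))),
                       measurement_spec = noiseless_measurement(), seed = 77)
  pd <- simulate_panel(cfg)
  st <- ascertain_dementia(pd)
  res <- subgroup_trend_test(pd, st, by = "education",
                             spec = msm_spec(calendar = "piecewise",
                                             emission = "none",
                                             cal_eval = "midpoint"),
                             status_col = "dementia_abs")
  expect_equal(res$df, 4L)   # 2 calendar columns x (3 - 1) levels
  expect_lt(res$p_value, 0.05)
  ## the low-education IRR rises faster after the break than high
  irr_low <- irr_curve(res$fit_interaction, 2016, ref = 2008,
                       group_level = "low")$irr
  irr_high <- irr_curve(res$fit_interaction, 2016, ref = 2008,
                        group_level = "high")$irr
  expect_gt(irr_low, irr_high)
})
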