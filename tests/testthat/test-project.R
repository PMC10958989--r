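proj_mort <- function() memo("proj_mort", {
  s <- simulate_mortality_surface(35:100, 2001:2018,
                                  baseline_spec = list(exposure = 1e5), seed = 3)
  forecast_mortality(s, "pspline", lambda = c(10, 10))
})

small_ages <- 60:70
small_years <- 2011:2026

small_trans <- function(scen = scenario_spec("constant")) {
  build_transition_array(proj_mort(), scen, ages = small_ages,
                         years = small_years[-length(small_years)])
}

small_init <- function() initial_state_grid(ages = small_ages,
                                            base_count = 1e4)

test_that("the state space partitions into 8 alive states plus two absorbing death states", {
  hs <- health_states()
  expect_equal(nrow(hs), 10L)
  expect_equal(dementia_states(), c(4L, 8L))
  al <- hs[!is.na(hs$cvd), ]
  expect_equal(nrow(unique(al[c("cvd", "ci", "fi")])), 8L)
})

test_that("transition matrices are row-stochastic with no recovery and absorbing deaths", {
  A <- small_trans(scenario_spec("upward"))
  hs <- health_states(); al <- hs[!is.na(hs$cvd), ]
  for (k in 1:25) {
    set.seed(k)
    ia <- sample(length(small_ages), 1); sx <- sample(2, 1)
    iy <- sample(dim(A)[5], 1)
    P <- A[, , ia, sx, iy]
    expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(P >= 0))
    expect_equal(P[9, 9], 1); expect_equal(P[10, 10], 1)
    ## no recovery: a target state may never lack an attribute the source has
    for (s in al$state) for (s2 in al$state) {
      if (al$cvd[s2] < al$cvd[s] || al$ci[s2] < al$ci[s] || al$fi[s2] < al$fi[s])
        expect_equal(P[s, s2], 0)
    }
  }
})

test_that("the incidence scenario rescales dementia-entry probabilities on the rate scale", {
  A0 <- small_trans(scenario_spec("constant"))
  A1 <- small_trans(scenario_spec("upward"))
  expect_equal(A1[, , , , "2018"], A0[, , , , "2018"])   # before compounding
  ## 2019: one year of compounding, multiplier 1.028 on the rate scale
  ## (source -> dementia-state pairs respect the no-CVD-reversal zeros)
  for (pair in list(c(1, 4), c(3, 4), c(5, 8), c(7, 8))) {
    p0 <- A0[pair[1], pair[2], 3, 1, "2019"]
    p1 <- A1[pair[1], pair[2], 3, 1, "2019"]
    expect_equal(-log(1 - p1), 1.028 * (-log(1 - p0)), tolerance = 1e-9)
  }
  ## cumulative factor at the horizon equals the independently compounded power
  mcum <- 1
  for (k in 1:7) mcum <- mcum * 1.028    # 2025 is 7 years past 2018
  p0 <- A0[1, 4, 3, 1, "2025"]; p1 <- A1[1, 4, 3, 1, "2025"]
  expect_equal(-log(1 - p1), mcum * (-log(1 - p0)), tolerance = 1e-9)
  ## a too-large multiplier is rejected rather than silently renormalised
  expect_error(small_trans(scenario_spec(300)), "multiplier")
})

test_that("identity transitions conserve and age the population; all-death matrices extinguish it", {
  n_age <- length(small_ages); n_yr <- length(small_years)
  I10 <- array(0, dim = c(10, 10, n_age, 2, n_yr - 1))
  for (s in 1:10) I10[s, s, , , ] <- 1
  dimnames(I10)[[5]] <- head(small_years, -1)
  dimnames(I10)[[1]] <- health_states()$label
  init <- small_init()
  pr <- run_projection(init, I10, entrants = 0, years = small_years)
  ## conservation: total mass constant, everyone just ages
  expect_equal(sum(pr$grid[, , , n_yr]), sum(init), tolerance = 1e-9)
  D10 <- I10 * 0
  D10[, 10, , , ] <- 1; D10[9, 9, , , ] <- 1; D10[9, 10, , , ] <- 0
  D10[10, 10, , , ] <- 1
  pr2 <- run_projection(init, D10, entrants = 1000, years = small_years)
  alive2 <- sum(pr2$grid[, , 1:8, 2])
  expect_equal(alive2, 2 * 1000)   # only the new entrants are alive
})

test_that("each cycle conserves mass: alive plus new deaths equals previous alive", {
  A <- small_trans()
  pr <- run_projection(small_init(), A, entrants = 0, years = small_years)
  g <- pr$grid
  for (t in 1:(dim(g)[4] - 1)) {
    alive_t <- sum(g[, , 1:8, t])
    alive_t1 <- sum(g[, , 1:8, t + 1])
    new_dead <- sum(g[, , 9:10, t + 1]) - sum(g[, , 9:10, t])
    expect_equal((alive_t1 + new_dead) / alive_t, 1, tolerance = 1e-9)
  }
})

test_that("larger incidence multipliers never produce fewer dementia cases", {
  init <- small_init()
  dc <- lapply(c(downward = "downward", constant = "constant",
                 upward = "upward"),
               function(s) dementia_counts(run_projection(init,
                 small_trans(scenario_spec(s)), entrants = 0,
                 years = small_years)))
  post <- as.character(2019:2026)
  expect_true(all(dc$upward[post] >= dc$constant[post]))
  expect_true(all(dc$constant[post] >= dc$downward[post]))
  expect_gt(dc$upward["2026"], dc$downward["2026"])
})

test_that("lower projected mortality yields at least as many dementia cases at the horizon", {
  s <- simulate_mortality_surface(35:100, 2001:2018,
                                  baseline_spec = list(exposure = 1e5,
                                                       year_slope = -0.02),
                                  seed = 3)
  init <- small_init()
  run_with <- function(mf) {
    tr <- build_transition_array(mf, scenario_spec("constant"),
                                 ages = small_ages,
                                 years = head(small_years, -1))
    dementia_counts(run_projection(init, tr, entrants = 0,
                                   years = small_years))
  }
  optimistic <- run_with(forecast_mortality(s, "loglinear"))
  conservative <- run_with(forecast_mortality(s, "constant"))
  expect_gte(optimistic[length(optimistic)], conservative[length(conservative)])
})

test_that("scenario reports ratio correctly and uncertainty widens with horizon", {
  init <- small_init()
  p1 <- run_projection(init, small_trans(scenario_spec("constant")),
                       entrants = 0, years = small_years)
  rep1 <- scenario_report(list(a = p1, b = p1))
  expect_true(all(rep1$ratio_vs_first == 1))
  p_short <- p1; p_short$years <- p1$years + 1
  expect_error(scenario_report(list(p1, p_short)), "year grids")
  ps <- project_scenario(proj_mort(), scenario_spec("upward"),
                         init = init, ages = small_ages, years = small_years,
                         entrants = 0, n_draws = 12, log_mult_se = 0.012,
                         seed = 9)
  dr <- ps$draws
  width <- function(j) diff(quantile(dr[, j], c(0.025, 0.975)))
  j25 <- match(2025, small_years); jend <- length(small_years)
  expect_gt(width(jend), width(j25))
})
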