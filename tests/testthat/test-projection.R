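# Small projection problems: short horizons and a reduced cohort window keep
# each run around a second.
proj_lt <- make_synthetic_lifetable(years = 1910:2030)
proj_cs <- make_cohort_sizes(1912:2010)

test_that("scenario specification validates and scales intensities exactly", {
  expect_error(scenario_spec(delta = 1.2), "negative rates")
  expect_error(scenario_spec(gamma = -0.1), "gamma")
  Q <- build_intensity_matrix(default_params(), covariate_profile("F", 40, 2010))
  sc <- scenario_spec(0.22, 0.33, start_year = 2022)
  # before the start year: untouched
  expect_equal(apply_scenario(Q, sc, 2020), Q)
  Qs <- apply_scenario(Q, sc, 2025)
  up <- cbind(c(1:4, 6:9), c(2:5, 7:10))
  down <- cbind(c(2:5, 7:10), c(1:4, 6:9))
  expect_equal(Qs[up], 0.78 * Q[up], tolerance = 1e-12)
  expect_equal(Qs[down], 1.33 * Q[down], tolerance = 1e-12)
  # diabetes-onset entries untouched, rows still sum to zero
  expect_equal(Qs[cbind(1:5, 6:10)], Q[cbind(1:5, 6:10)])
  expect_lt(max(abs(rowSums(Qs))), 1e-12)
  # boundary: delta = 1 removes all move-up flow
  Q1 <- apply_scenario(Q, scenario_spec(1, 0, 2022), 2025)
  expect_true(all(Q1[up] == 0))
})

test_that("one-year cohort step reproduces the scalar closed form", {
  p <- toy_params(nw_ow = 0.05)
  lt0 <- zero_mortality_lifetable(1990:2030)
  tr <- project_cohort(p, "M", 2000, lt0, end_year = 2010)
  # after the first year (age 3 -> 4): OW share = 1 - exp(-0.05)
  expect_equal(tr$OW[tr$age == 4], 1 - exp(-0.05), tolerance = 1e-10)
  expect_equal(tr$dead[nrow(tr)], 0)
})

test_that("cohort mass is conserved across living states and death", {
  tr <- project_cohort(default_params(), "F", 1950, proj_lt,
                       mort_adj = c(1, 1.1, 1.3, 1.5, 2, 2, 2.2, 2.6, 3, 4),
                       end_year = 2027)
  tot <- rowSums(tr[, c(STATE_LABELS, "dead")])
  expect_lt(max(abs(tot - 1)), 1e-10)
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(as.matrix(tr[, STATE_LABELS]) >= 0))
})

test_that("zero intensities and zero mortality give constant prevalences", {
  p <- toy_params()
  lt0 <- zero_mortality_lifetable(1900:2030)
  pr <- project_cohorts(p, lt0, proj_cs, 2022:2025, max_age = 100)
  expect_true(all(pr$NW == 1))
  expect_true(all(pr$obesity == 0))
  expect_equal(length(unique(round(pr$alive))), 1)
})

test_that("projected obesity responds monotonically to both scenario levers", {
  p <- default_params()
  ob_at <- function(delta, gamma) {
    pr <- project_cohorts(p, proj_lt, proj_cs, c(2022, 2026),
                          scenario = scenario_spec(delta, gamma, 2022),
                          max_age = 100)
    pr$obesity[pr$year == 2026]
  }
  by_delta <- c(ob_at(0, 0), ob_at(0.3, 0), ob_at(0.8, 0))
  expect_true(all(diff(by_delta) < 0))
  by_gamma <- c(ob_at(0, 0), ob_at(0, 0.4), ob_at(0, 1.2))
  expect_true(all(diff(by_gamma) < 0))
  # equal levers: reducing move-up beats increasing move-down
  expect_lt(ob_at(0.3, 0), ob_at(0, 0.3))
})

test_that("higher diabetic mortality lowers projected diabetes prevalence", {
  p <- default_params()
  dm_at <- function(hr_dm) {
    adj <- c(rep(1, 5), rep(hr_dm, 5))
    pr <- project_cohorts(p, proj_lt, proj_cs, c(2022, 2025),
                          mort_adj = adj, max_age = 100)
    pr$diabetes[pr$year == 2025]
  }
  expect_gt(dm_at(1), dm_at(2))
  expect_gt(dm_at(2), dm_at(4))
})

test_that("bisection for the required change matches a grid scan", {
  p <- default_params()
  # already-met objective returns zero
  res0 <- find_required_change(p, proj_lt, proj_cs,
                               objective = "relative_reduction",
                               reduction = -10, direction = "up",
                               end_year = 2024, max_age = 100)
  expect_equal(res0$value, 0)
  # unattainable objective reports the boundary, not an error
  resb <- find_required_change(p, proj_lt, proj_cs,
                               objective = "relative_reduction",
                               reduction = 0.9, direction = "up",
                               end_year = 2024, max_age = 100)
  expect_false(resb$achieved)
  expect_equal(resb$value, 1)
  # stabilization: bisection against a coarse grid scan
  res <- find_required_change(p, proj_lt, proj_cs, objective = "stabilize",
                              direction = "up", end_year = 2025,
                              max_age = 100, tol = 5e-4)
  expect_true(res$achieved)
  grid_d <- seq(0, 1, 0.05)
  prev <- vapply(grid_d, function(d) {
    pr <- project_cohorts(p, proj_lt, proj_cs, c(2022, 2025),
                          scenario = scenario_spec(d, 0, 2022), max_age = 100)
    pr$obesity[pr$year == 2025]
  }, 0)
  best <- grid_d[which(prev <= res$target)[1]]
  expect_lt(abs(res$value - best), 0.05 + 1e-9)
  expect_lte(res$prevalence, res$target + 5e-4)
})

test_that("the scenario surface has full shape and is monotone in both levers", {
  p <- default_params()
  g <- scenario_grid(p, proj_lt, proj_cs, deltas = c(0, 0.2, 0.4),
                     gammas = c(0, 0.3), end_year = 2025, max_age = 100)
  expect_equal(nrow(g), 6)
  m <- matrix(g$prevalence[order(g$gamma, g$delta)], nrow = 3)
  expect_true(all(diff(m[, 1]) < 0))       # along delta
  expect_true(all(diff(m[, 2]) < 0))
  expect_true(all(m[, 2] < m[, 1]))        # along gamma
  # both reduction conventions present and consistent at the status quo
  expect_equal(g$reduction_vs_statusquo[g$delta == 0 & g$gamma == 0], 0,
               tolerance = 1e-10)
})
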