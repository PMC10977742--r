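lt_real <- make_synthetic_lifetable(years = 2000:2030)

test_that("without diabetes intensities the lifetime risk is zero", {
  p <- toy_params(nw_ow = 0.05, prog = 0.01, ow_nw = 0.03, regr = 0.05)
  r <- lifetime_risk(p, lt_real, sex = "M", start_state = "NW")
  expect_equal(r$risk, 0)
})

test_that("constrained-BMI, zero-mortality risk equals its closed form", {
  # constant hazard h from the activation age (40) to the horizon (110)
  h <- 0.0009
  p <- toy_params(dm_nw = h)
  lt0 <- zero_mortality_lifetable(2000:2030)
  r <- lifetime_risk(p, lt0, sex = "M", start_age = 25, start_state = "NW",
                     constrain_bmi = TRUE)
  expect_equal(r$risk, 1 - exp(-h * (110 - 40)), tolerance = 1e-10)
  # before activation the curve is exactly flat
  expect_true(all(r$curve$cum_risk[r$curve$age <= 40] == 0))
})

test_that("lifetime risk increases with the starting BMI category", {
  p <- default_params()
  risks <- vapply(BMI_CLASSES, function(s) {
    lifetime_risk(p, lt_real, sex = "F", start_state = s)$risk
  }, 0)
  expect_true(all(diff(risks) > 0))
})

test_that("every intervention scenario lowers the lifetime risk from every start", {
  p <- default_params()
  for (s in c("NW", "OW", "OB2")) {
    base <- lifetime_risk(p, lt_real, sex = "M", start_state = s)$risk
    for (sc in standard_scenarios()[-1]) {
      expect_lt(lifetime_risk(p, lt_real, sex = "M", start_state = s,
                              scenario = sc)$risk, base)
    }
  }
})

test_that("the cumulative-incidence curve is monotone and converges", {
  # horizon past the table's last age (hazards extrapolate) so the living
  # mass is fully absorbed and the curve flattens below 1e-8 per year
  r <- lifetime_risk(default_params(), lt_real, sex = "F", start_state = "OW",
                     horizon_age = 140)
  expect_true(all(diff(r$curve$cum_risk) >= 0))
  tail_change <- diff(utils::tail(r$curve$cum_risk, 3))
  expect_true(all(tail_change < 1e-8))
  expect_true(r$risk >= 0 && r$risk <= 1)
})

test_that("higher mortality lowers lifetime diabetes risk (competing risk)", {
  p <- default_params()
  r1 <- lifetime_risk(p, lt_real, sex = "M", start_state = "OW")$risk
  r2 <- lifetime_risk(p, lt_real, mort_adj = rep(c(1, 3), c(1, 9)),
                      sex = "M", start_state = "OW")$risk
  expect_gt(r1, r2)
})

test_that("population lifetime risk is the exact mixture of component risks", {
  p <- default_params()
  # degenerate distribution equals the single-state risk
  d <- c(NW = 1, OW = 0, OB1 = 0, OB2 = 0, OB3 = 0)
  expect_equal(as.numeric(population_lifetime_risk(p, lt_real, sex = "M",
                                                   start_dist = d)),
               lifetime_risk(p, lt_real, sex = "M", start_state = "NW")$risk,
               tolerance = 1e-12)
  # reference mixture: equals the hand-computed weighted sum and lies
  # between the component extremes
  w <- reference_start_distribution("M")
  pop <- population_lifetime_risk(p, lt_real, sex = "M", start_dist = w)
  comp <- attr(pop, "components")
  expect_equal(as.numeric(pop), sum(w * comp), tolerance = 1e-12)
  expect_gt(as.numeric(pop), min(comp))
  expect_lt(as.numeric(pop), max(comp))
  # malformed inputs
  expect_error(population_lifetime_risk(p, lt_real, sex = "M",
                                        start_dist = d * 2), "sum to 1")
  expect_error(lifetime_risk(default_params(), lt_real, sex = "M",
                             start_state = "NW_D"), "non-diabetic")
})
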