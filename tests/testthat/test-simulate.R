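test_that("with all intensities zero the trajectory never leaves normal weight", {
  set.seed(51)
  tr <- simulate_trajectory(toy_params(), "F", 1950, 90)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$state, 1L)
})

test_that("single-rate exponential holding time matches its closed form", {
  a <- 0.048
  p <- toy_params(nw_ow = a)
  set.seed(52)
  # born 1930, observed at 60: ages 50-60 form one segment but with all HRs 1
  # every segment has the same generator, so P(OW by t) = 1 - exp(-a t)
  arr <- bmidiab:::build_Q_array(p, model_config())
  s <- make_segments(1930, "M", start_age = 50, end_age = 60)
  n <- 20000
  st <- bmidiab:::sim_endpoints_cpp(arr, list(cbind(s$qindex, s$dt)), n, 1L)
  phat <- mean(st == 2L)
  p0 <- 1 - exp(-a * 10)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(phat - p0), 3 * se)
})

test_that("simulated trajectories respect adjacency and never revert diabetes", {
  set.seed(53)
  for (r in 1:60) {
    tr <- simulate_trajectory(default_params(), sample(c("M", "F"), 1),
                              sample(1920:1990, 1), 85)
    st <- tr$state
    if (length(st) > 1) {
      from <- st[-length(st)]; to <- st[-1]
      bmi_from <- (from - 1) %% 5; bmi_to <- (to - 1) %% 5
      dm_from <- from > 5; dm_to <- to > 5
      bmi_step <- dm_from == dm_to & abs(bmi_from - bmi_to) == 1
      onset <- !dm_from & dm_to & bmi_from == bmi_to
      expect_true(all(bmi_step | onset))
      expect_true(all(cumsum(dm_to) >= 0))  # diabetes flag never drops
      expect_true(all(diff(as.integer(c(FALSE, st > 5))) >= 0))
      expect_true(all(diff(tr$age) > 0))
    }
  }
})

test_that("endpoint frequencies match the expm transition probabilities", {
  p <- default_params()
  set.seed(54)
  arr <- bmidiab:::build_Q_array(p, model_config())
  s <- make_segments(1960, "M", end_age = 55)
  n <- 30000
  st <- bmidiab:::sim_endpoints_cpp(arr, list(cbind(s$qindex, s$dt)), n, 1L)
  emp <- tabulate(st, 10) / n
  P <- transition_probability(p, 1960, "M", 3, 55)[1, ]
  se <- sqrt(P * (1 - P) / n)
  expect_true(all(abs(emp - P) < 4 * se + 1e-12))
})

test_that("panel generation is deterministic under a seed and honours n = 0", {
  a <- generate_panel(synthetic_config(n = 500, seed = 99))
  b <- generate_panel(synthetic_config(n = 500, seed = 99))
  expect_identical(a$sex, b$sex)
  expect_identical(a$birth_year, b$birth_year)
  expect_identical(a$bmi_class, b$bmi_class)
  expect_identical(a$diabetes, b$diabetes)
  expect_identical(attr(a, "true_state"), attr(b, "true_state"))
  e <- generate_panel(synthetic_config(n = 0))
  expect_equal(nrow(e), 0)
  expect_named(e, c("person_id", "sex", "birth_year", "survey_year",
                    "bmi_class", "diabetes"))
})

test_that("generated panels look like the survey: waves, ages, prevalence ordering", {
  pan <- generate_panel(synthetic_config(n = 4000, seed = 101))
  age <- pan$survey_year - pan$birth_year
  expect_true(all(pan$survey_year %in% seq(1998, 2014, 2)))
  expect_true(all(age >= 15 & age <= 90))
  st <- attr(pan, "true_state")
  # diabetes only arises through hazards no larger than obesity hazards,
  # so its prevalence must sit below overweight + obesity prevalence
  expect_lt(mean(st > 5), mean((st - 1) %% 5 + 1 >= 2))
})

test_that("synthetic life table behaves like a survival table", {
  lt <- make_synthetic_lifetable()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  m <- lt[lt$sex == "M" & lt$year == 2000, ]
  m <- m[order(m$age), ]
  expect_true(all(diff(m$qx[m$age >= 30]) > 0))
  le_m <- life_expectancy(lt, "M")
  le_f <- life_expectancy(lt, "F")
  expect_gt(le_m, 70); expect_lt(le_m, 90)
  expect_gt(le_f, le_m)
  # alpha = 0: immortal population
  lt0 <- zero_mortality_lifetable()
  expect_true(all(lt0$qx == 0))
  expect_error(make_synthetic_lifetable(alpha = -1), "non-negative")
})

test_that("cohort-size table covers both sexes over the requested years", {
  cs <- make_cohort_sizes(1980:1985, size = 1000, male_share = 0.5)
  expect_equal(nrow(cs), 12)
  expect_equal(sum(cs$n), 6000)
  expect_setequal(unique(cs$sex), c("M", "F"))
})
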