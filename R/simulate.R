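#' Configuration of the synthetic survey-panel generator
#'
#' Defaults emulate the structure of the French biennial health-survey panel:
#' nine waves 1998-2014, respondents aged 15-90 with mean age 44.7 (SD 18.7),
#' 51.5% men, each individual contributing a single observed state at the
#' survey age. A small rate of under-40 normal-weight respondents declaring
#' (non-type-2) diabetes is injected to exercise the reclassification rule in
#' [clean_records()].
#'
#' @param n Number of individuals.
#' @param survey_years Survey waves (default `seq(1998, 2014, 2)`).
#' @param age_range Admissible ages at survey (default 15-90).
#' @param age_mean,age_sd Moments of the (truncated normal, rounded) age
#'   distribution at survey.
#' @param p_male Proportion of men (default 0.515).
#' @param params True generating parameter set (default [default_params()]).
#' @param misdeclared_rate Probability that an under-40 normal-weight
#'   non-diabetic respondent declares diabetes of autoimmune/genetic origin
#'   (default 0.001).
#' @param mortality_thinning Apply survival filtering with `life_table`?
#'   Off by default so that parameter-recovery experiments are unbiased
#'   (estimation ignores mortality, as the survey observes survivors).
#' @param life_table Life table for thinning (see [make_synthetic_lifetable()]).
#' @param seed Integer seed; identical configurations give identical panels.
#' @return A list of class `bmidiab_simconfig`.
#' @export
synthetic_config <- function(n = 10000,
                             survey_years = seq(1998, 2014, 2),
                             age_range = c(15, 90),
                             age_mean = 44.7, age_sd = 18.7,
                             p_male = 0.515,
                             params = default_params(),
                             misdeclared_rate = 0.001,
                             mortality_thinning = FALSE,
                             life_table = NULL,
                             seed = NULL) {
  stopifnot(n >= 0, p_male >= 0, p_male <= 1,
            misdeclared_rate >= 0, misdeclared_rate <= 1,
            age_range[1] <= age_range[2])
  if (mortality_thinning && is.null(life_table)) {
    stop("mortality_thinning requires a life_table")
  }
  structure(list(n = as.integer(n), survey_years = survey_years,
                 age_range = age_range, age_mean = age_mean, age_sd = age_sd,
                 p_male = p_male, params = params,
                 misdeclared_rate = misdeclared_rate,
                 mortality_thinning = mortality_thinning,
                 life_table = life_table, seed = seed),
            class = "bmidiab_simconfig")
}

#' Simulate one health-state trajectory exactly
#'
#' Exact stochastic simulation (competing exponential clocks) of the
#' time-inhomogeneous chain: within each constant-covariate segment the
#' holding time in the current state is exponential with rate `-Q[s,s]` and
#' the destination is drawn proportionally to the off-diagonal intensities.
#' Diabetes never reverts and BMI moves one category at a time.
#'
#' @inheritParams transition_probability
#' @param end_age Final age (>= 3).
#' @return Data frame of events: `age`, `state` (index), `label`; first row
#'   is the origin (age 3, normal weight, non-diabetic). Uses R's RNG.
#' @export
simulate_trajectory <- function(params, sex, birth_year, end_age,
                                config = model_config()) {
  stopifnot(end_age >= config$start_age)
  segs <- make_segments(birth_year, sex, end_age = end_age, config = config)
  arr <- build_Q_array(params, config)
  s <- 1L
  t <- config$start_age
  ages <- t; states <- s
  for (r in seq_len(nrow(segs))) {
    Q <- arr[, , segs$qindex[r]]
    seg_end <- segs$end_age[r]
    repeat {
      lam <- -Q[s, s]
      if (lam <= 0) { t <- seg_end; break }
      w <- stats::rexp(1, lam)
      if (t + w >= seg_end) { t <- seg_end; break }
      t <- t + w
      rates <- Q[s, ]; rates[s] <- 0
      s <- sample.int(10L, 1L, prob = rates)
      ages <- c(ages, t); states <- c(states, s)
    }
  }
  data.frame(age = ages, state = states, label = STATE_LABELS[states],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic survey panel
#'
#' Draws sex, survey wave and age at survey for each individual, then
#' simulates the health-state trajectory from age 3 to the survey age under
#' the true parameters and records the state reached. The returned data frame
#' mimics a raw survey extract (`person_id`, `sex`, `birth_year`,
#' `survey_year`, `bmi_class`, `diabetes` as declared); the simulated true
#' state is attached as attribute `"true_state"`.
#'
#' @param sim A [synthetic_config()].
#' @param config A [model_config()].
#' @return Data frame with `sim$n` rows (class `data.frame`), deterministic
#'   given `sim$seed`.
#' @export
generate_panel <- function(sim = synthetic_config(), config = model_config()) {
  if (!is.null(sim$seed)) set.seed(sim$seed)
  n <- sim$n
  if (n == 0) {
    return(data.frame(person_id = integer(0), sex = character(0),
                      birth_year = integer(0), survey_year = integer(0),
                      bmi_class = character(0), diabetes = integer(0),
                      stringsAsFactors = FALSE))
  }
  sex <- ifelse(stats::runif(n) < sim$p_male, "M", "F")
  survey_year <- sample(sim$survey_years, n, replace = TRUE)
  age <- draw_ages(n, sim)
  birth_year <- as.integer(survey_year - age)
  if (sim$mortality_thinning) {
    keep <- stats::runif(n) < survival_to_age(sim$life_table, sex,
                                              birth_year, age)
    for (it in 1:100) {
      if (all(keep)) break
      idx <- which(!keep)
      sex[idx] <- ifelse(stats::runif(length(idx)) < sim$p_male, "M", "F")
      survey_year[idx] <- sample(sim$survey_years, length(idx), replace = TRUE)
      age[idx] <- draw_ages(length(idx), sim)
      birth_year[idx] <- as.integer(survey_year[idx] - age[idx])
      keep[idx] <- stats::runif(length(idx)) <
        survival_to_age(sim$life_table, sex[idx], birth_year[idx], age[idx])
    }
  }
  # group by observation key and simulate endpoints in compiled code
  key <- paste(sex, birth_year, survey_year, sep = "|")
  ord <- order(key)
  ukey <- unique(key[ord])
  n_per_key <- as.integer(table(factor(key, levels = ukey)))
  parts <- strsplit(ukey, "|", fixed = TRUE)
  seg_list <- lapply(parts, function(p) {
    s <- make_segments(as.integer(p[2]), p[1],
                       end_age = as.integer(p[3]) - as.integer(p[2]),
                       config = config)
    cbind(s$qindex, s$dt)
  })
  arr <- build_Q_array(sim$params, config)
  st_sorted <- sim_endpoints_cpp(arr, seg_list, n_per_key, 1L)
  state <- integer(n)
  state[ord] <- st_sorted
  diabetes <- as.integer(state > 5)
  mis <- state == 1L & age < config$dm_start_nw &
    stats::runif(n) < sim$misdeclared_rate
  declared <- as.integer(diabetes | mis)
  out <- data.frame(person_id = seq_len(n), sex = sex,
                    birth_year = birth_year, survey_year = survey_year,
                    bmi_class = BMI_CLASSES[(state - 1L) %% 5L + 1L],
                    diabetes = declared, stringsAsFactors = FALSE)
  attr(out, "true_state") <- state
  attr(out, "sim_config") <- sim
  out
}

draw_ages <- function(n, sim) {
  out <- integer(n)
  need <- seq_len(n)
  while (length(need)) {
    a <- round(stats::rnorm(length(need), sim$age_mean, sim$age_sd))
    ok <- a >= sim$age_range[1] & a <= sim$age_range[2]
    out[need[ok]] <- as.integer(a[ok])
    need <- need[!ok]
  }
  out
}

#' Synthetic life table with Gompertz mortality
#'
#' Annual death probabilities `qx(age) = 1 - exp(-alpha * exp(beta * age))`,
#' constant across calendar years, with a multiplicative reduction of the
#' hazard level for women. The defaults give a life expectancy at birth
#' around 80 years.
#'
#' @param alpha,beta Gompertz level and shape (both >= 0; `alpha = 0` gives
#'   an immortal population).
#' @param female_factor Multiplier on `alpha` for women (default 0.7).
#' @param years,ages Calendar years and ages covered.
#' @return Data frame `age`, `year`, `sex`, `qx` (class includes
#'   `bmidiab_lifetable`).
#' @export
make_synthetic_lifetable <- function(alpha = 2e-5, beta = 0.095,
                                     female_factor = 0.7,
                                     years = 1895:2030, ages = 0:110) {
  if (alpha < 0 || beta < 0 || female_factor < 0) {
    stop("life-table shape parameters must be non-negative")
  }
  qx_m <- 1 - exp(-alpha * exp(beta * ages))
  qx_f <- 1 - exp(-alpha * female_factor * exp(beta * ages))
  out <- expand.grid(age = ages, year = years, sex = c("M", "F"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$qx <- ifelse(out$sex == "M", qx_m[match(out$age, ages)],
                   qx_f[match(out$age, ages)])
  class(out) <- c("bmidiab_lifetable", "data.frame")
  out
}

# Fast lookup structure: array [age, year, sex].
lifetable_array <- function(lt) {
  ages <- sort(unique(lt$age)); years <- sort(unique(lt$year))
  arr <- array(NA_real_, dim = c(length(ages), length(years), 2),
               dimnames = list(NULL, NULL, c("M", "F")))
  arr[cbind(match(lt$age, ages), match(lt$year, years),
            match(lt$sex, c("M", "F")))] <- lt$qx
  list(arr = arr, ages = ages, years = years)
}

lookup_qx <- function(la, age, year, sex, clamp_year = FALSE) {
  yi <- match(year, la$years)
  if (clamp_year) {
    yi[is.na(yi) & year > max(la$years)] <- length(la$years)
    yi[is.na(yi) & year < min(la$years)] <- 1L
  }
  ai <- match(age, la$ages)
  if (anyNA(ai) || anyNA(yi)) {
    bad <- which(is.na(ai) | is.na(yi))[1]
    stop("life table does not cover age ", age[bad], " in year ", year[bad])
  }
  la$arr[cbind(ai, yi, match(sex, c("M", "F")))]
}

survival_to_age <- function(lt, sex, birth_year, age) {
  la <- lifetable_array(lt)
  vapply(seq_along(sex), function(i) {
    a <- seq_len(age[i]) - 1L
    prod(1 - lookup_qx(la, a, birth_year[i] + a, sex[i], clamp_year = TRUE))
  }, 0)
}

#' Life expectancy implied by a life table
#'
#' Discrete summation of survival: `e0 = sum_k prod_{a<k} (1 - qx(a))`.
#'
#' @param life_table A life table (`age`, `year`, `sex`, `qx`).
#' @param sex `"M"` or `"F"`.
#' @param year Calendar year of the (period) table to use.
#' @return Life expectancy at birth in years.
#' @export
life_expectancy <- function(life_table, sex = "M",
                            year = min(life_table$year)) {
  lt <- life_table[life_table$sex == sex & life_table$year == year, ]
  lt <- lt[order(lt$age), ]
  sum(cumprod(1 - lt$qx))
}

#' Synthetic birth-cohort sizes
#'
#' Constant-size stand-in for national birth-cohort tables.
#'
#' @param years Birth years.
#' @param size Births per year (both sexes combined).
#' @param male_share Share of male births (default 0.512).
#' @return Data frame `year`, `sex`, `n`.
#' @export
make_cohort_sizes <- function(years, size = 800000, male_share = 0.512) {
  stopifnot(size >= 0, male_share >= 0, male_share <= 1)
  data.frame(year = rep(years, 2),
             sex = rep(c("M", "F"), each = length(years)),
             n = rep(c(size * male_share, size * (1 - male_share)),
                     each = length(years)),
             stringsAsFactors = FALSE)
}
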