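#' Lifetime risk of type 2 diabetes under competing mortality
#'
#' Cumulative probability that an individual alive and non-diabetic at
#' `start_age` in `start_year` develops type 2 diabetes before death. The
#' chain is augmented with two absorbing death states (death without / after
#' diabetes); the risk is the terminal mass of the diabetic living states
#' plus death-after-diabetes at the horizon. Calendar-period effects are
#' frozen at the last estimated period for all future years, and mortality
#' beyond the life table's last calendar year is extrapolated at that year's
#' hazards.
#'
#' @inheritParams project_cohort
#' @param start_age Age at the start (default 25).
#' @param start_year Calendar year at the start (default 2022).
#' @param start_state Starting BMI category (a non-diabetic state label among
#'   [BMI_CLASSES]).
#' @param constrain_bmi If `TRUE`, all BMI transitions are zeroed: the
#'   "remaining in normal weight (or their category) all their life"
#'   variant.
#' @param horizon_age Horizon (default 110); the cumulative incidence has
#'   converged well before it with realistic mortality.
#' @return List of class `bmidiab_lifetime`: `risk` (probability), `curve`
#'   (data frame `age`, `cum_risk`, `alive`), and the call settings.
#' @examples
#' lt <- make_synthetic_lifetable()
#' r <- lifetime_risk(default_params(), lt, sex = "M", start_state = "NW")
#' r$risk
#' @export
lifetime_risk <- function(params, life_table, mort_adj = rep(1, 10),
                          sex, start_age = 25, start_year = 2022,
                          start_state = "NW",
                          scenario = scenario_spec(0, 0),
                          constrain_bmi = FALSE, horizon_age = 110,
                          config = model_config()) {
  stopifnot(length(mort_adj) == 10, all(mort_adj > 0))
  if (!start_state %in% BMI_CLASSES) {
    stop("start_state must be a non-diabetic BMI category: ",
         paste(BMI_CLASSES, collapse = ", "))
  }
  stopifnot(start_age >= config$start_age, horizon_age > start_age)
  la <- lifetable_array(life_table)
  stack <- scenario_Q_stack(params, scenario, config)
  nprof <- dim(stack)[3] / 2
  v <- numeric(12)
  v[state_index(start_state)] <- 1
  ages <- start_age:(horizon_age - 1)
  cum <- numeric(length(ages) + 1)
  alive <- numeric(length(ages) + 1)
  alive[1] <- 1
  for (i in seq_along(ages)) {
    a <- ages[i]
    y <- start_year + (a - start_age)
    qx <- lookup_qx(la, min(a, max(la$ages)), y, sex, clamp_year = TRUE)
    h <- -log(1 - qx)
    Q10 <- stack[, , profile_index(sex, a, y, config) +
                     nprof * (y >= scenario$start_year)]
    if (constrain_bmi) {
      Q10[up_entries] <- 0
      Q10[down_entries] <- 0
      diag(Q10) <- 0
      diag(Q10) <- -rowSums(Q10)
    }
    Q12 <- matrix(0, 12, 12)
    Q12[1:10, 1:10] <- Q10
    mu <- h * mort_adj
    Q12[cbind(1:5, rep(11, 5))] <- mu[1:5]
    Q12[cbind(6:10, rep(12, 5))] <- mu[6:10]
    diag(Q12)[1:10] <- diag(Q12)[1:10] - mu
    v <- as.vector(v %*% expm_cpp(Q12))
    cum[i + 1] <- sum(v[6:10]) + v[12]
    alive[i + 1] <- sum(v[1:10])
  }
  structure(list(risk = cum[length(cum)],
                 curve = data.frame(age = c(start_age, ages + 1),
                                    cum_risk = cum, alive = alive),
                 sex = sex, start_age = start_age, start_year = start_year,
                 start_state = start_state, scenario = scenario,
                 constrain_bmi = constrain_bmi),
            class = "bmidiab_lifetime")
}

#' @export
print.bmidiab_lifetime <- function(x, ...) {
  cat(sprintf("Lifetime risk of type 2 diabetes: %.1f%%\n", 100 * x$risk))
  cat(sprintf("  sex %s, from age %d in %d, starting %s%s, scenario %s\n",
              x$sex, x$start_age, x$start_year, x$start_state,
              if (x$constrain_bmi) " (BMI held fixed)" else "",
              x$scenario$name))
  invisible(x)
}

#' Population lifetime risk from a starting BMI-category mixture
#'
#' Mixture of per-category lifetime risks weighted by a starting distribution
#' over BMI categories (e.g. the projected 2022 distribution of 25-year-olds,
#' [reference_start_distribution()]).
#'
#' @inheritParams lifetime_risk
#' @param start_dist Named numeric vector over [BMI_CLASSES] summing to 1
#'   (tolerance 1e-6).
#' @return Scalar risk, with the per-category risks attached as attribute
#'   `"components"`.
#' @export
population_lifetime_risk <- function(params, life_table,
                                     mort_adj = rep(1, 10), sex,
                                     start_dist = reference_start_distribution(sex),
                                     start_age = 25, start_year = 2022,
                                     scenario = scenario_spec(0, 0),
                                     horizon_age = 110,
                                     config = model_config()) {
  if (!all(BMI_CLASSES %in% names(start_dist))) {
    stop("start_dist must be named over the BMI categories")
  }
  start_dist <- start_dist[BMI_CLASSES]
  if (abs(sum(start_dist) - 1) > 1e-6) {
    stop("start_dist must sum to 1 (tolerance 1e-6)")
  }
  comp <- vapply(BMI_CLASSES, function(s) {
    lifetime_risk(params, life_table, mort_adj, sex, start_age, start_year,
                  start_state = s, scenario = scenario,
                  horizon_age = horizon_age, config = config)$risk
  }, 0)
  out <- sum(start_dist * comp)
  attr(out, "components") <- comp
  out
}
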