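#' Intervention scenario specification
#'
#' A scenario modifies the BMI transition intensities from `start_year`
#' onwards: all "move up one BMI category" intensities (NW->OW and the three
#' progressions, in both diabetes layers) are multiplied by `1 - delta`, all
#' "move down" intensities by `1 + gamma`. Diabetes-onset and mortality
#' intensities are untouched. The status quo is `delta = gamma = 0`.
#'
#' @param delta Fractional decrease of move-up intensities, in `[0, 1]`.
#' @param gamma Fractional increase of move-down intensities, `>= 0`.
#' @param start_year First calendar year the modification applies
#'   (default 2022).
#' @param name Optional label.
#' @return List of class `bmidiab_scenario`.
#' @examples
#' standard_scenarios()$scenario1
#' @export
scenario_spec <- function(delta = 0, gamma = 0, start_year = 2022,
                          name = NULL) {
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1] (delta > 1 would give negative rates)")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(delta = delta, gamma = gamma,
                 start_year = as.numeric(start_year),
                 name = if (is.null(name)) sprintf("delta=%g,gamma=%g", delta, gamma) else name),
            class = "bmidiab_scenario")
}

#' The four standard scenarios
#'
#' Status quo, scenario 1 (22% decrease of move-up intensities), scenario 2
#' (33% increase of move-down intensities) and scenario 3 (both), all
#' starting in 2022 -- the configurations used for the published 2022-2027
#' projections.
#'
#' @param start_year First year of intervention (default 2022).
#' @return Named list of [scenario_spec()] objects.
#' @export
standard_scenarios <- function(start_year = 2022) {
  list(status_quo = scenario_spec(0, 0, start_year, "status_quo"),
       scenario1 = scenario_spec(0.22, 0, start_year, "scenario1"),
       scenario2 = scenario_spec(0, 0.33, start_year, "scenario2"),
       scenario3 = scenario_spec(0.22, 0.33, start_year, "scenario3"))
}

up_entries <- cbind(c(1:4, 6:9), c(2:5, 7:10))
down_entries <- cbind(c(2:5, 7:10), c(1:4, 6:9))

scale_scenario_Q <- function(Q, delta, gamma) {
  Q[up_entries] <- Q[up_entries] * (1 - delta)
  Q[down_entries] <- Q[down_entries] * (1 + gamma)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Apply a scenario to an intensity matrix
#'
#' Returns `Q` with move-up intensities scaled by `1 - delta` and move-down
#' intensities by `1 + gamma` if `year >= spec$start_year`, unchanged
#' otherwise. The diagonal is recomputed.
#'
#' @param Q A 10x10 generator as from [build_intensity_matrix()].
#' @param spec A [scenario_spec()].
#' @param year Calendar year the matrix applies to.
#' @return A 10x10 generator.
#' @export
apply_scenario <- function(Q, spec, year) {
  stopifnot(inherits(spec, "bmidiab_scenario"))
  if (year < spec$start_year) return(Q)
  scale_scenario_Q(Q, spec$delta, spec$gamma)
}

# Base and scenario-scaled generator stacks in one array, so a per-year index
# (qindex + nprof * scenario_active) selects the right slice.
scenario_Q_stack <- function(params, scenario, config) {
  base <- build_Q_array(params, config)
  nprof <- dim(base)[3]
  scaled <- base
  for (r in seq_len(nprof)) {
    scaled[, , r] <- scale_scenario_Q(base[, , r], scenario$delta,
                                      scenario$gamma)
  }
  array(c(base, scaled), dim = c(10, 10, 2 * nprof))
}

#' Project one birth cohort through states and death
#'
#' Advances the cohort's state distribution in annual steps from the origin
#' age with an 11-state generator: the 10 living states plus absorbing death,
#' with death intensity `-log(1 - qx) * HR(state)` added to every living
#' state. Scenario factors apply to BMI intensities from the scenario's start
#' year.
#'
#' @inheritParams transition_probability
#' @param life_table Life table covering all needed (age, year) cells.
#' @param mort_adj Mortality hazard ratios versus normal weight without
#'   diabetes for the 10 living states (default all 1; the first entry must
#'   be 1).
#' @param end_year Last calendar year projected.
#' @param scenario A [scenario_spec()].
#' @param max_age Oldest age simulated (default 110).
#' @return Data frame: `year`, `age`, ten living-state share columns and
#'   `dead` (cumulative); shares sum to 1 with `dead` included.
#' @export
project_cohort <- function(params, sex, birth_year, life_table,
                           mort_adj = rep(1, 10), end_year,
                           scenario = scenario_spec(0, 0),
                           config = model_config(), max_age = 110) {
  stopifnot(length(mort_adj) == 10, all(mort_adj > 0), mort_adj[1] == 1)
  a0 <- config$start_age
  A <- min(end_year - birth_year, max_age)
  stopifnot(A >= a0)
  ages <- a0:(A - 1)
  years <- birth_year + ages
  la <- lifetable_array(life_table)
  qx <- lookup_qx(la, ages, years, rep(sex, length(ages)))
  h <- -log(1 - qx)
  stack <- scenario_Q_stack(params, scenario, config)
  nprof <- dim(stack)[3] / 2
  idx <- profile_index(sex, ages, years, config) +
    nprof * (years >= scenario$start_year)
  res <- project_cohort_cpp(stack[, , idx, drop = FALSE], h, mort_adj)
  out <- data.frame(year = birth_year + c(a0, ages + 1),
                    age = c(a0, ages + 1))
  st <- as.data.frame(res)
  names(st) <- c(STATE_LABELS, "dead")
  cbind(out, st)
}

#' Population prevalence projection over birth cohorts
#'
#' Simulates every birth cohort needed to cover the requested calendar years
#' (all cohorts aged between `min_age` and `max_age` in those years), weights
#' them by cohort size, and aggregates BMI-category and type 2 diabetes
#' prevalence among the living.
#'
#' @inheritParams project_cohort
#' @param cohort_sizes Data frame `year`, `sex`, `n` of birth-cohort sizes
#'   covering all needed birth years.
#' @param years Calendar years to report.
#' @param min_age Youngest age included in the prevalence denominator
#'   (default 18, i.e. the adult population).
#' @param by_sex Also return per-sex rows?
#' @return Data frame with columns `year`, `sex` (`"all"` and, if requested,
#'   `"M"`/`"F"`), the five BMI-category shares among the living (summing to
#'   1), `obesity` (classes I-III combined), `diabetes`, and `alive` (the
#'   weighted living population).
#' @export
project_cohorts <- function(params, life_table, cohort_sizes, years,
                            scenario = scenario_spec(0, 0),
                            mort_adj = rep(1, 10),
                            config = model_config(),
                            min_age = 18, max_age = 110, by_sex = FALSE) {
  births <- (min(years) - max_age):(max(years) - min_age)
  need <- setdiff(births, unique(cohort_sizes$year))
  if (length(need)) {
    stop("cohort_sizes must cover birth years ", min(births), "-",
         max(births), "; missing: ", paste(utils::head(need, 5), collapse = ", "))
  }
  acc <- array(0, dim = c(length(years), 2, 11),
               dimnames = list(years, c("M", "F"), c(STATE_LABELS, "dead")))
  for (sx in c("M", "F")) {
    for (by in births) {
      w <- cohort_sizes$n[cohort_sizes$year == by & cohort_sizes$sex == sx]
      if (length(w) != 1 || w == 0) next
      traj <- project_cohort(params, sx, by, life_table, mort_adj,
                             end_year = max(years), scenario = scenario,
                             config = config, max_age = max_age)
      sel <- traj$year %in% years & traj$age >= min_age & traj$age <= max_age
      if (!any(sel)) next
      yi <- match(traj$year[sel], years)
      si <- match(sx, c("M", "F"))
      acc[yi, si, ] <- acc[yi, si, ] +
        w * as.matrix(traj[sel, c(STATE_LABELS, "dead")])
    }
  }
  summarise <- function(m, sexlab) {
    living <- m[, 1:10, drop = FALSE]
    alive <- rowSums(living)
    share <- living / alive
    data.frame(year = years, sex = sexlab,
               NW = share[, 1] + share[, 6], OW = share[, 2] + share[, 7],
               OB1 = share[, 3] + share[, 8], OB2 = share[, 4] + share[, 9],
               OB3 = share[, 5] + share[, 10],
               obesity = rowSums(share[, c(3:5, 8:10), drop = FALSE]),
               diabetes = rowSums(share[, 6:10, drop = FALSE]),
               alive = alive, row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- summarise(acc[, 1, , drop = TRUE] + acc[, 2, , drop = TRUE], "all")
  if (by_sex) {
    out <- rbind(out, summarise(acc[, 1, , drop = TRUE], "M"),
                 summarise(acc[, 2, , drop = TRUE], "F"))
  }
  out
}

#' Required intensity change to meet an obesity objective
#'
#' Searches, by bisection on the monotone map from the scenario lever to
#' projected obesity prevalence at `end_year`, for the smallest move-up
#' decrease `delta` (direction `"up"`) or move-down increase `gamma`
#' (direction `"down"`) that attains the objective: either stabilising
#' overall obesity at its `base_year` status-quo level, or a relative
#' reduction `reduction` below that level.
#'
#' @inheritParams project_cohorts
#' @param objective `"stabilize"` or `"relative_reduction"`.
#' @param reduction Target relative reduction (e.g. 0.15) when
#'   `objective = "relative_reduction"`.
#' @param direction `"up"` (search on delta) or `"down"` (search on gamma).
#' @param base_year,end_year Years defining the objective (defaults 2022 and
#'   2027).
#' @param start_year Intervention start (default 2022).
#' @param upper Upper search bound for the lever (1 for `"up"`; default 3
#'   for `"down"`).
#' @param tol Tolerance on prevalence (default 1e-3, i.e. 0.1 percentage
#'   point).
#' @return List: `value` (the lever), `direction`, `achieved` (logical;
#'   `FALSE` means the bound was hit and `value` is the boundary),
#'   `prevalence` (attained at `end_year`), `target`, `base_prevalence`.
#' @export
find_required_change <- function(params, life_table, cohort_sizes,
                                 objective = c("stabilize", "relative_reduction"),
                                 reduction = 0.15,
                                 direction = c("up", "down"),
                                 base_year = 2022, end_year = 2027,
                                 start_year = 2022, upper = NULL,
                                 mort_adj = rep(1, 10),
                                 config = model_config(),
                                 min_age = 18, max_age = 110, tol = 1e-3) {
  objective <- match.arg(objective)
  direction <- match.arg(direction)
  if (is.null(upper)) upper <- if (direction == "up") 1 else 3
  years <- base_year:end_year
  prev_at <- function(x) {
    sc <- if (direction == "up") scenario_spec(x, 0, start_year)
          else scenario_spec(0, x, start_year)
    pr <- project_cohorts(params, life_table, cohort_sizes, years,
                          scenario = sc, mort_adj = mort_adj, config = config,
                          min_age = min_age, max_age = max_age)
    c(base = pr$obesity[pr$year == base_year],
      end = pr$obesity[pr$year == end_year])
  }
  p0 <- prev_at(0)
  target <- if (objective == "stabilize") p0[["base"]] else
    (1 - reduction) * p0[["base"]]
  if (p0[["end"]] <= target + tol) {
    return(list(value = 0, direction = direction, achieved = TRUE,
                prevalence = p0[["end"]], target = target,
                base_prevalence = p0[["base"]]))
  }
  pU <- prev_at(upper)
  if (pU[["end"]] > target + tol) {
    return(list(value = upper, direction = direction, achieved = FALSE,
                prevalence = pU[["end"]], target = target,
                base_prevalence = p0[["base"]]))
  }
  lo <- 0; hi <- upper; phi <- pU[["end"]]
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    pm <- prev_at(mid)[["end"]]
    if (pm > target) lo <- mid else { hi <- mid; phi <- pm }
    if (abs(pm - target) <= tol || (hi - lo) < 1e-3 * upper) {
      if (pm <= target) { hi <- mid; phi <- pm }
      break
    }
  }
  list(value = hi, direction = direction, achieved = TRUE,
       prevalence = phi, target = target, base_prevalence = p0[["base"]])
}

#' Scenario surface over (delta, gamma)
#'
#' Projects end-year overall obesity prevalence for every combination of the
#' supplied move-up decreases and move-down increases, reporting relative
#' reductions against two baselines: the `base_year` prevalence and the
#' status-quo `end_year` prevalence (both reporting conventions are emitted
#' because published surfaces can be read either way).
#'
#' @inheritParams find_required_change
#' @param deltas,gammas Lever grids.
#' @return Data frame `delta`, `gamma`, `prevalence` (end-year obesity),
#'   `reduction_vs_base`, `reduction_vs_statusquo` (percent).
#' @export
scenario_grid <- function(params, life_table, cohort_sizes,
                          deltas = seq(0, 0.4, 0.1),
                          gammas = seq(0, 0.4, 0.1),
                          base_year = 2022, end_year = 2027,
                          start_year = 2022, mort_adj = rep(1, 10),
                          config = model_config(), min_age = 18,
                          max_age = 110) {
  years <- base_year:end_year
  grid <- expand.grid(delta = deltas, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)
  prev <- numeric(nrow(grid))
  base_prev <- NA_real_; sq_end <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sc <- scenario_spec(grid$delta[i], grid$gamma[i], start_year)
    pr <- project_cohorts(params, life_table, cohort_sizes, years,
                          scenario = sc, mort_adj = mort_adj, config = config,
                          min_age = min_age, max_age = max_age)
    prev[i] <- pr$obesity[pr$year == end_year]
    if (grid$delta[i] == 0 && grid$gamma[i] == 0) {
      base_prev <- pr$obesity[pr$year == base_year]
      sq_end <- prev[i]
    }
  }
  if (is.na(base_prev)) {
    pr <- project_cohorts(params, life_table, cohort_sizes, years,
                          scenario = scenario_spec(0, 0, start_year),
                          mort_adj = mort_adj, config = config,
                          min_age = min_age, max_age = max_age)
    base_prev <- pr$obesity[pr$year == base_year]
    sq_end <- pr$obesity[pr$year == end_year]
  }
  grid$prevalence <- prev
  grid$reduction_vs_base <- -relative_change(base_prev, prev)
  grid$reduction_vs_statusquo <- -relative_change(sq_end, prev)
  grid
}
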