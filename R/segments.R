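#' Model configuration constants
#'
#' Breakpoints and activation ages that define the piecewise-constant
#' covariate structure:
#'
#' * `bmi_age_breaks`: age-class boundaries for BMI transitions (classes
#'   `< 25`, `25-49`, `>= 50`; the last is the reference);
#' * `period_breaks`: calendar-period boundaries (periods before 1995 =
#'   reference, 1995-2004, 2005 onwards -- the last period is carried forward
#'   indefinitely for projection years);
#' * `dm_start_nw` / `dm_start_owob`: ages at which the diabetes-onset
#'   intensity switches on in normal weight (40) and in overweight/obesity
#'   (25); before these ages the onset intensity is exactly 0;
#' * `dm_age_break`: the single age boundary for the diabetes-onset age
#'   effect (`< 50` vs the `>= 50` reference);
#' * `start_age`: age at which BMI progression may start (3); everybody is
#'   assumed normal weight and non-diabetic at that age.
#'
#' Ages are in whole years; an individual's age in calendar year `y` is
#' `y - birth_year`. Age intervals are half-open `[a, b)` and period
#' boundaries fall on January 1 of the break years.
#'
#' @param bmi_age_breaks,period_breaks,dm_start_nw,dm_start_owob,dm_age_break,start_age
#'   See above.
#' @return A list of class `bmidiab_config`.
#' @export
model_config <- function(bmi_age_breaks = c(25, 50),
                         period_breaks = c(1995, 2005),
                         dm_start_nw = 40,
                         dm_start_owob = 25,
                         dm_age_break = 50,
                         start_age = 3) {
  stopifnot(length(bmi_age_breaks) == 2, length(period_breaks) == 2,
            start_age >= 0, dm_start_owob <= dm_start_nw)
  structure(list(
    bmi_age_breaks = sort(as.numeric(bmi_age_breaks)),
    period_breaks = sort(as.numeric(period_breaks)),
    dm_start_nw = as.numeric(dm_start_nw),
    dm_start_owob = as.numeric(dm_start_owob),
    dm_age_break = as.numeric(dm_age_break),
    start_age = as.numeric(start_age)
  ), class = "bmidiab_config")
}

# Ages at which any component of the covariate profile can change.
age_band_breaks <- function(config) {
  b <- sort(unique(c(config$bmi_age_breaks, config$dm_start_nw,
                     config$dm_start_owob, config$dm_age_break)))
  b[b > config$start_age]
}

period_labels <- c("pre1995", "p1995_2004", "p2005_2014")
age_class_labels <- c("age_lt25", "age_25_49", "age_ge50")

#' Resolve the covariate profile at a given age and calendar year
#'
#' @param sex `"M"` or `"F"`.
#' @param age Age in years.
#' @param year Calendar year.
#' @param config A [model_config()].
#' @return A list with elements `sex`, `age_class`, `period`,
#'   `dm_active_nw`, `dm_active_owob` and `dm_age_lt50`.
#' @export
covariate_profile <- function(sex, age, year, config = model_config()) {
  stopifnot(sex %in% c("M", "F"))
  ac <- findInterval(age, config$bmi_age_breaks) + 1L
  pd <- findInterval(year, config$period_breaks) + 1L
  list(sex = sex,
       age_class = age_class_labels[ac],
       period = period_labels[pd],
       dm_active_nw = age >= config$dm_start_nw,
       dm_active_owob = age >= config$dm_start_owob,
       dm_age_lt50 = age < config$dm_age_break)
}

# Enumerate the distinct covariate profiles as (sex x age band x period).
# Each row carries a representative age (the band's left end) so that all
# age-driven profile components are constant within a band.
profile_grid <- function(config = model_config()) {
  breaks <- age_band_breaks(config)
  band_start <- c(config$start_age, breaks)
  g <- expand.grid(sex = c("M", "F"), band = seq_along(band_start),
                   period = 1:3, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$rep_age <- band_start[g$band]
  g$qindex <- seq_len(nrow(g))
  g
}

# Map (sex, age, year) to the row of profile_grid() governing that instant.
profile_index <- function(sex, age, year, config = model_config(),
                          grid = profile_grid(config)) {
  breaks <- age_band_breaks(config)
  band <- findInterval(age, breaks) + 1L
  period <- findInterval(year, config$period_breaks) + 1L
  sx <- ifelse(sex == "F", 2L, 1L)
  nb <- length(breaks) + 1L
  # grid is expand.grid(sex, band, period): sex fastest, then band, then period
  (period - 1L) * (2L * nb) + (band - 1L) * 2L + sx
}

#' Split an observation interval into constant-covariate segments
#'
#' Covariates are piecewise constant in age and calendar time; the interval
#' from `start_age` to `end_age` of an individual's life is split exactly at
#' the age breakpoints (25, 40, 50 by default) and at the ages when the
#' calendar-period boundaries (1995, 2005) are crossed, given the birth year.
#'
#' @param birth_year Integer year of birth.
#' @param sex `"M"` or `"F"`.
#' @param start_age,end_age Age interval (years); `start_age` defaults to
#'   the model's origin age 3.
#' @param config A [model_config()].
#' @return A data frame with one row per segment: `start_age`, `end_age`,
#'   `sex`, `age_class`, `period`, `dm_active_nw`, `dm_active_owob`,
#'   `dm_age_lt50`, `qindex` (row in the internal profile grid) and `dt`
#'   (duration). Zero rows when `end_age == start_age`.
#' @examples
#' make_segments(1980, "M", end_age = 34)
#' @export
make_segments <- function(birth_year, sex, start_age = NULL, end_age,
                          config = model_config()) {
  if (is.null(start_age)) start_age <- config$start_age
  if (end_age < config$start_age) {
    stop("invalid observation: end_age ", end_age, " is before the model ",
         "origin age ", config$start_age)
  }
  stopifnot(end_age >= start_age, sex %in% c("M", "F"))
  if (end_age == start_age) {
    out <- data.frame(start_age = numeric(0), end_age = numeric(0),
                      sex = character(0), age_class = character(0),
                      period = character(0), dm_active_nw = logical(0),
                      dm_active_owob = logical(0), dm_age_lt50 = logical(0),
                      qindex = integer(0), dt = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  cuts <- sort(unique(c(age_band_breaks(config),
                        config$period_breaks - birth_year)))
  cuts <- cuts[cuts > start_age & cuts < end_age]
  lo <- c(start_age, cuts)
  hi <- c(cuts, end_age)
  prof <- lapply(lo, function(a) {
    covariate_profile(sex, a, birth_year + a, config)
  })
  data.frame(
    start_age = lo, end_age = hi, sex = sex,
    age_class = vapply(prof, `[[`, "", "age_class"),
    period = vapply(prof, `[[`, "", "period"),
    dm_active_nw = vapply(prof, `[[`, NA, "dm_active_nw"),
    dm_active_owob = vapply(prof, `[[`, NA, "dm_active_owob"),
    dm_age_lt50 = vapply(prof, `[[`, NA, "dm_age_lt50"),
    qindex = profile_index(sex, lo, birth_year + lo, config),
    dt = hi - lo,
    stringsAsFactors = FALSE
  )
}
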