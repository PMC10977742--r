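#' Classify BMI from weight and height
#'
#' Standard cut-points 25/30/35/40 kg/m2, lower bound inclusive.
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres.
#' @return Character vector of [BMI_CLASSES] labels (NA where inputs are
#'   missing or non-positive).
#' @examples
#' classify_bmi(c(70, 95), c(1.75, 1.70))
#' @export
classify_bmi <- function(weight_kg, height_m) {
  bmi <- ifelse(weight_kg > 0 & height_m > 0, weight_kg / height_m^2, NA)
  BMI_CLASSES[findInterval(bmi, c(25, 30, 35, 40)) + 1]
}

#' Read a survey-panel file
#'
#' Delimited text with header. Required columns: `person_id`, `sex` (M/F),
#' `birth_year`, `survey_year`, `diabetes` (0/1) and either `bmi_class`
#' (labels in [BMI_CLASSES]) or `weight` (kg) + `height` (m), from which the
#' BMI category is derived.
#'
#' @param file Path.
#' @param sep Field separator (default comma).
#' @return Data frame of raw records (uncleaned; see [clean_records()]).
#' @export
read_panel_data <- function(file, sep = ",") {
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("person_id", "sex", "birth_year", "survey_year", "diabetes")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"bmi_class" %in% names(raw)) {
    if (!all(c("weight", "height") %in% names(raw))) {
      stop("need either bmi_class or weight + height columns")
    }
    raw$bmi_class <- classify_bmi(raw$weight, raw$height)
  }
  raw
}

#' Clean raw survey records
#'
#' Applies the survey inclusion and reclassification rules:
#'
#' * rows with missing BMI category or missing diabetes status are dropped
#'   (counted);
#' * malformed rows (unknown sex or BMI label, non-numeric years, survey age
#'   below 15) are collected into a rejects table, never silently dropped;
#' * respondents under age 40, of normal weight, who declare diabetes are
#'   reclassified as non-diabetic normal weight (declared diabetes at that
#'   age and weight is taken to be of autoimmune or genetic origin, not
#'   type 2).
#'
#' @param raw Data frame as from [read_panel_data()] (or [generate_panel()]).
#' @param config A [model_config()]; its `dm_start_nw` is the
#'   reclassification age bound (40).
#' @param min_age Minimum survey age for inclusion (default 15).
#' @return List: `records` (clean data frame with an added `state` column),
#'   `rejects` (malformed rows with a `reason` column) and `audit` (named
#'   counts: `n_input`, `n_missing`, `n_malformed`, `n_reclassified`,
#'   `n_clean`).
#' @export
clean_records <- function(raw, config = model_config(), min_age = 15) {
  n_input <- nrow(raw)
  missing <- is.na(raw$bmi_class) | is.na(raw$diabetes)
  n_missing <- sum(missing)
  dat <- raw[!missing, , drop = FALSE]
  bad_sex <- !dat$sex %in% c("M", "F")
  bad_bmi <- !dat$bmi_class %in% BMI_CLASSES
  age <- suppressWarnings(as.numeric(dat$survey_year) -
                            as.numeric(dat$birth_year))
  bad_age <- is.na(age) | age < min_age
  bad <- bad_sex | bad_bmi | bad_age
  rejects <- dat[bad, , drop = FALSE]
  if (nrow(rejects)) {
    rejects$reason <- ifelse(bad_sex[bad], "bad_sex",
                             ifelse(bad_bmi[bad], "bad_bmi_class", "bad_age"))
  } else {
    rejects$reason <- character(0)
  }
  dat <- dat[!bad, , drop = FALSE]
  age <- age[!bad]
  reclass <- dat$bmi_class == "NW" & dat$diabetes == 1 &
    age < config$dm_start_nw
  dat$diabetes[reclass] <- 0L
  dat$state <- state_index(dat$bmi_class, dat$diabetes)
  rownames(dat) <- NULL
  audit <- c(n_input = n_input, n_missing = n_missing,
             n_malformed = nrow(rejects), n_reclassified = sum(reclass),
             n_clean = nrow(dat))
  message("clean_records: ", audit[["n_clean"]], " kept, ",
          audit[["n_missing"]], " missing dropped, ",
          audit[["n_malformed"]], " malformed rejected, ",
          audit[["n_reclassified"]], " under-40 normal-weight diabetics reclassified")
  list(records = dat, rejects = rejects, audit = audit)
}

#' Write a fitted parameter table
#'
#' CSV mirroring the layout of the published estimate table: one row per
#' free parameter with natural-scale estimate and 95% CI. Provenance is
#' recorded in `#` comment lines.
#'
#' @param fit A [fit_model()] result.
#' @param file Output path.
#' @param provenance Optional named character vector added to the header.
#' @export
write_fit_table <- function(fit, file, provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bmidiab %s fit table",
                       as.character(utils::packageVersion("bmidiab"))),
               sprintf("# loglik=%.6f n=%d convergence=%d", fit$loglik,
                       fit$n, fit$convergence),
               if (!is.null(provenance))
                 sprintf("# %s=%s", names(provenance), provenance)), con)
  utils::write.table(fit$table, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read/write model configuration as YAML
#'
#' @param config A [model_config()].
#' @param file Path.
#' @return `read_model_config()` returns a [model_config()].
#' @export
write_model_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(file) {
  do.call(model_config, yaml::read_yaml(file))
}

#' Write/read a parameter set as YAML
#'
#' @param params A [make_params()] object.
#' @param file Path.
#' @export
write_params <- function(params, file) {
  yaml::write_yaml(list(baseline = as.list(params$baseline),
                        hr = lapply(params$hr, as.list)), file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  x <- yaml::read_yaml(file)
  make_params(baseline = unlist(x$baseline), hr = lapply(x$hr, unlist))
}
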