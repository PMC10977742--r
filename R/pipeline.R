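#' End-to-end pipeline configuration
#'
#' @param sim A [synthetic_config()] describing the synthetic panel to
#'   generate, or `NULL` to read data from `data_file` instead.
#' @param data_file Path to a panel CSV (used when `sim` is `NULL`).
#' @param years Projection years (default 2022:2027).
#' @param scenarios Named list of [scenario_spec()] (default
#'   [standard_scenarios()]).
#' @param grid_deltas,grid_gammas Levers for the scenario surface.
#' @param fit_control,fit_hessian Passed to [fit_model()].
#' @param lifetable_args Arguments for [make_synthetic_lifetable()].
#' @param cohort_years,cohort_size Arguments for [make_cohort_sizes()].
#' @param mort_adj Mortality hazard ratios for the 10 living states.
#' @param min_age Adult-population cutoff for prevalence denominators.
#' @param plots Also write simple PNG figures?
#' @return List of class `bmidiab_pipeline_config`.
#' @export
pipeline_config <- function(sim = synthetic_config(n = 2000),
                            data_file = NULL,
                            years = 2022:2027,
                            scenarios = standard_scenarios(),
                            grid_deltas = seq(0, 0.4, 0.2),
                            grid_gammas = seq(0, 0.4, 0.2),
                            fit_control = list(),
                            fit_hessian = TRUE,
                            lifetable_args = list(),
                            cohort_years = 1895:2015,
                            cohort_size = 800000,
                            mort_adj = rep(1, 10),
                            min_age = 18,
                            plots = TRUE) {
  structure(as.list(environment()), class = "bmidiab_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a survey panel, clean it, fit the multi-state model,
#' produce goodness-of-fit tables, project prevalence under every scenario,
#' compute the scenario surface and lifetime risks, and write all artifacts
#' to `out_dir` as CSV (plus optional PNG figures). Every artifact carries a
#' provenance header (package version, seed, configuration hash). All
#' randomness flows from `seed`; per-stage child seeds are derived
#' deterministically, so identical configuration and seed give identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param model_cfg A [model_config()].
#' @return Invisibly, a list with the in-memory results (`panel`, `clean`,
#'   `fit`, `gof`, `projections`, `grid`, `lifetime`) and `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1,
                         model_cfg = model_config()) {
  stopifnot(inherits(config, "bmidiab_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  child_seed <- function(stage) (seed * 1000003 + stage) %% 2147483647
  cfg_chars <- utf8ToInt(paste(utils::capture.output(utils::str(config)),
                               collapse = "\n"))
  cfg_hash <- sum(cfg_chars * seq_along(cfg_chars)) %% 1e9
  prov <- c(version = as.character(utils::packageVersion("bmidiab")),
            seed = as.character(seed), config_hash = sprintf("%.0f", cfg_hash))
  write_artifact <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# %s=%s", names(prov), prov), con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. data
  panel <- stage("simulate", {
    if (!is.null(config$sim)) {
      sc <- config$sim
      sc$seed <- child_seed(1L)
      generate_panel(sc, model_cfg)
    } else {
      read_panel_data(config$data_file)
    }
  })
  cleaned <- stage("clean", clean_records(panel, model_cfg))
  files <- c(panel = write_artifact(cleaned$records, "panel_clean.csv"))

  # 2. fit
  fit <- stage("fit", fit_model(cleaned$records, config = model_cfg,
                                hessian = config$fit_hessian,
                                control = config$fit_control))
  files <- c(files, fit = write_fit_table(fit, file.path(out_dir, "fit_table.csv"),
                                          provenance = prov))
  gof <- stage("gof", goodness_of_fit(cleaned$records, fit$params, model_cfg))
  files <- c(files, gof_year = write_artifact(gof$by_year, "gof_by_year.csv"))

  # 3. projection inputs
  lt <- stage("lifetable", do.call(make_synthetic_lifetable,
                                   utils::modifyList(
                                     list(years = min(config$cohort_years):max(config$years)),
                                     config$lifetable_args)))
  cs <- stage("cohorts", make_cohort_sizes(
    (min(config$years) - 110):(max(config$years) - config$min_age),
    size = config$cohort_size))

  # 4. scenario projections (published-table layout: indicators x years)
  projections <- stage("project", {
    lapply(config$scenarios, function(sc) {
      project_cohorts(fit$params, lt, cs, config$years, scenario = sc,
                      mort_adj = config$mort_adj, config = model_cfg,
                      min_age = config$min_age)
    })
  })
  proj_tab <- do.call(rbind, lapply(names(projections), function(nm) {
    p <- projections[[nm]]
    data.frame(scenario = nm, year = p$year,
               overweight = 100 * p$OW, obesity1 = 100 * p$OB1,
               obesity2 = 100 * p$OB2, obesity3 = 100 * p$OB3,
               obesity_total = 100 * p$obesity, diabetes = 100 * p$diabetes,
               stringsAsFactors = FALSE)
  }))
  files <- c(files, projection = write_artifact(proj_tab, "projection.csv"))

  # 5. scenario surface
  grid <- stage("grid", scenario_grid(fit$params, lt, cs,
                                      deltas = config$grid_deltas,
                                      gammas = config$grid_gammas,
                                      base_year = min(config$years),
                                      end_year = max(config$years),
                                      mort_adj = config$mort_adj,
                                      config = model_cfg,
                                      min_age = config$min_age))
  files <- c(files, grid = write_artifact(grid, "scenario_grid.csv"))

  # 6. lifetime risks
  lifetime <- stage("lifetime", {
    do.call(rbind, lapply(names(config$scenarios), function(nm) {
      sc <- config$scenarios[[nm]]
      data.frame(scenario = nm, sex = c("M", "F"),
                 risk = c(population_lifetime_risk(fit$params, lt, config$mort_adj,
                                                   "M", scenario = sc,
                                                   config = model_cfg),
                          population_lifetime_risk(fit$params, lt, config$mort_adj,
                                                   "F", scenario = sc,
                                                   config = model_cfg)),
                 stringsAsFactors = FALSE)
    }))
  })
  files <- c(files, lifetime = write_artifact(lifetime, "lifetime_risk.csv"))

  if (isTRUE(config$plots)) {
    stage("plots", {
      grDevices::png(file.path(out_dir, "prevalence_projection.png"),
                     width = 900, height = 600)
      sq <- projections[[1]]
      graphics::plot(sq$year, 100 * sq$obesity, type = "b",
                     ylim = c(0, max(100 * sq$obesity) * 1.3),
                     xlab = "year", ylab = "prevalence (%)",
                     main = "Projected adult obesity prevalence by scenario")
      i <- 1
      for (nm in names(projections)[-1]) {
        i <- i + 1
        graphics::lines(projections[[nm]]$year, 100 * projections[[nm]]$obesity,
                        type = "b", col = i, pch = i)
      }
      graphics::legend("bottomleft", legend = names(projections),
                       col = seq_along(projections),
                       pch = seq_along(projections), bty = "n")
      grDevices::dev.off()
    })
    files <- c(files, plot = file.path(out_dir, "prevalence_projection.png"))
  }
  invisible(list(panel = panel, clean = cleaned, fit = fit, gof = gof,
                 projections = projections, grid = grid, lifetime = lifetime,
                 files = files))
}
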