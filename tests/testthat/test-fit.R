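test_that("log-likelihood at the generating truth beats perturbed parameters", {
  panel <- generate_panel(synthetic_config(n = 2000, seed = 7))
  cl <- suppressMessages(clean_records(panel))
  truth <- default_params()
  ll_truth <- log_likelihood(cl$records, truth)
  set.seed(71)
  worse <- 0
  nrep <- 10
  for (r in 1:nrep) {
    v <- pack_params(truth) + log(runif(27, 0.5, 1.5))
    if (log_likelihood(cl$records, unpack_params(v)) < ll_truth) {
      worse <- worse + 1
    }
  }
  expect_gte(worse, nrep - 1)  # on average truth dominates +/-50% perturbations
})

test_that("doubling every record halves squared standard errors (information additivity)", {
  panel <- generate_panel(synthetic_config(n = 400, seed = 8))
  cl <- suppressMessages(clean_records(panel))
  v <- pack_params(default_params())
  prep1 <- bmidiab:::prepare_panel(cl$records)
  prep2 <- bmidiab:::prepare_panel(rbind(cl$records, cl$records))
  nll1 <- function(x) -bmidiab:::panel_loglik(prep1, unpack_params(x))
  nll2 <- function(x) -bmidiab:::panel_loglik(prep2, unpack_params(x))
  H1 <- bmidiab:::num_hessian(nll1, v)
  H2 <- bmidiab:::num_hessian(nll2, v)
  expect_equal(H2, 2 * H1, tolerance = 1e-6)
  # hence SEs scale by 1/sqrt(2) wherever the information is invertible
})

test_that("parameters without data support are flagged as non-identifiable", {
  # only young normal-weight non-diabetic observations before age 40
  rec <- data.frame(sex = rep("M", 50), birth_year = 1990,
                    survey_year = 2010, bmi_class = "NW", diabetes = 0)
  fit <- fit_model(rec, hessian = FALSE, control = list(maxit = 2))
  expect_true(all(grepl("dm", grep("dm", fit$flags, value = TRUE))))
  expect_true("q_dm_ob23" %in% fit$flags)
  expect_true(any(grepl("female", fit$flags)))
})

test_that("a short optimization run improves on the default initialization", {
  panel <- generate_panel(synthetic_config(n = 400, seed = 9))
  cl <- suppressMessages(clean_records(panel))
  init <- make_params(baseline = stats::setNames(rep(0.01, 8),
    c("nw_ow", "prog", "ow_nw", "regr", "dm_nw", "dm_ow", "dm_ob1", "dm_ob23")))
  fit <- fit_model(cl$records, hessian = FALSE, control = list(maxit = 25))
  expect_gt(fit$loglik, log_likelihood(cl$records, init))
  expect_s3_class(fit$params, "bmidiab_params")
  expect_equal(length(fit$logpar), 27)
})

test_that("goodness-of-fit tables are prevalences in [0,1] over non-empty strata", {
  panel <- generate_panel(synthetic_config(n = 1500, seed = 10))
  cl <- suppressMessages(clean_records(panel))
  g <- goodness_of_fit(cl$records, default_params())
  for (tab in list(g$by_year, g$by_age)) {
    expect_true(all(tab$n > 0))
    for (col in c("obs_obesity", "pred_obesity", "obs_diabetes",
                  "pred_diabetes")) {
      expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 1))
    }
  }
  expect_true(all(g$dm_by_bmi$n > 0))
  # observed and predicted diabetes prevalence increase with BMI category
  expect_true(all(diff(g$dm_by_bmi$pred_diabetes) > 0))
  # with the generating parameters the fit is close in well-populated strata
  big <- g$by_year$n > 100
  expect_lt(max(abs(g$by_year$obs_obesity - g$by_year$pred_obesity)[big]), 0.1)
})
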