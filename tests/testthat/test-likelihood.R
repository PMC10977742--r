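test_that("zero-length interval gives the identity matrix", {
  P <- transition_probability(default_params(), 1980, "M", 30, 30)
  expect_equal(unname(P), diag(10))
})

test_that("two-state closed form matches the segment expm product to 1e-10", {
  a <- 0.048; b <- 0.027
  p <- toy_params(nw_ow = a, ow_nw = b)
  # birth 1930, ages 50 -> 60: single covariate segment (>= 50, pre-1995)
  P <- transition_probability(p, 1930, "M", 50, 60)
  t <- 10
  p12 <- a / (a + b) * (1 - exp(-(a + b) * t))
  expect_equal(P["NW", "OW"], p12, tolerance = 1e-10)
  expect_equal(P["NW", "NW"], 1 - p12, tolerance = 1e-10)
  expect_equal(P["OW", "NW"], b / (a + b) * (1 - exp(-(a + b) * t)),
               tolerance = 1e-10)
  # unreachable states: no off-diagonal mass outside the two-state block
  expect_true(all(P[1:2, 3:10] == 0))
})

test_that("expm probabilities agree with the uniformization oracle", {
  set.seed(41)
  for (r in 1:12) {
    p <- random_params()
    by <- sample(1920:1990, 1)
    ea <- sample(20:80, 1)
    P <- transition_probability(p, by, "F", 3, ea)
    segs <- make_segments(by, "F", end_age = ea)
    arr <- bmidiab:::build_Q_array(p, model_config())
    Pu <- diag(10)
    for (i in seq_len(nrow(segs))) {
      Pu <- Pu %*% expm_unif(arr[, , segs$qindex[i]], segs$dt[i])
    }
    expect_lt(max(abs(P - Pu)), 1e-9)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
})

test_that("log-likelihood of trivial and closed-form observations is exact", {
  # all intensities zero, observed NW: P = 1, loglik = 0
  rec <- data.frame(sex = "M", birth_year = 1980, survey_year = 2010,
                    bmi_class = "NW", diabetes = 0)
  expect_equal(log_likelihood(rec, toy_params()), 0)
  # two-state toy observed OW at age 13 (t = 10 inside one segment)
  a <- 0.048; b <- 0.027
  rec2 <- data.frame(sex = "M", birth_year = 1980, survey_year = 1993,
                     bmi_class = "OW", diabetes = 0)
  expect_equal(log_likelihood(rec2, toy_params(nw_ow = a, ow_nw = b)),
               log(a / (a + b) * (1 - exp(-(a + b) * 10))),
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant to dataset permutation and additive", {
  set.seed(42)
  panel <- generate_panel(synthetic_config(n = 300, seed = 5))
  cl <- suppressMessages(clean_records(panel))
  rec <- cl$records
  p <- default_params()
  ll <- log_likelihood(rec, p)
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(log_likelihood(perm, p), ll, tolerance = 1e-10)
  # doubling the dataset doubles the log-likelihood
  expect_equal(log_likelihood(rbind(rec, rec), p), 2 * ll, tolerance = 1e-8)
})

test_that("structurally impossible observations yield -Inf with flagged keys", {
  # diabetic normal weight observed at age 20: onset cannot have occurred
  rec <- data.frame(sex = "M", birth_year = 1990, survey_year = 2010,
                    bmi_class = "NW", diabetes = 1)
  ll <- log_likelihood(rec, default_params())
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_prob_keys")$birth_year, 1990)
})
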