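#' Maximum-likelihood fit of the multi-state model
#'
#' Maximises the interval-censored panel log-likelihood over the 27 free
#' parameters (8 log baseline intensities, 19 log hazard ratios) with a
#' quasi-Newton (BFGS) search on the unconstrained log scale. Standard errors
#' come from the inverse of a central-difference observed-information matrix;
#' confidence intervals are `exp(log-estimate +/- 1.96 SE)` on the natural
#' scale.
#'
#' Before fitting, simple informativeness checks are run (e.g. whether any
#' diabetic state was observed, whether any observation interval overlaps
#' each covariate level); parameters without supporting observations are
#' reported in `$flags` and their estimates should not be interpreted.
#'
#' @inheritParams log_likelihood
#' @param init Initial [make_params()] values. Default: all baseline
#'   intensities 0.01 per year, all hazard ratios 1.
#' @param hessian Compute the observed information (and hence SEs and CIs)?
#'   Skipping it saves roughly a third of the run time.
#' @param control Passed to [stats::optim()] (method BFGS); `maxit` defaults
#'   to 500 and `reltol` to 1e-10.
#' @return An object of class `bmidiab_fit`: list with `params` (estimates as
#'   a parameter set), `logpar`, `vcov` (log scale), `table` (natural-scale
#'   estimates with 95% CIs), `loglik`, `convergence` (0 = converged),
#'   `counts`, `flags` and `n`.
#' @examples
#' \donttest{
#' sim <- generate_panel(synthetic_config(n = 500, seed = 1))
#' fit <- fit_model(sim, hessian = FALSE, control = list(maxit = 5))
#' }
#' @export
fit_model <- function(records, init = NULL, config = model_config(),
                      hessian = TRUE, control = list()) {
  prep <- prepare_panel(records, config)
  if (is.null(init)) {
    init <- make_params(baseline = stats::setNames(rep(0.01, 8),
      c("nw_ow", "prog", "ow_nw", "regr", "dm_nw", "dm_ow", "dm_ob1", "dm_ob23")))
  }
  flags <- identifiability_flags(prep)
  v0 <- pack_params(init)
  negll <- function(v) {
    # keep the search inside a generous but numerically safe box
    if (any(!is.finite(v)) || any(abs(v) > 20)) return(1e10)
    ll <- panel_loglik(prep, unpack_params(v))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- stats::optim(v0, negll, method = "BFGS", control = ctl)
  v <- opt$par
  est <- unpack_params(v)
  vc <- NULL
  se <- rep(NA_real_, 27)
  if (hessian) {
    H <- num_hessian(negll, v)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) <= 0)) {
      # fall back to a pseudo-inverse with clipped curvature
      ei <- eigen(H, symmetric = TRUE)
      lam <- pmax(ei$values, 1e-8 * max(abs(ei$values)))
      vc <- ei$vectors %*% diag(1 / lam) %*% t(ei$vectors)
    }
    se <- sqrt(pmax(diag(vc), 0))
    flags <- c(flags, param_names()[se > 5][!param_names()[se > 5] %in% flags])
  }
  tab <- data.frame(
    param = param_names(),
    estimate = exp(unname(v)),
    lower = exp(unname(v) - 1.96 * se),
    upper = exp(unname(v) + 1.96 * se),
    se_log = se,
    stringsAsFactors = FALSE
  )
  structure(list(params = est, logpar = v, vcov = vc, table = tab,
                 loglik = -opt$value, convergence = opt$convergence,
                 counts = opt$counts, flags = flags, n = prep$n),
            class = "bmidiab_fit")
}

# Coarse data-support checks for each parameter group.
identifiability_flags <- function(prep) {
  flags <- character(0)
  k <- prep$keys
  cfg <- prep$config
  obs_state <- which(colSums(prep$counts) > 0)
  if (!any(obs_state >= 6)) {
    flags <- c(flags, grep("dm", param_names(), value = TRUE))
  }
  if (!any(k$sex == "F")) {
    flags <- c(flags, grep("female", param_names(), value = TRUE))
  }
  # interval [3, survey age] overlap with each period
  yr0 <- k$birth_year + cfg$start_age
  if (!any(yr0 < cfg$period_breaks[1])) {
    flags <- c(flags, grep("pre", param_names(), value = TRUE))
  }
  if (!any(k$survey_year >= cfg$period_breaks[1] &
           yr0 < cfg$period_breaks[2])) {
    flags <- c(flags, grep("p1995_2004", param_names(), value = TRUE))
  }
  if (!any(k$survey_year >= cfg$period_breaks[2])) {
    flags <- c(flags, grep("p2005_2014", param_names(), value = TRUE))
  }
  age <- k$survey_year - k$birth_year
  if (!any(age >= cfg$dm_start_nw) && length(obs_state) > 0) {
    # nobody observed past the normal-weight activation age
    flags <- unique(c(flags, "q_dm_nw"))
  }
  unique(flags)
}

# Central-difference Hessian (symmetric by construction).
num_hessian <- function(f, x, eps = 1e-4) {
  n <- length(x)
  h <- eps * pmax(1, abs(x))
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- rep(0, n); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < n) {
      for (j in (i + 1):n) {
        ej <- rep(0, n); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.bmidiab_fit <- function(x, ...) {
  cat("Multi-state BMI / type 2 diabetes model fit\n")
  cat("  records:", x$n, "  log-likelihood:", format(x$loglik), "\n")
  cat("  convergence code:", x$convergence,
      if (x$convergence == 0) "(converged)" else "(check diagnostics)", "\n")
  if (length(x$flags)) {
    cat("  flagged (weak/no data support):", paste(x$flags, collapse = ", "),
        "\n")
  }
  print(transform(x$table, estimate = signif(estimate, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4),
                  se_log = signif(se_log, 3)), row.names = FALSE)
  invisible(x)
}

#' Observed vs model-predicted prevalence tables
#'
#' Goodness-of-fit summaries comparing observed proportions with the model's
#' predicted state-occupation probabilities averaged over the individuals in
#' each stratum: by survey year (obesity and type 2 diabetes prevalence), by
#' age group, and type 2 diabetes prevalence by BMI category. Empty strata
#' are omitted.
#'
#' @inheritParams log_likelihood
#' @param age_breaks Age-group boundaries for the by-age table.
#' @return List of data frames `by_year`, `by_age`, `dm_by_bmi`.
#' @export
goodness_of_fit <- function(records, params, config = model_config(),
                            age_breaks = c(15, 25, 35, 45, 55, 65, 75)) {
  prep <- prepare_panel(records, config)
  P <- key_probs(prep, params)
  cnt <- prep$counts
  nk <- rowSums(cnt)
  obese_s <- c(3:5, 8:10)
  dm_s <- 6:10
  obs_ob <- rowSums(cnt[, obese_s, drop = FALSE])
  obs_dm <- rowSums(cnt[, dm_s, drop = FALSE])
  pred_ob <- rowSums(P[, obese_s, drop = FALSE]) * nk
  pred_dm <- rowSums(P[, dm_s, drop = FALSE]) * nk
  agg <- function(g) {
    keep <- tapply(nk, g, sum) > 0
    out <- data.frame(
      stratum = names(keep)[keep],
      n = as.vector(tapply(nk, g, sum))[keep],
      obs_obesity = (as.vector(tapply(obs_ob, g, sum)) /
                       as.vector(tapply(nk, g, sum)))[keep],
      pred_obesity = (as.vector(tapply(pred_ob, g, sum)) /
                        as.vector(tapply(nk, g, sum)))[keep],
      obs_diabetes = (as.vector(tapply(obs_dm, g, sum)) /
                        as.vector(tapply(nk, g, sum)))[keep],
      pred_diabetes = (as.vector(tapply(pred_dm, g, sum)) /
                         as.vector(tapply(nk, g, sum)))[keep],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  }
  by_year <- agg(prep$keys$survey_year)
  age <- prep$keys$survey_year - prep$keys$birth_year
  grp <- cut(age, c(age_breaks, Inf), right = FALSE)
  by_age <- agg(grp)
  # diabetes prevalence within BMI category (observed and predicted)
  dm_by_bmi <- do.call(rbind, lapply(1:5, function(b) {
    n_b <- sum(cnt[, b]) + sum(cnt[, b + 5])
    if (n_b == 0) return(NULL)
    pred_b <- sum(P[, b] * nk) + sum(P[, b + 5] * nk)
    data.frame(bmi_class = BMI_CLASSES[b], n = n_b,
               obs_diabetes = sum(cnt[, b + 5]) / n_b,
               pred_diabetes = sum(P[, b + 5] * nk) / pred_b,
               stringsAsFactors = FALSE)
  }))
  list(by_year = by_year, by_age = by_age, dm_by_bmi = dm_by_bmi)
}
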