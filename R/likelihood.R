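#' Interval transition-probability matrix
#'
#' Probability matrix P(from_age, to_age) of the time-inhomogeneous chain for
#' an individual of given sex and birth year: the product, over the
#' constant-covariate segments of [make_segments()], of `expm(Q_k * dt_k)`.
#'
#' @inheritParams make_segments
#' @param params A [make_params()] parameter set.
#' @param from_age,to_age Age interval; `from_age >= 3`, `to_age >= from_age`.
#' @return A 10x10 stochastic matrix (rows sum to 1).
#' @examples
#' P <- transition_probability(default_params(), 1960, "M", 3, 50)
#' rowSums(P)
#' @export
transition_probability <- function(params, birth_year, sex, from_age, to_age,
                                   config = model_config()) {
  stopifnot(from_age >= config$start_age, to_age >= from_age)
  segs <- make_segments(birth_year, sex, start_age = from_age,
                        end_age = to_age, config = config)
  P <- diag(10)
  if (nrow(segs) == 0) {
    dimnames(P) <- list(STATE_LABELS, STATE_LABELS)
    return(P)
  }
  arr <- build_Q_array(params, config)
  for (r in seq_len(nrow(segs))) {
    M <- expm_cpp(arr[, , segs$qindex[r]] * segs$dt[r])
    if (any(!is.finite(M))) {
      stop("non-finite transition probabilities on segment [",
           segs$start_age[r], ", ", segs$end_age[r], ") for birth year ",
           birth_year)
    }
    P <- P %*% M
  }
  dimnames(P) <- list(STATE_LABELS, STATE_LABELS)
  P
}

# Convert a panel-record data frame (sex, birth_year, survey_year and either
# `state` or bmi_class+diabetes) into the cached structure the likelihood
# needs: unique observation keys, their segment products expressed as indices
# into a pool of unique (generator slice, duration) pairs, and a key x state
# count matrix.
prepare_panel <- function(records, config = model_config()) {
  stopifnot(nrow(records) > 0)
  if (is.null(records$state)) {
    records$state <- state_index(records$bmi_class, records$diabetes)
  }
  stopifnot(all(records$state %in% 1:10),
            all(records$sex %in% c("M", "F")))
  age <- records$survey_year - records$birth_year
  if (any(age < config$start_age)) {
    stop("invalid observation: survey before the model origin age")
  }
  key <- paste(records$sex, records$birth_year, records$survey_year, sep = "|")
  ukey <- sort(unique(key))
  krow <- match(key, ukey)
  counts <- matrix(0L, length(ukey), 10)
  for (i in seq_along(krow)) {
    counts[krow[i], records$state[i]] <- counts[krow[i], records$state[i]] + 1L
  }
  parts <- strsplit(ukey, "|", fixed = TRUE)
  ksex <- vapply(parts, `[[`, "", 1L)
  kby <- as.integer(vapply(parts, `[[`, "", 2L))
  ksy <- as.integer(vapply(parts, `[[`, "", 3L))
  seg_list <- vector("list", length(ukey))
  for (k in seq_along(ukey)) {
    s <- make_segments(kby[k], ksex[k], end_age = ksy[k] - kby[k],
                       config = config)
    seg_list[[k]] <- cbind(s$qindex, s$dt)
  }
  all_pairs <- do.call(rbind, seg_list)
  pid <- paste(all_pairs[, 1], all_pairs[, 2], sep = "_")
  upairs <- !duplicated(pid)
  pair_q <- as.integer(all_pairs[upairs, 1])
  pair_dt <- as.numeric(all_pairs[upairs, 2])
  pair_map <- match(pid, pid[upairs])
  key_pairs <- vector("list", length(ukey))
  off <- 0L
  for (k in seq_along(ukey)) {
    nk <- nrow(seg_list[[k]])
    key_pairs[[k]] <- if (nk > 0) pair_map[off + seq_len(nk)] else integer(0)
    off <- off + nk
  }
  list(keys = data.frame(sex = ksex, birth_year = kby, survey_year = ksy,
                         stringsAsFactors = FALSE),
       counts = counts, pair_q = pair_q, pair_dt = pair_dt,
       key_pairs = key_pairs, n = nrow(records), config = config)
}

# State-occupation probabilities P[NW-nonD -> s] at the survey age, one row
# per observation key.
key_probs <- function(prep, params) {
  arr <- build_Q_array(params, prep$config)
  key_state_probs_cpp(arr, prep$pair_q, prep$pair_dt, prep$key_pairs, 1L)
}

#' Panel log-likelihood
#'
#' Log-likelihood of interval-censored survey observations: every individual
#' starts in normal weight without diabetes at age 3, so each record
#' contributes `log P[NW -> observed state]` over the interval from age 3 to
#' the survey age. Records sharing sex, birth year and survey year reuse one
#' matrix product.
#'
#' A structurally impossible observation (probability 0 under `params`)
#' contributes `-Inf`; the offending keys are attached as attribute
#' `"zero_prob_keys"`.
#'
#' @param records Data frame with columns `sex` (`"M"`/`"F"`), `birth_year`,
#'   `survey_year` and either `state` (1-10) or `bmi_class` + `diabetes`.
#' @param params A [make_params()] parameter set.
#' @param config A [model_config()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(records, params, config = model_config()) {
  prep <- prepare_panel(records, config)
  panel_loglik(prep, params)
}

panel_loglik <- function(prep, params) {
  P <- key_probs(prep, params)
  obs <- prep$counts > 0
  p <- P[obs]
  n <- prep$counts[obs]
  # guard against loss of validity in the matrix exponential for extreme
  # intensities: probabilities must stay in [0, 1]
  if (any(!is.finite(p)) || any(p > 1 + 1e-8)) return(-Inf)
  if (any(p <= 0)) {
    ll <- -Inf
    bad <- which(rowSums(obs & P <= 0) > 0)
    attr(ll, "zero_prob_keys") <- prep$keys[bad, , drop = FALSE]
    return(ll)
  }
  sum(n * log(p))
}
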