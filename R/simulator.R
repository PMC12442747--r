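# Synthetic diagnostic studies with a disease-state-dependent interfering
# event. Every subject carries a counterfactual result (what the test would
# have shown had the event not occurred) and a pre-event partial result, so
# all six handling strategies are testable without external data. Defaults
# reproduce the conditions of the worked CT-scan study: prevalence 0.2,
# event rates 24/40 (diseased) and 40/160 (healthy), baseline accuracy
# sens 0.75 / spec 11/12, degraded accuracy 2/3 and 0.85 under the event,
# partial-data accuracy 0.5 and 0.7.

#' Simulation parameters
#'
#' @param n subject count, \code{>= 1}.
#' @param prevalence probability of the target condition.
#' @param sens0,spec0 index-test accuracy absent any interfering event (the
#'   counterfactual accuracy).
#' @param ie_rate_diseased,ie_rate_healthy per-state event probabilities
#'   (events in diagnostic studies are typically tied to the true disease
#'   state, e.g. diseased patients terminate the scan more often).
#' @param sens_ie,spec_ie accuracy of the observed result when the event
#'   occurs (degradation model).
#' @param p_absent_given_ie probability that the event leaves a
#'   non-existent (absent) result instead of an affected one.
#' @param partial_sens,partial_spec accuracy of the pre-event partial
#'   result for event-affected subjects.
#' @param event_type name of the simulated event.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return validated list of class \code{simulation_params}.
#' @export
simulation_params <- function(n = 200, prevalence = 0.2,
                              sens0 = 0.75, spec0 = 11 / 12,
                              ie_rate_diseased = 0.6,
                              ie_rate_healthy = 0.25,
                              sens_ie = 2 / 3, spec_ie = 0.85,
                              p_absent_given_ie = 0,
                              partial_sens = 0.5, partial_spec = 0.7,
                              event_type = "ie", seed = 1L) {
  p <- list(n = as.integer(n), prevalence = prevalence, sens0 = sens0,
            spec0 = spec0, ie_rate_diseased = ie_rate_diseased,
            ie_rate_healthy = ie_rate_healthy, sens_ie = sens_ie,
            spec_ie = spec_ie, p_absent_given_ie = p_absent_given_ie,
            partial_sens = partial_sens, partial_spec = partial_spec,
            event_type = event_type, seed = as.integer(seed))
  probs <- unlist(p[c("prevalence", "sens0", "spec0", "ie_rate_diseased",
                      "ie_rate_healthy", "sens_ie", "spec_ie",
                      "p_absent_given_ie", "partial_sens", "partial_spec")])
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (p$n < 1) stop("n must be >= 1", call. = FALSE)
  structure(p, class = "simulation_params")
}

draw_result <- function(cond, acc_sens, acc_spec) {
  n <- length(cond)
  correct <- stats::runif(n) < ifelse(cond == "diseased", acc_sens, acc_spec)
  ifelse(cond == "diseased",
         ifelse(correct, "positive", "negative"),
         ifelse(correct, "negative", "positive"))
}

#' Simulate a diagnostic accuracy study
#'
#' Per subject: condition from the prevalence; event occurrence from the
#' state-specific rate; a counterfactual result from the baseline accuracy
#' (sens0/spec0); the observed result equal to the counterfactual without
#' the event, otherwise drawn from the degraded accuracy (sens_ie/spec_ie)
#' or set absent with probability \code{p_absent_given_ie}; and a pre-event
#' partial result from the partial accuracy for affected subjects. Fully
#' deterministic given the seed.
#'
#' @param params a \code{\link{simulation_params}} object.
#' @return a \code{\link{subject_table}} with counterfactual and partial
#'   results and a perfect reference standard.
#' @export
simulate_study <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, {
    n <- params$n
    cond <- ifelse(stats::runif(n) < params$prevalence,
                   "diseased", "non_diseased")
    rate <- ifelse(cond == "diseased", params$ie_rate_diseased,
                   params$ie_rate_healthy)
    occ <- stats::runif(n) < rate
    cf <- draw_result(cond, params$sens0, params$spec0)
    obs <- cf
    if (any(occ)) {
      affected <- draw_result(cond[occ], params$sens_ie, params$spec_ie)
      absent <- stats::runif(sum(occ)) < params$p_absent_given_ie
      affected[absent] <- "absent"
      obs[occ] <- affected
    }
    part <- obs
    part[part == "absent"] <- "absent"
    if (any(occ)) {
      part[occ] <- draw_result(cond[occ], params$partial_sens,
                               params$partial_spec)
    }
    df <- data.frame(
      subject_id = sprintf("sim%06d", seq_len(n)),
      true_condition = cond,
      reference_result = ifelse(cond == "diseased", "positive", "negative"),
      index_result = obs,
      partial_result = part,
      counterfactual_result = cf,
      stringsAsFactors = FALSE)
    df[[paste0("ie_", params$event_type)]] <- occ
    subject_table(df)
  })
}

#' Simulate several independent interfering events with timestamps
#'
#' Lightweight generator used to exercise multi-event resolution: each
#' declared event type occurs independently at its own rate, and occurred
#' events get times drawn uniformly on (0, 1).
#'
#' @param n subject count.
#' @param rates named numeric vector: event type -> occurrence probability.
#' @param seed integer seed.
#' @return a \code{\link{subject_table}} with one flag and one time column
#'   per event type (index results are drawn fair-coin; the object exists
#'   to test event resolution, not accuracy).
#' @export
simulate_multi_events <- function(n, rates, seed = 1L) {
  stopifnot(length(names(rates)) == length(rates))
  withr::with_seed(as.integer(seed), {
    df <- data.frame(
      subject_id = sprintf("me%05d", seq_len(n)),
      true_condition = ifelse(stats::runif(n) < 0.5,
                              "diseased", "non_diseased"),
      index_result = ifelse(stats::runif(n) < 0.5, "positive", "negative"),
      stringsAsFactors = FALSE)
    for (ev in names(rates)) {
      occ <- stats::runif(n) < rates[[ev]]
      df[[paste0("ie_", ev)]] <- occ
      df[[paste0("ie_", ev, "_time")]] <- ifelse(occ, stats::runif(n),
                                                 NA_real_)
    }
    subject_table(df)
  })
}

#' Closed-form strategy targets for simulated studies
#'
#' The large-sample sensitivity and specificity each strategy estimates
#' under the simulator's data-generating model (with
#' \code{p_absent_given_ie = 0}). Writing \code{r} for the state-specific
#' event rate: diagnostic policy targets the mixture
#' \code{(1 - r) * acc0 + r * acc_ie}; the hypothetical strategy with the
#' oracle imputer targets \code{acc0}; setback targets \code{(1 - r) *
#' acc0}; the indicative-positive rule targets \code{(1 - r) * sens0 + r}
#' for sensitivity and \code{(1 - r) * spec0} for specificity (mirrored
#' for the negative rule); the principal strata target \code{acc0} and
#' \code{acc_ie}; while-under-monitoring targets
#' \code{(1 - r) * acc0 + r * partial_acc}.
#'
#' @param params a \code{\link{simulation_params}} object.
#' @return data frame: strategy, measure, target.
#' @export
analytic_targets <- function(params) {
  rd <- params$ie_rate_diseased
  rh <- params$ie_rate_healthy
  rows <- rbind(
    c("diagnostic_policy",
      (1 - rd) * params$sens0 + rd * params$sens_ie,
      (1 - rh) * params$spec0 + rh * params$spec_ie),
    c("hypothetical", params$sens0, params$spec0),
    c("while_under_monitoring",
      (1 - rd) * params$sens0 + rd * params$partial_sens,
      (1 - rh) * params$spec0 + rh * params$partial_spec),
    c("principal_stratum_event_free", params$sens0, params$spec0),
    c("principal_stratum_event_affected", params$sens_ie, params$spec_ie),
    c("indicative_event_positive", (1 - rd) * params$sens0 + rd,
      (1 - rh) * params$spec0),
    c("indicative_event_negative", (1 - rd) * params$sens0,
      (1 - rh) * params$spec0 + rh),
    c("setback", (1 - rd) * params$sens0, (1 - rh) * params$spec0))
  data.frame(strategy = rows[, 1],
             sensitivity = as.numeric(rows[, 2]),
             specificity = as.numeric(rows[, 3]),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo recovery experiment over strategies
#'
#' Repeatedly simulates studies, analyzes each under every strategy
#' configuration of \code{\link{sweep_strategies}}, and summarizes bias and
#' RMSE of the combined sensitivity and specificity against the
#' \code{\link{analytic_targets}} of the data-generating model.
#'
#' @param params a \code{\link{simulation_params}} object; per-replicate
#'   seeds are derived from \code{seed}.
#' @param replicates number of simulated studies, \code{>= 1}.
#' @param seed integer master seed.
#' @return data frame: strategy, measure, mean_estimate, target, bias,
#'   rmse, mc_se (Monte-Carlo standard error of the mean estimate).
#' @export
strategy_recovery_experiment <- function(params, replicates = 100,
                                         seed = 1L) {
  stopifnot(replicates >= 1)
  seeds <- withr::with_seed(as.integer(seed), {
    sample.int(.Machine$integer.max, replicates)
  })
  ests <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    p <- params
    p$seed <- seeds[r]
    sw <- sweep_strategies(simulate_study(p))
    ests[[r]] <- data.frame(strategy = sw$strategy,
                            sensitivity = sw$sensitivity,
                            specificity = sw$specificity,
                            stringsAsFactors = FALSE)
  }
  tg <- analytic_targets(params)
  out <- do.call(rbind, lapply(c("sensitivity", "specificity"), function(m) {
    per <- sapply(ests, function(e) e[[m]][match(tg$strategy, e$strategy)])
    per <- matrix(per, nrow = nrow(tg))
    data.frame(
      strategy = tg$strategy, measure = m,
      mean_estimate = rowMeans(per, na.rm = TRUE),
      target = tg[[m]],
      bias = rowMeans(per, na.rm = TRUE) - tg[[m]],
      rmse = sqrt(rowMeans((per - tg[[m]])^2, na.rm = TRUE)),
      mc_se = apply(per, 1, stats::sd, na.rm = TRUE) / sqrt(replicates),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
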