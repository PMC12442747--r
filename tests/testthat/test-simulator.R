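# The synthetic study generator and the Monte-Carlo recovery experiment.

test_that("simulation is deterministic given the seed", {
  p <- simulation_params(n = 500, seed = 123)
  expect_identical(simulate_study(p), simulate_study(p))
  p2 <- simulation_params(n = 500, seed = 124)
  expect_false(identical(simulate_study(p), simulate_study(p2)))
})

test_that("parameter validation catches impossible settings", {
  expect_error(simulation_params(prevalence = 1.2), "probability")
  expect_error(simulation_params(n = 0), "n must be")
})

test_that("without events the study recovers baseline accuracy within 3 SE", {
  p <- simulation_params(n = 10000, ie_rate_diseased = 0,
                         ie_rate_healthy = 0, seed = 11)
  rec <- simulate_study(p)
  expect_false(any(event_occurred(rec, "ie")))
  expect_identical(rec$index_result, rec$counterfactual_result)
  dis <- rec$true_condition == "diseased"
  sens_hat <- mean(rec$index_result[dis] == "positive")
  spec_hat <- mean(rec$index_result[!dis] == "negative")
  expect_lt(abs(sens_hat - p$sens0),
            3 * sqrt(p$sens0 * (1 - p$sens0) / sum(dis)))
  expect_lt(abs(spec_hat - p$spec0),
            3 * sqrt(p$spec0 * (1 - p$spec0) / sum(!dis)))
})

test_that("per-stratum accuracies converge to their generating values", {
  p <- simulation_params(n = 20000, seed = 21)
  rec <- simulate_study(p)
  occ <- event_occurred(rec, "ie")
  dis <- rec$true_condition == "diseased"
  check <- function(sel, target, what) {
    n <- sum(sel)
    hat <- mean(ifelse(dis[sel], rec$index_result[sel] == "positive",
                       rec$index_result[sel] == "negative"))
    expect_lt(abs(hat - target), 3 * sqrt(target * (1 - target) / n),
              label = what)
  }
  check(dis & !occ, p$sens0, "sens0")
  check(dis & occ, p$sens_ie, "sens_ie")
  check(!dis & !occ, p$spec0, "spec0")
  check(!dis & occ, p$spec_ie, "spec_ie")
  # event rates are state-specific
  expect_lt(abs(mean(occ[dis]) - p$ie_rate_diseased),
            3 * sqrt(p$ie_rate_diseased * (1 - p$ie_rate_diseased) / sum(dis)))
  expect_lt(abs(mean(occ[!dis]) - p$ie_rate_healthy),
            3 * sqrt(p$ie_rate_healthy * (1 - p$ie_rate_healthy) / sum(!dis)))
})

test_that("the default parameters emulate the worked CT study", {
  p <- simulation_params(seed = 42)
  rec <- simulate_study(p)
  expect_equal(nrow(rec), 200)
  cnt <- tabulate_records(rec, "ie")
  # statistically compatible, not exact: totals within loose binomial bands
  expect_lt(abs(sum(cnt$core["diseased", , ]) - 40), 20)
  expect_lt(abs(sum(cnt$core["diseased", "with_ie", ]) -
                  0.6 * sum(cnt$core["diseased", , ])), 15)
})

test_that("absent results appear at the configured conditional rate", {
  p <- simulation_params(n = 8000, p_absent_given_ie = 0.3, seed = 31)
  rec <- simulate_study(p)
  occ <- event_occurred(rec, "ie")
  expect_false(any(rec$index_result[!occ] == "absent"))
  frac <- mean(rec$index_result[occ] == "absent")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / sum(occ)))
  # partial results exist for every affected subject regardless
  expect_true(all(rec$partial_result[occ] %in% c("positive", "negative")))
})

test_that("closed-form targets are internally consistent", {
  p <- simulation_params(seed = 1)
  tg <- analytic_targets(p)
  # degenerate equality: no degradation makes policy and hypothetical targets
  # coincide
  p2 <- simulation_params(sens_ie = p$sens0, spec_ie = p$spec0)
  tg2 <- analytic_targets(p2)
  expect_equal(
    tg2$sensitivity[tg2$strategy == "diagnostic_policy"],
    tg2$sensitivity[tg2$strategy == "hypothetical"])
  # setback with certain events drives sensitivity to zero
  p3 <- simulation_params(ie_rate_diseased = 1)
  tg3 <- analytic_targets(p3)
  expect_equal(tg3$sensitivity[tg3$strategy == "setback"], 0)
  # the policy target is always between setback and indicative-positive
  expect_lte(tg$sensitivity[tg$strategy == "setback"],
             tg$sensitivity[tg$strategy == "diagnostic_policy"])
  expect_lte(tg$sensitivity[tg$strategy == "diagnostic_policy"],
             tg$sensitivity[tg$strategy == "indicative_event_positive"])
})

test_that("the recovery experiment is unbiased for the oracle strategies", {
  p <- simulation_params(n = 1500, seed = 7)
  out <- strategy_recovery_experiment(p, replicates = 30, seed = 77)
  for (m in c("sensitivity", "specificity")) {
    for (s in c("hypothetical", "diagnostic_policy", "setback")) {
      row <- out[out$strategy == s & out$measure == m, ]
      expect_lt(abs(row$bias), 3.5 * row$mc_se,
                label = paste(s, m))
    }
  }
})

test_that("mixture identity holds exactly on every simulated dataset", {
  for (seed in c(13, 14, 15)) {
    sw <- sweep_strategies(simulate_study(random_params(seed, n = 300)))
    dp <- sw[sw$strategy == "diagnostic_policy", ]
    ps1 <- sw[sw$strategy == "principal_stratum_event_free", ]
    ps2 <- sw[sw$strategy == "principal_stratum_event_affected", ]
    expect_equal(dp$sensitivity,
                 (ps1$sens_n * ps1$sensitivity + ps2$sens_n * ps2$sensitivity) /
                   (ps1$sens_n + ps2$sens_n))
    expect_equal(dp$specificity,
                 (ps1$spec_n * ps1$specificity + ps2$spec_n * ps2$specificity) /
                   (ps1$spec_n + ps2$spec_n))
  }
})
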