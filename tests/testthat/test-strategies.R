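# The six event-handling strategies, multi-event resolution, and the
# composite-test view.

test_that("each strategy maps the canonical cases of the worked example", {
  # diseased, positive result, event occurred
  r <- one_record("positive", TRUE)
  expect_identical(apply_diagnostic_policy(r, "ie")$decision, "positive")
  expect_identical(apply_setback(r, "ie")$decision, "negative")
  expect_identical(
    apply_indicative_event(r, "ie", list(fixed_result = "positive"))$decision,
    "positive")
  # non-diseased, negative result, event occurred: setback forces the
  # opposite of the true state
  r <- one_record("negative", TRUE, condition = "non_diseased")
  expect_identical(apply_setback(r, "ie")$decision, "positive")
  expect_identical(
    apply_indicative_event(r, "ie", list(fixed_result = "positive"))$decision,
    "positive")
  # indicative event overrides even an absent result
  r <- one_record("absent", TRUE)
  expect_identical(
    apply_indicative_event(r, "ie", list(fixed_result = "negative"))$decision,
    "negative")
  # absent + diagnostic policy needs an imputer
  expect_error(apply_diagnostic_policy(r, "ie"), "imputer")
  expect_identical(
    apply_diagnostic_policy(
      r, "ie", list(imputer = list(name = "constant",
                                   result = "positive")))$decision,
    "positive")
  # setback with unknown condition needs a reference imputer
  r <- one_record("positive", TRUE, condition = "unknown")
  expect_error(apply_setback(r, "ie"), "true state")
  expect_identical(
    apply_setback(r, "ie", list(imputer = list(name = "constant",
                                               result = "positive")))$decision,
    "negative")
})

test_that("hypothetical and monitoring strategies use counterfactual and partial data", {
  rec <- make_records(
    condition = c("diseased", "diseased", "non_diseased"),
    result = c("negative", "positive", "positive"),
    occurred = c(TRUE, FALSE, TRUE),
    partial = c("positive", "positive", "negative"),
    counterfactual = c("positive", "positive", "negative"))
  hy <- apply_hypothetical(rec, "ie", list(imputer = list(name = "oracle")))
  expect_identical(hy$decision, c("positive", "positive", "negative"))
  wum <- apply_while_under_monitoring(rec, "ie")
  expect_identical(wum$decision, c("positive", "positive", "negative"))
  # monitoring without a pre-event observation period is an error
  rec2 <- make_records("diseased", "positive", TRUE, partial = "absent")
  expect_error(apply_while_under_monitoring(rec2, "ie"),
               "observation period")
  # degenerate imputer: bernoulli p = 1 forces positive
  hy2 <- apply_hypothetical(rec, "ie",
                            list(imputer = list(name = "bernoulli", p = 1)),
                            seed = 1)
  expect_identical(hy2$decision[c(1, 3)], c("positive", "positive"))
  # when partials equal the observed results, monitoring equals policy
  rec3 <- make_records(c("diseased", "non_diseased"),
                       c("positive", "negative"), c(TRUE, TRUE),
                       partial = c("positive", "negative"))
  expect_identical(apply_while_under_monitoring(rec3, "ie")$decision,
                   apply_diagnostic_policy(rec3, "ie")$decision)
})

test_that("principal stratum selects the analysis set by event occurrence", {
  rec <- ct_example_records()
  free <- apply_principal_stratum(rec, "coughing",
                                  list(stratum = "event_free"))
  free$true_condition <- rec$true_condition
  kept <- free[free$decision != "excluded", ]
  expect_equal(sum(kept$true_condition == "diseased"), 16)
  expect_equal(sum(kept$true_condition == "non_diseased"), 120)
  aff <- apply_principal_stratum(rec, "coughing",
                                 list(stratum = "event_affected"))
  aff$true_condition <- rec$true_condition
  kept <- aff[aff$decision != "excluded", ]
  expect_equal(sum(kept$true_condition == "diseased"), 24)
  expect_equal(sum(kept$true_condition == "non_diseased"), 40)
  expect_identical(unique(free$stratum_membership[free$decision == "excluded"]),
                   "event_affected")
})

test_that("every strategy passes an event-free record through unchanged", {
  results <- c("positive", "negative", "inconclusive")
  for (res in results) {
    r <- make_records("diseased", res, FALSE,
                      counterfactual = if (res == "inconclusive") "positive" else res)
    strategies <- list(
      list("diagnostic_policy", list()),
      list("indicative_event", list(fixed_result = "negative")),
      list("setback", list()),
      list("hypothetical", list(imputer = list(name = "oracle"))),
      list("while_under_monitoring", list()),
      list("principal_stratum", list(stratum = "event_free")))
    for (s in strategies) {
      d <- apply_strategy(r, "ie", s[[1]], s[[2]])
      expect_identical(d$decision, res,
                       label = paste(s[[1]], "on", res))
    }
    # the one exception: the event-affected stratum excludes event-free rows
    d <- apply_strategy(r, "ie", "principal_stratum",
                        list(stratum = "event_affected"))
    expect_identical(d$decision, "excluded")
  }
})

test_that("composite g(I,E) matches the strategy functions on the full truth table", {
  results <- c("positive", "negative", "inconclusive", "absent")
  for (res in results) {
    for (occ in c(FALSE, TRUE)) {
      for (cond in c("diseased", "non_diseased")) {
        r <- one_record(res, occ, condition = cond)
        # indicative event, both rules
        for (fr in c("positive", "negative")) {
          expect_identical(
            composite_decision(res, occ, "indicative_event",
                               list(fixed_result = fr)),
            apply_indicative_event(r, "ie",
                                   list(fixed_result = fr))$decision)
        }
        # setback needs the condition as context
        expect_identical(
          composite_decision(res, occ, "setback", condition = cond),
          apply_setback(r, "ie")$decision)
        # diagnostic policy agrees wherever it is applicable
        if (res != "absent") {
          expect_identical(
            composite_decision(res, occ, "diagnostic_policy"),
            apply_diagnostic_policy(r, "ie")$decision)
        } else {
          expect_identical(composite_decision(res, occ, "diagnostic_policy"),
                           "needs_imputation")
        }
      }
    }
  }
  expect_error(composite_decision("positive", TRUE, "hypothetical"),
               "arg")
})

test_that("multi-event resolution picks the earliest or highest-priority event", {
  df <- data.frame(subject_id = c("a", "b", "c"),
                   true_condition = "diseased",
                   index_result = "positive",
                   ie_A = c(TRUE, TRUE, FALSE),
                   ie_A_time = c(2, 2, NA),
                   ie_B = c(TRUE, FALSE, FALSE),
                   ie_B_time = c(1, NA, NA),
                   stringsAsFactors = FALSE)
  rec <- subject_table(df)
  gov <- resolve_events(rec, list(policy = "first_event"))
  expect_identical(gov, c("B", "A", NA_character_))
  gov <- resolve_events(rec, list(policy = "priority",
                                  priority = c("A", "B")))
  expect_identical(gov, c("A", "A", NA_character_))

  # missing time or tied times with several occurred events: hard errors
  df$ie_B_time[1] <- NA
  expect_error(resolve_events(subject_table(df), list(policy = "first_event")),
               "missing event time")
  df$ie_B_time[1] <- 2
  expect_error(resolve_events(subject_table(df), list(policy = "first_event")),
               "tied")
})

test_that("priority resolution maximizes the declared order (brute force, <= 4 events)", {
  types <- c("w", "x", "y", "z")
  withr::with_seed(42, {
    for (k in 1:20) {
      occ <- stats::runif(4) < 0.6
      if (!any(occ)) occ[1] <- TRUE
      prio <- sample(types)
      df <- data.frame(subject_id = "s1", true_condition = "diseased",
                       index_result = "positive", stringsAsFactors = FALSE)
      for (i in seq_along(types)) df[[paste0("ie_", types[i])]] <- occ[i]
      gov <- resolve_events(subject_table(df),
                            list(policy = "priority", priority = prio))
      # oracle: enumerate occurred events, take the one ranked best
      occurred <- types[occ]
      oracle <- occurred[which.min(match(occurred, prio))]
      expect_identical(gov, oracle)
    }
  })
})

test_that("simulated multi-event studies resolve deterministically", {
  rec <- simulate_multi_events(200, c(a = 0.3, b = 0.3, c = 0.2), seed = 9)
  gov <- resolve_events(rec, list(policy = "first_event"))
  occ_any <- event_occurred(rec, "a") | event_occurred(rec, "b") |
    event_occurred(rec, "c")
  expect_identical(is.na(gov), !occ_any)
  # the governing event is the earliest occurred one
  for (i in which(!is.na(gov))) {
    times <- vapply(c("a", "b", "c"), function(t) {
      if (rec[[paste0("ie_", t)]][i]) rec[[paste0("ie_", t, "_time")]][i]
      else Inf
    }, numeric(1))
    expect_identical(gov[i], names(which.min(times)))
  }
})
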