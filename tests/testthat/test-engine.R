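# The estimand engine: full pipeline, condition resolution, validation.

ct_coughing_spec <- function(strategy, options = list(),
                             measures = c("sensitivity", "specificity")) {
  estimand_spec(
    target_condition = "lung_carcinoma",
    accuracy_measures = measures,
    interfering_events = list(
      coughing = list(strategy = strategy, options = options)))
}

test_that("a principal-stratum estimand on the CT study gives the event-free panel", {
  rep <- apply_estimand(ct_example_records(),
                        ct_coughing_spec("principal_stratum",
                                         list(stratum = "event_free")))
  expect_equal(rep$measures$sensitivity$estimate, 12 / 16)
  expect_equal(rep$measures$sensitivity$denominator, 16)
  expect_equal(rep$measures$specificity$estimate, 110 / 120)
  expect_equal(rep$n_excluded, 64)
  # subject conservation: analyzed + excluded + held-out = input
  expect_equal(rep$n_included + rep$n_excluded + rep$n_inconclusive,
               rep$n_input)
})

test_that("a spec with no declared events reduces to plain accuracy", {
  rec <- make_records(
    condition = rep(c("diseased", "non_diseased"), c(10, 20)),
    result = c(rep("positive", 8), rep("negative", 2),
               rep("negative", 17), rep("positive", 3)),
    occurred = rep(FALSE, 30))
  spc <- estimand_spec(target_condition = "x")
  rep <- apply_estimand(rec, spc)
  expect_equal(rep$measures$sensitivity$estimate, 0.8)
  expect_equal(rep$measures$specificity$estimate, 17 / 20)
  expect_equal(rep$n_excluded, 0)
})

test_that("the engine sweep across strategies reproduces the published rows", {
  rec <- ct_example_records()
  configs <- list(
    diagnostic_policy = list("diagnostic_policy", list(), 28 / 40, 144 / 160),
    hypothetical = list("hypothetical", list(imputer = "oracle"),
                        30 / 40, 147 / 160),
    while_under_monitoring = list("while_under_monitoring", list(),
                                  24 / 40, 138 / 160),
    ps_free = list("principal_stratum", list(stratum = "event_free"),
                   12 / 16, 110 / 120),
    ps_affected = list("principal_stratum", list(stratum = "event_affected"),
                       16 / 24, 34 / 40),
    ie_pos = list("indicative_event", list(fixed_result = "positive"),
                  36 / 40, 110 / 160),
    ie_neg = list("indicative_event", list(fixed_result = "negative"),
                  12 / 40, 150 / 160),
    setback = list("setback", list(), 12 / 40, 110 / 160))
  for (nm in names(configs)) {
    cf <- configs[[nm]]
    rep <- apply_estimand(rec, ct_coughing_spec(cf[[1]], cf[[2]]))
    expect_equal(rep$measures$sensitivity$estimate, cf[[3]], label = nm)
    expect_equal(rep$measures$specificity$estimate, cf[[4]], label = nm)
  }
})

test_that("the packaged CT estimand runs end to end with mixed strategies", {
  spec <- read_estimand_spec(system.file("extdata", "ct_estimand.yaml",
                                         package = "dxestimand"))
  # a study realizing the spec's three declared events: the worked records
  # with the event read as arrhythmical breathing, plus a couple of
  # affected subjects for the other two strategies
  df <- as.data.frame(ct_example_records())
  names(df)[names(df) == "ie_coughing"] <- "ie_arrhythmical_breathing"
  df$ie_early_termination <- FALSE
  df$ie_claustrophobic_seizure <- FALSE
  # one event-free diseased subject terminates early (indicative positive),
  # one event-free healthy subject has a seizure (hypothetical oracle)
  free_d <- which(!df$ie_arrhythmical_breathing &
                    df$true_condition == "diseased" &
                    df$index_result == "negative")[1]
  free_h <- which(!df$ie_arrhythmical_breathing &
                    df$true_condition == "non_diseased" &
                    df$index_result == "positive")[1]
  df$ie_early_termination[free_d] <- TRUE
  df$index_result[free_d] <- "absent"
  df$partial_result[free_d] <- "absent"
  df$ie_claustrophobic_seizure[free_h] <- TRUE
  df$counterfactual_result[free_h] <- "negative"
  rec <- subject_table(df)
  rep <- apply_estimand(rec, spec)
  # arrhythmical breathing excludes its 64 affected subjects (event-free
  # principal stratum); the early termination flips one diseased negative
  # to positive (13/16); the seizure's oracle counterfactual restores one
  # healthy false positive (111/120)
  expect_equal(rep$n_excluded, 64)
  expect_equal(rep$measures$sensitivity$estimate, 13 / 16)
  expect_equal(rep$measures$specificity$estimate, 111 / 120)
  expect_match(rep$limitations, "reference standard")
  aud <- rep$audit
  expect_identical(aud$strategy[free_d], "indicative_event")
  expect_identical(aud$strategy[free_h], "hypothetical")
  expect_true(aud$imputed[free_h])
})

test_that("a principal-stratum panel of the worked study: event-free sensitivity is 75%", {
  spec <- read_estimand_spec(system.file("extdata", "ct_estimand.yaml",
                                         package = "dxestimand"))
  df <- as.data.frame(ct_example_records())
  names(df)[names(df) == "ie_coughing"] <- "ie_arrhythmical_breathing"
  rep <- apply_estimand(subject_table(df), spec)
  expect_equal(rep$measures$sensitivity$estimate, 0.75)
  expect_equal(rep$measures$sensitivity$numerator, 12)
  expect_equal(rep$measures$sensitivity$denominator, 16)
})

test_that("the audit log traces every decision to its strategy", {
  rep <- apply_estimand(ct_example_records(),
                        ct_coughing_spec("indicative_event",
                                         list(fixed_result = "positive")))
  audit <- rep$audit
  expect_equal(nrow(audit), 200)
  affected <- audit[!is.na(audit$governing_event), ]
  expect_equal(nrow(affected), 64)
  expect_true(all(affected$strategy == "indicative_event"))
  expect_true(all(affected$source == "indicative_event:positive"))
  expect_true(all(audit$decision[is.na(audit$governing_event)] %in%
                    c("positive", "negative")))
})

test_that("identical inputs and seed give byte-identical reports", {
  p <- random_params(3, n = 100)
  p$p_absent_given_ie <- 0.4
  rec <- simulate_study(p)
  spc <- estimand_spec(
    interfering_events = list(
      ie = list(strategy = "diagnostic_policy",
                options = list(imputer = list(name = "bernoulli", p = 0.5)))))
  opts <- engine_options(seed = 99)
  r1 <- report_to_json(apply_estimand(rec, spc, opts))
  r2 <- report_to_json(apply_estimand(rec, spc, opts))
  expect_identical(r1, r2)
})

test_that("population filters act before event handling", {
  rec <- simulate_study(random_params(4, n = 120))
  df <- as.data.frame(rec)
  df$age <- rep(c(25, 45), length.out = nrow(df))
  rec <- subject_table(df)
  spc <- estimand_spec(
    population = list(description = "over 30", filter = "age >= 30"),
    interfering_events = list(ie = list(strategy = "diagnostic_policy")))
  rep <- apply_estimand(rec, spc)
  expect_equal(rep$n_excluded, sum(df$age < 30))
  expect_equal(rep$measures$sensitivity$denominator,
               sum(df$age >= 30 & df$true_condition == "diseased"))
})

test_that("reference-standard resolution maps, excludes, or imputes", {
  df <- data.frame(
    subject_id = sprintf("r%02d", 1:6),
    reference_result = c("positive", "negative", "inconclusive",
                         "absent", "positive", "negative"),
    index_result = "positive",
    stringsAsFactors = FALSE)
  rec <- subject_table(df)
  rc <- resolve_condition(rec, "reference_result")
  expect_identical(rc$records$true_condition[1:2],
                   c("diseased", "non_diseased"))
  expect_setequal(rc$excluded_ids, c("r03", "r04"))
  expect_match(rc$warnings, "bias")

  # bernoulli imputation recovers the prevalence within 3 binomial SE
  big <- subject_table(data.frame(
    subject_id = sprintf("b%05d", 1:10000),
    reference_result = "absent",
    index_result = "negative",
    stringsAsFactors = FALSE))
  rc <- resolve_condition(big, "reference_result",
                          engine_options(reference_missing = "impute_bernoulli",
                                         prevalence = 0.2, seed = 5))
  phat <- mean(rc$records$true_condition == "diseased")
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # identity when all references are conclusive
  clean <- subject_table(data.frame(
    subject_id = "x1", reference_result = "positive",
    index_result = "positive", stringsAsFactors = FALSE))
  expect_identical(resolve_condition(clean, "reference_result")$excluded_ids,
                   character())
})

test_that("the three imputation prohibitions are hard validation errors", {
  # 1. imputing into the event-free principal stratum
  spc <- estimand_spec(interfering_events = list(
    ev = list(strategy = "principal_stratum",
              options = list(stratum = "event_free",
                             imputer = list(name = "constant",
                                            result = "positive")))))
  expect_length(validate_imputation_plan(spc), 1)
  expect_match(validate_imputation_plan(spc), "stratum")
  rec <- make_records("diseased", "positive", FALSE, event_type = "ev")
  expect_error(apply_estimand(rec, spc), "imputation plan")

  # 2. imputing index results outside the sensitivity denominator
  spc <- estimand_spec(
    accuracy_measures = "sensitivity",
    interfering_events = list(
      ev = list(strategy = "diagnostic_policy",
                options = list(imputer = list(name = "constant",
                                              result = "positive",
                                              scope = "all")))))
  expect_match(validate_imputation_plan(spc), "denominator")
  expect_error(apply_estimand(rec, spc), "imputation plan")
  # scoped to the diseased it is legitimate
  spc_ok <- estimand_spec(
    accuracy_measures = "sensitivity",
    interfering_events = list(
      ev = list(strategy = "diagnostic_policy",
                options = list(imputer = list(name = "constant",
                                              result = "positive",
                                              scope = "diseased")))))
  expect_length(validate_imputation_plan(spc_ok), 0)

  # 3. imputing the reference only for index-positives when PPV is targeted
  spc <- estimand_spec(accuracy_measures = c("sensitivity", "specificity",
                                             "ppv"))
  opts <- engine_options(reference_missing = "impute_bernoulli",
                         reference_impute_scope = "index_positive",
                         prevalence = 0.2)
  expect_match(validate_imputation_plan(spc, opts), "verification")

  # a spec with no imputers is clean
  expect_length(validate_imputation_plan(estimand_spec()), 0)
})

test_that("unresolved absences and undeclared events are hard errors", {
  rec <- make_records("diseased", "absent", FALSE)
  spc <- estimand_spec()
  expect_error(apply_estimand(rec, spc), "unresolved")
  rec2 <- make_records("diseased", "positive", TRUE, event_type = "surprise")
  expect_error(apply_estimand(rec2, spc), "surprise")
})

test_that("derived measures ride along in the report", {
  spc <- ct_coughing_spec("diagnostic_policy",
                          measures = c("sensitivity", "specificity",
                                       "youden", "lr_positive", "ppv",
                                       "npv"))
  rep <- apply_estimand(ct_example_records(), spc,
                        engine_options(prevalence = 0.2))
  expect_equal(rep$measures$youden, 0.7 + 0.9 - 1)
  expect_equal(rep$measures$lr_positive, 0.7 / 0.1)
  expect_equal(rep$measures$ppv, 0.7 * 0.2 / (0.7 * 0.2 + 0.1 * 0.8))
})
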