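# Shared generators for the test suite. Everything is built in code under
# explicit seeds; no stored binary fixtures.

# a random 2x2x2 stratified count table with strictly positive cells (so
# every stratum denominator is defined)
random_counts <- function(seed, max_cell = 60) {
  withr::with_seed(seed, {
    v <- sample.int(max_cell, 8, replace = TRUE)
    stratified_counts(
      d_pos_noie = v[1], d_neg_noie = v[2], d_pos_ie = v[3], d_neg_ie = v[4],
      h_pos_noie = v[5], h_neg_noie = v[6], h_pos_ie = v[7], h_neg_ie = v[8])
  })
}

# a small subject table built from explicit vectors
make_records <- function(condition, result, occurred,
                         partial = NULL, counterfactual = NULL,
                         event_type = "ie") {
  n <- length(result)
  df <- data.frame(
    subject_id = sprintf("t%03d", seq_len(n)),
    true_condition = condition,
    index_result = result,
    stringsAsFactors = FALSE)
  if (!is.null(partial)) df$partial_result <- partial
  if (!is.null(counterfactual)) df$counterfactual_result <- counterfactual
  df[[paste0("ie_", event_type)]] <- occurred
  subject_table(df)
}

# one-row record for truth-table comparisons
one_record <- function(result, occurred, condition = "diseased",
                       counterfactual = NULL) {
  make_records(condition, result, occurred,
               partial = if (result == "inconclusive") "absent" else NULL,
               counterfactual = counterfactual)
}

# random simulation parameters with non-degenerate accuracies and rates
random_params <- function(seed, n = 400) {
  withr::with_seed(seed, {
    simulation_params(
      n = n,
      prevalence = stats::runif(1, 0.15, 0.5),
      sens0 = stats::runif(1, 0.6, 0.95),
      spec0 = stats::runif(1, 0.6, 0.95),
      ie_rate_diseased = stats::runif(1, 0.1, 0.7),
      ie_rate_healthy = stats::runif(1, 0.1, 0.7),
      sens_ie = stats::runif(1, 0.3, 0.9),
      spec_ie = stats::runif(1, 0.3, 0.9),
      partial_sens = stats::runif(1, 0.3, 0.9),
      partial_spec = stats::runif(1, 0.3, 0.9),
      seed = seed)
  })
}
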