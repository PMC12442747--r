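# The worked CT-scan study: 200 subjects suspected of lung carcinoma, one
# interfering event (coughing during the scan). Observed results give the
# published two-way tables; counterfactual and partial results encode the
# study's stated assumptions for the hypothetical and while-under-monitoring
# strategies (accuracy similar across strata had the event not occurred;
# degraded accuracy from pre-event partial data). All values are notional.

#' Subject records for the worked CT-scan example study
#'
#' Builds, in code, the 200-subject lung-carcinoma CT study used throughout
#' the documentation: 40 diseased (12 positive / 4 negative without the
#' coughing event; 16 / 8 with it) and 160 non-diseased (10 / 110 without;
#' 6 / 34 with). Counterfactual results are set so that 18 of 24 diseased
#' and 37 of 40 healthy event-affected subjects would have been classified
#' correctly had coughing not occurred; partial (pre-event) results so that
#' 12 of 24 and 28 of 40 are classified correctly from pre-event data.
#'
#' @return a \code{\link{subject_table}} of 200 records with event type
#'   \code{coughing}, counterfactual and partial results filled in.
#' @seealso \code{\link{ct_example_counts}},
#'   \code{\link{read_estimand_spec}} with the packaged
#'   \code{ct_estimand.yaml}.
#' @export
ct_example_records <- function() {
  blocks <- list(
    # diseased, no event: 12 positive, 4 negative
    list(dis = "diseased", ie = FALSE, obs = c("positive", "negative"),
         n = c(12, 4), cf = NULL, part = NULL),
    # diseased, event: observed 16/8; counterfactual 18 correct (positive);
    # partial 12 correct
    list(dis = "diseased", ie = TRUE, obs = c("positive", "negative"),
         n = c(16, 8), cf = c(pos = 18), part = c(pos = 12)),
    # non-diseased, no event: 10 positive, 110 negative
    list(dis = "non_diseased", ie = FALSE, obs = c("positive", "negative"),
         n = c(10, 110), cf = NULL, part = NULL),
    # non-diseased, event: observed 6/34; counterfactual 37 correct
    # (negative); partial 28 correct
    list(dis = "non_diseased", ie = TRUE, obs = c("positive", "negative"),
         n = c(6, 34), cf = c(neg = 37), part = c(neg = 28))
  )
  out <- list()
  for (b in blocks) {
    nb <- sum(b$n)
    obs <- rep(b$obs, b$n)
    if (b$ie) {
      correct <- if (b$dis == "diseased") "positive" else "negative"
      wrong <- setdiff(c("positive", "negative"), correct)
      n_cf <- unname(b$cf)
      n_pt <- unname(b$part)
      cf <- c(rep(correct, n_cf), rep(wrong, nb - n_cf))
      part <- c(rep(correct, n_pt), rep(wrong, nb - n_pt))
    } else {
      cf <- obs
      part <- obs
    }
    out[[length(out) + 1L]] <- data.frame(
      true_condition = b$dis, index_result = obs, partial_result = part,
      counterfactual_result = cf, ie_coughing = b$ie,
      stringsAsFactors = FALSE)
  }
  x <- do.call(rbind, out)
  x <- cbind(subject_id = sprintf("ct%03d", seq_len(nrow(x))), x,
             stringsAsFactors = FALSE)
  x$reference_result <- ifelse(x$true_condition == "diseased",
                               "positive", "negative")
  subject_table(x)
}

#' Stratified counts for the worked CT-scan example
#'
#' The two published two-way tables of the example study as a
#' \code{\link{stratified_counts}} object (event type \code{coughing}).
#'
#' @return a \code{stratified_counts} object with 200 subjects.
#' @export
ct_example_counts <- function() {
  stratified_counts(
    d_pos_noie = 12, d_neg_noie = 4, d_pos_ie = 16, d_neg_ie = 8,
    h_pos_noie = 10, h_neg_noie = 110, h_pos_ie = 6, h_neg_ie = 34,
    event_type = "coughing")
}

#' Corrected event-stratum counts assumed by the CT example
#'
#' Numbers of event-affected subjects classified correctly under the
#' hypothetical scenario (no coughing) and from pre-event partial data,
#' used by counts-only strategy sweeps.
#'
#' @return named list with elements \code{hypothetical} and
#'   \code{while_under_monitoring}, each \code{c(diseased_correct = ,
#'   non_diseased_correct = )}.
#' @export
ct_example_corrections <- function() {
  list(hypothetical = c(diseased_correct = 18, non_diseased_correct = 37),
       while_under_monitoring = c(diseased_correct = 12,
                                  non_diseased_correct = 28))
}
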