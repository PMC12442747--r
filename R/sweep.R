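# Strategy sweep: the same study analyzed under each of the eight
# single-event strategy configurations (diagnostic policy; hypothetical;
# while-under-monitoring; the two principal strata; indicative event with
# positive and with negative rule; setback), reported as per-stratum
# fractions and combined sensitivity/specificity. Runs on subject-level
# records (hypothetical via the oracle counterfactual, monitoring via the
# stored partial result) or directly on stratified counts, where the
# hypothetical and monitoring rows need user-supplied corrected counts.

sweep_strategy_labels <- function() {
  c(diagnostic_policy = "DP", hypothetical = "HY",
    while_under_monitoring = "WUM",
    principal_stratum_event_free = "PS1",
    principal_stratum_event_affected = "PS2",
    indicative_event_positive = "IE+", indicative_event_negative = "IE-",
    setback = "SB")
}

#' Compare all eight strategy configurations on one study
#'
#' Computes, for each strategy configuration, the number of correctly
#' classified subjects per interfering-event stratum and the combined
#' sensitivity and specificity.
#'
#' @param x a \code{\link{subject_table}} (with counterfactual and partial
#'   results for the hypothetical and while-under-monitoring rows) or a
#'   \code{\link{stratified_counts}} object.
#' @param event_type event type to sweep over (defaults to the single
#'   declared type).
#' @param corrections counts input only: named list as returned by
#'   \code{\link{ct_example_corrections}} giving, for the hypothetical and
#'   while-under-monitoring rows, the corrected numbers of event-affected
#'   subjects classified correctly. Rows whose corrections are missing are
#'   omitted.
#' @param ... unused.
#' @return a data frame of class \code{strategy_sweep}: one row per
#'   strategy with numerators/denominators per stratum and combined, and
#'   \code{sensitivity}/\code{specificity} as proportions.
#' @examples
#' sweep_strategies(ct_example_counts(),
#'                  corrections = ct_example_corrections())
#' @export
sweep_strategies <- function(x, ...) UseMethod("sweep_strategies")

sweep_row <- function(strategy, d_no, d_no_n, d_ie, d_ie_n,
                      h_no, h_no_n, h_ie, h_ie_n) {
  data.frame(
    strategy = strategy, label = unname(sweep_strategy_labels()[strategy]),
    sens_correct_without = d_no, sens_n_without = d_no_n,
    sens_correct_with = d_ie, sens_n_with = d_ie_n,
    sens_correct = d_no + d_ie, sens_n = d_no_n + d_ie_n,
    sensitivity = (d_no + d_ie) / (d_no_n + d_ie_n),
    spec_correct_without = h_no, spec_n_without = h_no_n,
    spec_correct_with = h_ie, spec_n_with = h_ie_n,
    spec_correct = h_no + h_ie, spec_n = h_no_n + h_ie_n,
    specificity = (h_no + h_ie) / (h_no_n + h_ie_n),
    stringsAsFactors = FALSE)
}

#' @rdname sweep_strategies
#' @export
sweep_strategies.stratified_counts <- function(x, corrections = list(), ...) {
  if (any(x$overflow > 0)) {
    stop("counts-only sweep requires conclusive results only; found ",
         "inconclusive/absent overflow counts", call. = FALSE)
  }
  co <- x$core
  d_no_n <- sum(co["diseased", "without_ie", ])
  d_ie_n <- sum(co["diseased", "with_ie", ])
  h_no_n <- sum(co["non_diseased", "without_ie", ])
  h_ie_n <- sum(co["non_diseased", "with_ie", ])
  d_no <- co["diseased", "without_ie", "positive"]
  d_ie <- co["diseased", "with_ie", "positive"]
  h_no <- co["non_diseased", "without_ie", "negative"]
  h_ie <- co["non_diseased", "with_ie", "negative"]

  rows <- list(
    sweep_row("diagnostic_policy", d_no, d_no_n, d_ie, d_ie_n,
              h_no, h_no_n, h_ie, h_ie_n))
  if (!is.null(corrections$hypothetical)) {
    cc <- corrections$hypothetical
    rows <- c(rows, list(sweep_row("hypothetical", d_no, d_no_n,
                                   unname(cc["diseased_correct"]), d_ie_n,
                                   h_no, h_no_n,
                                   unname(cc["non_diseased_correct"]),
                                   h_ie_n)))
  }
  if (!is.null(corrections$while_under_monitoring)) {
    cc <- corrections$while_under_monitoring
    rows <- c(rows, list(sweep_row("while_under_monitoring", d_no, d_no_n,
                                   unname(cc["diseased_correct"]), d_ie_n,
                                   h_no, h_no_n,
                                   unname(cc["non_diseased_correct"]),
                                   h_ie_n)))
  }
  rows <- c(rows, list(
    sweep_row("principal_stratum_event_free", d_no, d_no_n, 0, 0,
              h_no, h_no_n, 0, 0),
    sweep_row("principal_stratum_event_affected", 0, 0, d_ie, d_ie_n,
              0, 0, h_ie, h_ie_n),
    sweep_row("indicative_event_positive", d_no, d_no_n, d_ie_n, d_ie_n,
              h_no, h_no_n, 0, h_ie_n),
    sweep_row("indicative_event_negative", d_no, d_no_n, 0, d_ie_n,
              h_no, h_no_n, h_ie_n, h_ie_n),
    sweep_row("setback", d_no, d_no_n, 0, d_ie_n,
              h_no, h_no_n, 0, h_ie_n)))
  out <- do.call(rbind, rows)
  attr(out, "event_type") <- x$event_type
  class(out) <- c("strategy_sweep", "data.frame")
  out
}

#' @rdname sweep_strategies
#' @export
sweep_strategies.subject_table <- function(x, event_type = NULL, ...) {
  types <- event_types(x)
  if (is.null(event_type)) {
    if (length(types) != 1L) {
      stop("event_type must be named when several event types are declared",
           call. = FALSE)
    }
    event_type <- types
  }
  occ <- event_occurred(x, event_type)
  configs <- list(
    diagnostic_policy = list(strategy = "diagnostic_policy",
                             options = list()),
    hypothetical = list(strategy = "hypothetical",
                        options = list(imputer = list(name = "oracle"))),
    while_under_monitoring = list(strategy = "while_under_monitoring",
                                  options = list()),
    principal_stratum_event_free = list(
      strategy = "principal_stratum", options = list(stratum = "event_free")),
    principal_stratum_event_affected = list(
      strategy = "principal_stratum",
      options = list(stratum = "event_affected")),
    indicative_event_positive = list(
      strategy = "indicative_event",
      options = list(fixed_result = "positive")),
    indicative_event_negative = list(
      strategy = "indicative_event",
      options = list(fixed_result = "negative")),
    setback = list(strategy = "setback", options = list()))
  # hypothetical needs counterfactuals, monitoring needs partials; skip a
  # row when the study does not carry what it requires
  if (is.null(x$counterfactual_result) ||
      any(x$counterfactual_result[occ] == "absent")) {
    configs$hypothetical <- NULL
  }
  if (any(x$partial_result[occ] == "absent")) {
    configs$while_under_monitoring <- NULL
  }
  rows <- lapply(names(configs), function(nm) {
    cf <- configs[[nm]]
    dec <- apply_strategy(x, event_type, cf$strategy, cf$options)
    dec$true_condition <- x$true_condition
    keep <- dec$decision != "excluded"
    correct <- dec$decision == ifelse(dec$true_condition == "diseased",
                                      "positive", "negative")
    cell <- function(cond, with_ie, what) {
      sel <- keep & dec$true_condition == cond & occ == with_ie
      if (what == "n") sum(sel) else sum(sel & correct)
    }
    sweep_row(nm,
              cell("diseased", FALSE, "correct"), cell("diseased", FALSE, "n"),
              cell("diseased", TRUE, "correct"), cell("diseased", TRUE, "n"),
              cell("non_diseased", FALSE, "correct"),
              cell("non_diseased", FALSE, "n"),
              cell("non_diseased", TRUE, "correct"),
              cell("non_diseased", TRUE, "n"))
  })
  out <- do.call(rbind, rows)
  attr(out, "event_type") <- event_type
  class(out) <- c("strategy_sweep", "data.frame")
  out
}

#' @export
print.strategy_sweep <- function(x, ...) {
  frac <- function(a, b) ifelse(b > 0, paste0(a, "/", b), "-")
  tab <- data.frame(
    Strategy = x$label,
    `Sens w/o IE` = frac(x$sens_correct_without, x$sens_n_without),
    `Sens w/ IE` = frac(x$sens_correct_with, x$sens_n_with),
    `Sens comb` = frac(x$sens_correct, x$sens_n),
    Sensitivity = format_percent(x$sensitivity),
    `Spec w/o IE` = frac(x$spec_correct_without, x$spec_n_without),
    `Spec w/ IE` = frac(x$spec_correct_with, x$spec_n_with),
    `Spec comb` = frac(x$spec_correct, x$spec_n),
    Specificity = format_percent(x$specificity),
    check.names = FALSE)
  cat("Strategy comparison (event:", attr(x, "event_type"), ")\n")
  print(tab, row.names = FALSE)
  invisible(x)
}
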