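# Controlled vocabularies shared across the package. "absent" models a test
# decision that never came into being (e.g., scan terminated by an event);
# "inconclusive" models an existing result that classifies neither positive
# nor negative (intermediate or uninterpretable). The two are never conflated.

#' Result and condition vocabularies
#'
#' Fixed vocabularies used throughout the package. Test results take values
#' \code{positive}, \code{negative}, \code{inconclusive}, \code{absent};
#' true condition takes \code{diseased}, \code{non_diseased}, \code{unknown}.
#' Derived per-subject decisions additionally allow \code{excluded} (subject
#' outside the analysis set) and \code{needs_imputation} (an absent result
#' that no strategy or imputer has yet resolved).
#'
#' @name vocabularies
#' @keywords internal
NULL

result_levels <- function() c("positive", "negative", "inconclusive", "absent")
partial_levels <- function() c("positive", "negative", "absent")
condition_levels <- function() c("diseased", "non_diseased", "unknown")
decision_levels <- function() {
  c("positive", "negative", "inconclusive", "excluded", "needs_imputation")
}
strategy_names <- function() {
  c("diagnostic_policy", "indicative_event", "setback",
    "hypothetical", "while_under_monitoring", "principal_stratum")
}
measure_names <- function() {
  c("sensitivity", "specificity", "youden", "lr_positive", "lr_negative",
    "ppv", "npv")
}

check_vocab <- function(x, allowed, what, where = NULL) {
  bad <- !(x %in% allowed) & !is.na(x)
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf(
      "invalid %s token %s at %s %s (allowed: %s)",
      what, paste(sQuote(unique(x[bad])), collapse = ", "),
      if (is.null(where)) "position" else where,
      paste(utils::head(rows, 5L), collapse = ", "),
      paste(allowed, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' Format a proportion as a percentage string
#'
#' Rounds to two decimal places and drops trailing zeros, the convention
#' used in the package's strategy-comparison tables (70\%, 91.67\%, 92.88\%).
#'
#' @param p numeric proportion(s) in \[0, 1\].
#' @return character vector like \code{"91.67\%"}.
#' @export
format_percent <- function(p) {
  s <- sprintf("%.2f", round(100 * p, 2))
  s <- sub("\\.$", "", sub("0+$", "", s))
  paste0(s, "%")
}
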