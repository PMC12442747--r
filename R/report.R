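# The accuracy report: point estimates with intervals per requested
# measure, a per-event-stratum breakdown, exclusion/inconclusive accounting,
# and the audit trail tying every altered or excluded subject back to the
# estimand attribute that produced the alteration.

new_accuracy_report <- function(measures, strata, n_input, n_included,
                                n_excluded, n_inconclusive, spec, audit,
                                limitations = character(), warnings = character()) {
  structure(list(
    measures = measures, strata = strata,
    n_input = n_input, n_included = n_included, n_excluded = n_excluded,
    n_inconclusive = n_inconclusive,
    estimand = spec, audit = audit,
    limitations = limitations, warnings = warnings
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 4, ...) {
  cat("Diagnostic accuracy report\n")
  cat("  Subjects: ", x$n_input, " in, ", x$n_included, " analyzed, ",
      x$n_excluded, " excluded, ", x$n_inconclusive,
      " inconclusive held out\n", sep = "")
  for (m in names(x$measures)) {
    mm <- x$measures[[m]]
    if (is.list(mm) && !is.null(mm$estimate)) {
      cat(sprintf("  %-12s %s (%d/%d), %d%% CI %s-%s\n", m,
                  format_percent(mm$estimate), mm$numerator, mm$denominator,
                  round(100 * mm$conf_level),
                  format_percent(mm$ci[1]), format_percent(mm$ci[2])))
    } else if (!is.null(mm) && !is.na(mm)) {
      cat(sprintf("  %-12s %s\n", m, format(mm, digits = digits)))
    }
  }
  if (!is.null(x$strata) && nrow(x$strata)) {
    cat("  Per-stratum breakdown (interfering event):\n")
    print(x$strata, row.names = FALSE)
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  for (l in x$limitations) cat("  limitation: ", l, "\n", sep = "")
  invisible(x)
}

#' Serialize an accuracy report to JSON
#'
#' @param report an \code{accuracy_report}.
#' @param path optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @param include_audit include the per-subject audit log.
#' @return the JSON string (invisibly when written to \code{path}).
#' @export
report_to_json <- function(report, path = NULL, include_audit = TRUE) {
  stopifnot(inherits(report, "accuracy_report"))
  out <- unclass(report)
  out$estimand <- unclass(out$estimand)
  if (!include_audit) out$audit <- NULL
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null", force = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Aligned plain-text accuracy table
#'
#' Renders the per-stratum breakdown of one or more reports (or a
#' \code{\link{sweep_strategies}} result) as an aligned text table with
#' percentages to two decimals.
#'
#' @param x a \code{strategy_sweep} data frame or \code{accuracy_report}.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
format_accuracy_table <- function(x) {
  txt <- utils::capture.output(print(x))
  cat(txt, sep = "\n")
  invisible(txt)
}
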