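# The six interfering-event handling strategies, each a pure transformation
# from (record, event, options) to a derived per-subject decision with
# provenance. Strategies act on the event, never on inconclusiveness: an
# observed inconclusive result passes through untouched and its downstream
# mapping is an engine-level option. An observed absent result with no
# governing rule becomes needs_imputation, which the engine refuses to let
# reach an accuracy estimate.

decision_frame <- function(records, decision, source) {
  data.frame(subject_id = records$subject_id,
             decision = decision,
             source = source,
             stratum_membership = NA_character_,
             stringsAsFactors = FALSE)
}

passthrough_decision <- function(res) {
  ifelse(res == "absent", "needs_imputation", res)
}

#' Diagnostic policy strategy
#'
#' Accepts the occurrence of the interfering event and ignores it: the
#' decision is the observed index result regardless of event occurrence.
#' Absent results (the event left no decision) are routed to the configured
#' imputer; an event that leaves absent results with no imputer configured
#' is a strategy-applicability error, because an event that consistently
#' yields non-existent decisions cannot be handled by this strategy.
#'
#' @param records a \code{\link{subject_table}}.
#' @param event_type declared event type the strategy governs.
#' @param options list; optional \code{imputer} (see
#'   \code{\link{register_imputer}}).
#' @param seed integer seed forwarded to stochastic imputers.
#' @return data frame of derived decisions (subject_id, decision, source,
#'   stratum_membership).
#' @export
apply_diagnostic_policy <- function(records, event_type, options = list(),
                                    seed = NULL) {
  options <- normalize_strategy_options(options)
  out <- decision_frame(records, passthrough_decision(records$index_result),
                        "diagnostic_policy")
  abs_i <- which(records$index_result == "absent")
  if (length(abs_i)) {
    if (is.null(options$imputer)) {
      stop("diagnostic policy: absent index result(s) for subject(s) ",
           paste(utils::head(records$subject_id[abs_i], 5L), collapse = ", "),
           " and no imputer configured; an event that leaves non-existent ",
           "test decisions needs an imputer under this strategy",
           call. = FALSE)
    }
    out$decision[abs_i] <- run_imputer(records[abs_i, , drop = FALSE],
                                       options$imputer, seed)
    out$source[abs_i] <- paste0("diagnostic_policy+imputer:",
                                options$imputer$name)
  }
  out
}

#' Indicative event strategy
#'
#' The event itself carries diagnostic information and becomes part of the
#' decision rule: if the event occurred the decision is the configured
#' \code{fixed_result} (positive or negative), irrespective of the observed
#' index result -- even when that result is absent. Without the event, the
#' observed result passes through.
#'
#' @inheritParams apply_diagnostic_policy
#' @param options list with required \code{fixed_result}
#'   (\code{"positive"} or \code{"negative"}).
#' @export
apply_indicative_event <- function(records, event_type, options, seed = NULL) {
  if (is.null(options$fixed_result)) {
    stop("indicative_event requires options$fixed_result", call. = FALSE)
  }
  occ <- event_occurred(records, event_type)
  dec <- passthrough_decision(records$index_result)
  dec[occ] <- options$fixed_result
  out <- decision_frame(records, dec, "indicative_event")
  out$source[occ] <- paste0("indicative_event:", options$fixed_result)
  out
}

#' Setback strategy
#'
#' The event is penalized: when it occurs, the decision is set to the
#' opposite of the true disease state (a guaranteed misclassification), so
#' accuracy deteriorates as the event frequency rises. Requires the true
#' state for affected subjects; if it is unknown, a reference imputer must
#' be configured, since the strategy needs the true state to assign the
#' misclassification.
#'
#' @inheritParams apply_diagnostic_policy
#' @param options list; optional \code{imputer} for records whose true
#'   condition is unknown (imputes the condition as positive/negative
#'   reference, then misclassifies against it).
#' @export
apply_setback <- function(records, event_type, options = list(),
                          seed = NULL) {
  options <- normalize_strategy_options(options)
  occ <- event_occurred(records, event_type)
  cond <- records$true_condition
  unk <- which(occ & cond == "unknown")
  if (length(unk)) {
    if (is.null(options$imputer)) {
      stop("setback: true condition unknown for affected subject(s) ",
           paste(utils::head(records$subject_id[unk], 5L), collapse = ", "),
           "; the strategy needs the true state (configure a reference ",
           "imputer or resolve the condition first)", call. = FALSE)
    }
    ref <- run_imputer(records[unk, , drop = FALSE], options$imputer, seed)
    cond[unk] <- ifelse(ref == "positive", "diseased", "non_diseased")
  }
  dec <- passthrough_decision(records$index_result)
  dec[occ] <- ifelse(cond[occ] == "diseased", "negative", "positive")
  out <- decision_frame(records, dec, "setback")
  out$source[occ] <- "setback:misclassify"
  out
}

#' Hypothetical strategy
#'
#' Targets accuracy in a scenario where the event cannot occur: for
#' affected subjects the decision is the imputed result had the event not
#' occurred (from baseline values, prevalence, test probability, or -- in
#' simulation -- the stored counterfactual via the \code{oracle} imputer);
#' unaffected subjects pass through.
#'
#' @inheritParams apply_diagnostic_policy
#' @param options list with required \code{imputer}.
#' @export
apply_hypothetical <- function(records, event_type, options, seed = NULL) {
  options <- normalize_strategy_options(options)
  if (is.null(options$imputer)) {
    stop("hypothetical strategy requires an imputer", call. = FALSE)
  }
  occ <- event_occurred(records, event_type)
  dec <- passthrough_decision(records$index_result)
  if (any(occ)) {
    dec[occ] <- run_imputer(records[occ, , drop = FALSE], options$imputer,
                            seed)
  }
  out <- decision_frame(records, dec, "hypothetical")
  out$source[occ] <- paste0("hypothetical+imputer:", options$imputer$name)
  out
}

#' While-under-monitoring strategy
#'
#' For tests with an observation period: only measurements collected before
#' the event are used. Affected subjects are decided from their stored
#' pre-event \code{partial_result} (or a registered \code{partial_rule});
#' post-event values are simply not part of the decision and are not
#' treated as missing. Unaffected subjects pass through.
#'
#' @inheritParams apply_diagnostic_policy
#' @param options list; optional \code{partial_rule}, a function
#'   \code{function(records)} mapping pre-event data to
#'   positive/negative decisions for the affected subset.
#' @export
apply_while_under_monitoring <- function(records, event_type,
                                         options = list(), seed = NULL) {
  occ <- event_occurred(records, event_type)
  dec <- passthrough_decision(records$index_result)
  part <- records$partial_result
  no_part <- which(occ & part == "absent")
  if (length(no_part) && is.null(options$partial_rule)) {
    stop("while_under_monitoring: no pre-event partial result for ",
         "subject(s) ",
         paste(utils::head(records$subject_id[no_part], 5L), collapse = ", "),
         "; this strategy requires an observation period with measurements ",
         "recorded before the event (or a partial_rule)", call. = FALSE)
  }
  if (any(occ)) {
    if (is.null(options$partial_rule)) {
      dec[occ] <- part[occ]
    } else if (is.character(options$partial_rule)) {
      dec[occ] <- run_imputer(records[occ, , drop = FALSE],
                              list(name = options$partial_rule), seed)
    } else {
      dec[occ] <- options$partial_rule(records[occ, , drop = FALSE])
    }
  }
  out <- decision_frame(records, dec, "while_under_monitoring")
  out$source[occ] <- "while_under_monitoring:partial"
  out
}

#' Principal stratum strategy
#'
#' Accuracy within the subpopulation in whom the event would (or would not)
#' occur. Records outside the target stratum are excluded from the analysis
#' set; records inside it pass through with their observed result. Stratum
#' membership is taken from the observed event occurrence.
#'
#' @inheritParams apply_diagnostic_policy
#' @param options list with required \code{stratum}, \code{"event_free"} or
#'   \code{"event_affected"}.
#' @export
apply_principal_stratum <- function(records, event_type, options,
                                    seed = NULL) {
  if (is.null(options$stratum) ||
      !options$stratum %in% c("event_free", "event_affected")) {
    stop("principal_stratum requires options$stratum = 'event_free' or ",
         "'event_affected'", call. = FALSE)
  }
  occ <- event_occurred(records, event_type)
  member <- if (options$stratum == "event_free") !occ else occ
  dec <- passthrough_decision(records$index_result)
  dec[!member] <- "excluded"
  out <- decision_frame(records, dec, "principal_stratum")
  out$stratum_membership <- ifelse(occ, "event_affected", "event_free")
  out$source[!member] <- paste0("principal_stratum:excluded(",
                                options$stratum, ")")
  out
}

#' Apply a named strategy
#'
#' Dispatcher over the six strategy implementations, keyed by the stable
#' strategy vocabulary used in estimand specification files.
#'
#' @inheritParams apply_diagnostic_policy
#' @param strategy one of \code{diagnostic_policy}, \code{indicative_event},
#'   \code{setback}, \code{hypothetical}, \code{while_under_monitoring},
#'   \code{principal_stratum}.
#' @param options strategy options list.
#' @export
apply_strategy <- function(records, event_type, strategy, options = list(),
                           seed = NULL) {
  strategy <- match.arg(strategy, strategy_names())
  fun <- switch(strategy,
    diagnostic_policy = apply_diagnostic_policy,
    indicative_event = apply_indicative_event,
    setback = apply_setback,
    hypothetical = apply_hypothetical,
    while_under_monitoring = apply_while_under_monitoring,
    principal_stratum = apply_principal_stratum)
  fun(records, event_type, options, seed = seed)
}

#' Resolve multiple interfering events to one governing event per subject
#'
#' A subject is assumed to be governed by a single event. When several
#' occurred, the governing one is either the earliest by recorded time
#' (\code{first_event}) or the highest in a declared total priority order
#' (\code{priority}). Ambiguity is an error, never a silent tie-break.
#'
#' @param records a \code{\link{subject_table}}.
#' @param policy list with \code{policy} (\code{"first_event"} or
#'   \code{"priority"}) and \code{priority} (character, highest first), as
#'   stored in an \code{\link{estimand_spec}}.
#' @return character vector: the governing event type per subject, or
#'   \code{NA} when no declared event occurred.
#' @export
resolve_events <- function(records, policy = list(policy = "first_event")) {
  types <- event_types(records)
  n <- nrow(records)
  if (!length(types) || !n) return(rep(NA_character_, n))
  occ <- sapply(types, function(t) event_occurred(records, t))
  occ <- matrix(occ, nrow = n, dimnames = list(NULL, types))
  n_occ <- rowSums(occ)
  gov <- rep(NA_character_, n)
  single <- which(n_occ == 1L)
  if (length(single)) {
    gov[single] <- types[max.col(occ[single, , drop = FALSE] * 1)]
  }
  multi <- which(n_occ > 1L)
  if (!length(multi)) return(gov)

  pol <- policy$policy %||% "first_event"
  if (pol == "first_event") {
    time_of <- function(typ) {
      col <- paste0("ie_", typ, "_time")
      if (col %in% names(records)) records[[col]] else rep(NA_real_, n)
    }
    tm <- sapply(types, time_of)
    tm <- matrix(tm, nrow = n, dimnames = list(NULL, types))
    for (i in multi) {
      ts <- tm[i, occ[i, ]]
      if (anyNA(ts)) {
        stop("first_event policy: missing event time(s) for subject ",
             records$subject_id[i], " with multiple occurred events",
             call. = FALSE)
      }
      if (any(duplicated(ts))) {
        stop("first_event policy: tied event times for subject ",
             records$subject_id[i], "; no silent tie-break", call. = FALSE)
      }
      gov[i] <- names(ts)[which.min(ts)]
    }
  } else if (pol == "priority") {
    prio <- policy$priority %||% character()
    miss <- setdiff(types[colSums(occ[multi, , drop = FALSE]) > 0], prio)
    if (length(miss)) {
      stop("priority policy: no priority rank for event type(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (i in multi) {
      cand <- types[occ[i, ]]
      gov[i] <- prio[min(match(cand, prio))]
    }
  } else {
    stop("unknown multi-event policy ", sQuote(pol), call. = FALSE)
  }
  gov
}

#' Composite-test decision function g(I, E)
#'
#' The diagnostic policy, indicative event, and setback strategies form a
#' family of composite tests whose final decision depends only on the
#' observed index result I and whether the event occurred E. This exposes
#' that family as a pure truth-table function; it agrees with the
#' corresponding \code{apply_*} on a minimal record.
#'
#' @param index_result character vector over
#'   positive/negative/inconclusive/absent.
#' @param event_occurred logical vector.
#' @param strategy one of \code{diagnostic_policy}, \code{indicative_event},
#'   \code{setback}.
#' @param options options for the strategy (e.g. \code{fixed_result}).
#' @param condition true condition, required by \code{setback}
#'   (diseased/non_diseased), recycled.
#' @return character vector of decisions (\code{needs_imputation} where an
#'   absent result reaches the diagnostic policy with no rule to fill it).
#' @export
composite_decision <- function(index_result, event_occurred, strategy,
                               options = list(), condition = NULL) {
  strategy <- match.arg(strategy,
                        c("diagnostic_policy", "indicative_event", "setback"))
  check_vocab(index_result, result_levels(), "index_result")
  n <- max(length(index_result), length(event_occurred))
  index_result <- rep_len(index_result, n)
  event_occurred <- rep_len(event_occurred, n)
  dec <- passthrough_decision(index_result)
  if (strategy == "indicative_event") {
    if (is.null(options$fixed_result)) {
      stop("indicative_event requires options$fixed_result", call. = FALSE)
    }
    dec[event_occurred] <- options$fixed_result
  } else if (strategy == "setback") {
    if (is.null(condition)) {
      stop("setback composite needs the true condition as context",
           call. = FALSE)
    }
    condition <- rep_len(condition, n)
    dec[event_occurred] <- ifelse(condition[event_occurred] == "diseased",
                                  "negative", "positive")
  }
  dec
}
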