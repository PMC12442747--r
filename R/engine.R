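# The estimand engine: runs a declarative estimand against subject-level
# study records. Pipeline: population filter -> reference-standard
# resolution -> principal-stratum membership -> per-subject event
# resolution -> mapped strategy application -> missing/inconclusive
# handling -> accuracy measures. Every exclusion or alteration is recorded
# in an audit log, so the estimate is traceable to the estimand attribute
# that produced it.

#' Engine options
#'
#' @param ci_level two-sided confidence level for proportion intervals.
#' @param ci_method \code{"wilson"} (default) or \code{"clopper_pearson"}.
#' @param inconclusive handling of inconclusive decisions at measure time:
#'   \code{"separate"} (reported alongside, default), \code{"as_positive"},
#'   \code{"as_negative"}, or \code{"exclude_with_warning"}.
#' @param reference_missing policy for inconclusive/absent reference
#'   results when the condition comes from the reference standard:
#'   \code{"exclude_with_warning"} or \code{"impute_bernoulli"}.
#' @param prevalence assumed prevalence for predictive values and the
#'   bernoulli reference policy; \code{NULL} uses the sample prevalence.
#' @param reference_impute_scope which subjects a reference imputation may
#'   touch: \code{"all"}, \code{"index_positive"}, or
#'   \code{"index_negative"}.
#' @param seed integer seed for all stochastic steps (bernoulli imputers);
#'   no global randomness is consumed.
#' @return list of engine options.
#' @export
engine_options <- function(ci_level = 0.95, ci_method = "wilson",
                           inconclusive = "separate",
                           reference_missing = "exclude_with_warning",
                           prevalence = NULL,
                           reference_impute_scope = "all",
                           seed = NULL) {
  stopifnot(ci_level > 0, ci_level < 1)
  list(ci_level = ci_level, ci_method = ci_method,
       inconclusive = inconclusive, reference_missing = reference_missing,
       prevalence = prevalence,
       reference_impute_scope = reference_impute_scope, seed = seed)
}

#' Fill the true condition from the chosen source
#'
#' At the estimand level the target condition is known; at the study level
#' a reference standard stands in for it. With
#' \code{source = "reference_result"}, positive/negative reference results
#' map to diseased/non-diseased, and inconclusive or absent references are
#' handled by the configured policy: excluded with a warning, or imputed by
#' a seeded Bernoulli draw at the supplied prevalence.
#'
#' @param records a \code{\link{subject_table}}.
#' @param source \code{"true_condition"} or \code{"reference_result"}.
#' @param options \code{\link{engine_options}}.
#' @return list: \code{records} (condition filled; subjects excluded by the
#'   policy get \code{true_condition = "unknown"}), \code{excluded_ids},
#'   \code{warnings} (character).
#' @export
resolve_condition <- function(records,
                              source = c("true_condition",
                                         "reference_result"),
                              options = engine_options()) {
  source <- match.arg(source)
  warnings <- character()
  excluded <- character()
  if (source == "reference_result") {
    ref <- records$reference_result
    if (is.null(ref)) {
      stop("condition_source is reference_result but the records carry no ",
           "reference_result column", call. = FALSE)
    }
    cond <- rep("unknown", nrow(records))
    cond[ref == "positive"] <- "diseased"
    cond[ref == "negative"] <- "non_diseased"
    unresolved <- which(!ref %in% c("positive", "negative"))
    if (length(unresolved)) {
      pol <- options$reference_missing
      if (pol == "exclude_with_warning") {
        excluded <- records$subject_id[unresolved]
        warnings <- c(warnings, paste0(
          length(unresolved), " subject(s) excluded for an inconclusive or ",
          "missing reference-standard result; exclusion can bias accuracy ",
          "estimates"))
      } else if (pol == "impute_bernoulli") {
        prev <- options$prevalence
        if (is.null(prev)) {
          stop("impute_bernoulli reference policy requires options$prevalence",
               call. = FALSE)
        }
        draw <- function() stats::runif(length(unresolved)) < prev
        dis <- if (is.null(options$seed)) draw() else {
          withr::with_seed(options$seed, draw())
        }
        cond[unresolved] <- ifelse(dis, "diseased", "non_diseased")
        warnings <- c(warnings, paste0(
          length(unresolved), " missing reference result(s) imputed by a ",
          "Bernoulli(", prev, ") draw"))
      } else {
        stop("unknown reference_missing policy ", sQuote(pol), call. = FALSE)
      }
    }
    records$true_condition <- cond
  }
  list(records = records, excluded_ids = excluded, warnings = warnings)
}

#' Validate an estimand's imputation plan
#'
#' Pure validation of forbidden imputation patterns before any estimation:
#' \itemize{
#'   \item an event handled with the principal-stratum strategy targeting
#'     the event-free stratum must not carry an imputer -- subjects in whom
#'     the event occurs are outside the stratum of interest and their
#'     results must not be imputed into it;
#'   \item when sensitivity is requested without specificity, a missing
#'     index result must not be imputed for non-diseased subjects (they are
#'     outside the sensitivity denominator), so index imputers must be
#'     scoped to diseased subjects;
#'   \item when the positive predictive value is requested, the reference
#'     standard must not be imputed only for index-positive subjects
#'     (partial-verification bias).
#' }
#'
#' @param spec an \code{\link{estimand_spec}}.
#' @param options \code{\link{engine_options}}.
#' @return character vector of violations (empty when the plan is clean).
#' @export
validate_imputation_plan <- function(spec, options = engine_options()) {
  problems <- character()
  evs <- spec$interfering_events
  for (ev in names(evs)) {
    e <- evs[[ev]]
    if (e$strategy == "principal_stratum" &&
        identical(e$options$stratum, "event_free") &&
        !is.null(e$options$imputer)) {
      problems <- c(problems, paste0(
        "event ", sQuote(ev), ": imputer configured under a ",
        "principal-stratum strategy targeting the event-free stratum; ",
        "results of subjects in whom the event occurs must not be imputed ",
        "into a stratum they do not belong to"))
    }
  }
  wants_sens <- "sensitivity" %in% spec$accuracy_measures
  wants_spec <- "specificity" %in% spec$accuracy_measures
  if (wants_sens && !wants_spec) {
    for (ev in names(evs)) {
      imp <- evs[[ev]]$options$imputer
      if (!is.null(imp) && (imp$scope %||% "all") != "diseased") {
        problems <- c(problems, paste0(
          "event ", sQuote(ev), ": index-result imputer scoped to ",
          sQuote(imp$scope %||% "all"), " while only sensitivity is ",
          "requested; a missing index result must not be imputed for ",
          "non-diseased subjects outside the sensitivity denominator ",
          "(set scope = 'diseased')"))
      }
    }
  }
  if ("ppv" %in% spec$accuracy_measures &&
      identical(options$reference_missing, "impute_bernoulli") &&
      identical(options$reference_impute_scope, "index_positive")) {
    problems <- c(problems, paste0(
      "reference-standard imputation scoped to index-positive subjects ",
      "while the positive predictive value is requested; imputing the ",
      "reference only where the index is positive reproduces ",
      "partial-verification bias"))
  }
  problems
}

#' Run a full estimand analysis
#'
#' Applies an \code{\link{estimand_spec}} to subject records: population
#' filter, condition resolution, principal-stratum membership, per-subject
#' event resolution, the mapped per-event strategies, inconclusive/missing
#' handling, and finally the requested accuracy measures with confidence
#' intervals and a per-event-stratum breakdown. The audit log records the
#' governing event, the strategy fired, and any imputation per subject.
#'
#' @param records a \code{\link{subject_table}}.
#' @param spec an \code{\link{estimand_spec}}; every occurred event type
#'   must be declared in it.
#' @param options \code{\link{engine_options}}.
#' @return an \code{accuracy_report}; the analysis set (decisions joined to
#'   condition) is attached as attribute \code{"analysis"} for bootstrap
#'   contrasts.
#' @examples
#' rec <- ct_example_records()
#' spec <- estimand_spec(
#'   target_condition = "lung_carcinoma",
#'   interfering_events = list(coughing = list(strategy = "diagnostic_policy"))
#' )
#' apply_estimand(rec, spec)
#' @export
apply_estimand <- function(records, spec, options = engine_options()) {
  stopifnot(inherits(records, "subject_table"),
            inherits(spec, "estimand_spec"))
  problems <- validate_imputation_plan(spec, options)
  if (length(problems)) {
    stop("invalid imputation plan:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  undeclared <- setdiff(event_types(records),
                        names(spec$interfering_events))
  occurred_undeclared <- Filter(function(t) any(event_occurred(records, t)),
                                undeclared)
  if (length(occurred_undeclared)) {
    stop("event type(s) ", paste(occurred_undeclared, collapse = ", "),
         " occurred but have no strategy in the estimand", call. = FALSE)
  }

  n_input <- nrow(records)
  audit <- data.frame(subject_id = records$subject_id,
                      governing_event = NA_character_,
                      strategy = NA_character_,
                      decision = NA_character_,
                      source = NA_character_,
                      imputed = FALSE,
                      note = NA_character_,
                      stringsAsFactors = FALSE)

  # 1. population filter (an estimand attribute, so it precedes everything)
  keep <- rep(TRUE, n_input)
  if (!is.null(spec$population$filter)) {
    env <- as.data.frame(records)
    keep <- eval(parse(text = spec$population$filter), envir = env,
                 enclos = baseenv())
    keep[is.na(keep)] <- FALSE
    audit$decision[!keep] <- "excluded"
    audit$source[!keep] <- "population:filter"
  }
  work <- records[keep, , drop = FALSE]
  class(work) <- class(records)
  attr(work, "event_types") <- event_types(records)

  # 2. target condition from the chosen source
  warnings <- character()
  limitations <- character()
  if (spec$condition_source == "reference_result") {
    rc <- resolve_condition(work, "reference_result", options)
    work <- rc$records
    warnings <- c(warnings, rc$warnings)
    limitations <- c(limitations, paste0(
      "true condition taken from the reference standard, a study-level ",
      "proxy for the target condition ",
      sQuote(spec$target_condition$label %||% ""),
      "; its imperfection is a limitation of every estimate below"))
    if (length(rc$excluded_ids)) {
      i <- match(rc$excluded_ids, audit$subject_id)
      audit$decision[i] <- "excluded"
      audit$source[i] <- "reference:missing"
      work <- work[!work$subject_id %in% rc$excluded_ids, , drop = FALSE]
    }
  }

  # 3. principal-stratum membership filters (population-level)
  for (ev in names(spec$interfering_events)) {
    e <- spec$interfering_events[[ev]]
    if (e$strategy != "principal_stratum") next
    if (!ev %in% event_types(records)) next
    occ <- event_occurred(work, ev)
    outside <- if (e$options$stratum == "event_free") occ else !occ
    if (any(outside)) {
      ids <- work$subject_id[outside]
      i <- match(ids, audit$subject_id)
      audit$decision[i] <- "excluded"
      audit$source[i] <- paste0("principal_stratum:", ev, "(",
                                e$options$stratum, ")")
      audit$strategy[i] <- "principal_stratum"
      audit$governing_event[i] <- ev
      work <- work[!outside, , drop = FALSE]
    }
  }

  # 4. governing event per remaining subject, principal-stratum events
  #    excluded from the race (their work is done)
  non_ps <- names(Filter(function(e) e$strategy != "principal_stratum",
                         spec$interfering_events))
  race <- work
  for (ev in setdiff(event_types(records), non_ps)) {
    race[[paste0("ie_", ev)]] <- FALSE
  }
  attr(race, "event_types") <- event_types(records)
  gov <- resolve_events(race, spec$multi_event_policy)

  # 5. strategy application per governing event
  dec <- rep(NA_character_, nrow(work))
  src <- rep(NA_character_, nrow(work))
  imputed <- rep(FALSE, nrow(work))
  none <- is.na(gov)
  dec[none] <- passthrough_decision(work$index_result[none])
  src[none] <- "no_event:observed"
  for (ev in unique(gov[!is.na(gov)])) {
    sel <- which(!is.na(gov) & gov == ev)
    e <- spec$interfering_events[[ev]]
    sub <- work[sel, , drop = FALSE]
    class(sub) <- class(records)
    attr(sub, "event_types") <- event_types(records)
    d <- apply_strategy(sub, ev, e$strategy, e$options, seed = options$seed)
    dec[sel] <- d$decision
    src[sel] <- d$source
    imputed[sel] <- grepl("imputer", d$source)
  }

  i <- match(work$subject_id, audit$subject_id)
  audit$governing_event[i] <- gov
  audit$strategy[i] <- ifelse(is.na(gov), NA_character_,
                              vapply(gov, function(g) {
                                if (is.na(g)) NA_character_ else
                                  spec$interfering_events[[g]]$strategy
                              }, character(1)))
  audit$decision[i] <- dec
  audit$source[i] <- src
  audit$imputed[i] <- imputed

  # 6. unresolved absences are a hard error, never a silent drop
  if (any(dec == "needs_imputation")) {
    bad <- work$subject_id[dec == "needs_imputation"]
    stop("absent results remain unresolved for subject(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         "; configure an imputer or a strategy that resolves them",
         call. = FALSE)
  }

  analysis <- data.frame(subject_id = work$subject_id,
                         true_condition = work$true_condition,
                         decision = dec,
                         with_ie = !is.na(gov) |
                           Reduce(`|`, c(list(rep(FALSE, nrow(work))),
                                         lapply(event_types(records),
                                                function(t) {
                                                  event_occurred(work, t)
                                                }))),
                         stringsAsFactors = FALSE)

  # 7. measures
  measures <- list()
  sens <- spec_ <- NULL
  ci_args <- list(conf_level = options$ci_level,
                  ci_method = options$ci_method,
                  inconclusive = options$inconclusive)
  if ("sensitivity" %in% spec$accuracy_measures) {
    sens <- do.call(estimate_sensitivity, c(list(analysis), ci_args))
    measures$sensitivity <- sens
  }
  if ("specificity" %in% spec$accuracy_measures) {
    spec_ <- do.call(estimate_specificity, c(list(analysis), ci_args))
    measures$specificity <- spec_
  }
  extra <- intersect(spec$accuracy_measures,
                     c("youden", "lr_positive", "lr_negative", "ppv", "npv"))
  if (length(extra)) {
    if (is.null(sens)) {
      sens <- do.call(estimate_sensitivity, c(list(analysis), ci_args))
    }
    if (is.null(spec_)) {
      spec_ <- do.call(estimate_specificity, c(list(analysis), ci_args))
    }
    prev <- options$prevalence
    if (is.null(prev) && any(c("ppv", "npv") %in% extra)) {
      prev <- mean(analysis$true_condition == "diseased")
    }
    dm <- derived_measures(sens$estimate, spec_$estimate, prev)
    for (m in extra) measures[[m]] <- dm[[m]]
    if (length(dm$infinite)) {
      warnings <- c(warnings, paste0("infinite ratio measure(s): ",
                                     paste(dm$infinite, collapse = ", ")))
    }
  }

  # per-stratum breakdown
  strata <- do.call(rbind, lapply(c(FALSE, TRUE), function(w) {
    a <- analysis[analysis$with_ie == w, , drop = FALSE]
    data.frame(
      stratum = if (w) "with_ie" else "without_ie",
      n = nrow(a),
      sens = safe_prop(a, "diseased", "positive"),
      spec = safe_prop(a, "non_diseased", "negative"),
      stringsAsFactors = FALSE)
  }))

  n_excluded <- sum(audit$decision == "excluded", na.rm = TRUE)
  n_inconclusive <- sum(analysis$decision == "inconclusive")
  n_included <- nrow(analysis) - n_inconclusive
  out <- new_accuracy_report(measures, strata, n_input, n_included,
                             n_excluded, n_inconclusive, spec, audit,
                             limitations, warnings)
  attr(out, "analysis") <- analysis
  out
}

safe_prop <- function(a, cond, success) {
  d <- a[a$true_condition == cond &
           a$decision %in% c("positive", "negative"), , drop = FALSE]
  if (!nrow(d)) return(NA_real_)
  mean(d$decision == success)
}
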