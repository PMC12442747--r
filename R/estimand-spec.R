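# The declarative estimand: five attributes pin down the clinical question a
# diagnostic accuracy study answers -- population, target condition, index
# test, accuracy measure(s), and one handling strategy per anticipated
# interfering event. Changing any attribute changes the question.

strategy_option_rules <- function() {
  list(
    diagnostic_policy      = list(required = character(), allowed = "imputer"),
    indicative_event       = list(required = "fixed_result",
                                  allowed = "fixed_result"),
    setback                = list(required = character(), allowed = "imputer"),
    hypothetical           = list(required = "imputer", allowed = "imputer"),
    while_under_monitoring = list(required = character(),
                                  allowed = "partial_rule"),
    # an imputer is syntactically allowed here so that the forbidden
    # combination (imputing into the event-free stratum) is caught by
    # validate_imputation_plan with a substantive message, not a schema one
    principal_stratum      = list(required = "stratum",
                                  allowed = c("stratum", "imputer"))
  )
}

#' Construct a validated estimand specification
#'
#' The five estimand attributes as a declarative, serializable object.
#' Every declared interfering event must carry exactly one handling
#' strategy; strategy options are validated against the strategy
#' (\code{fixed_result} belongs to \code{indicative_event} only,
#' \code{stratum} to \code{principal_stratum} only, an \code{imputer} is
#' required by \code{hypothetical} and optional under
#' \code{diagnostic_policy} and \code{setback}, \code{partial_rule} belongs
#' to \code{while_under_monitoring}).
#'
#' @param population list with \code{description} (free text) and optional
#'   \code{filter}, an R expression over covariates given as a string
#'   (inclusion predicate).
#' @param target_condition list with \code{label} and optional
#'   \code{definition}.
#' @param index_test list with \code{id} (decision-rule identifier) and
#'   optional \code{description}.
#' @param accuracy_measures ordered character vector from
#'   \code{sensitivity, specificity, youden, lr_positive, lr_negative, ppv,
#'   npv}.
#' @param interfering_events named list: event type -> list with
#'   \code{strategy} and optional \code{options} list. May be empty for a
#'   study that anticipates no events.
#' @param multi_event_policy list with \code{policy} (\code{first_event} or
#'   \code{priority}) and, for \code{priority}, a \code{priority} character
#'   vector totally ordering the declared event types (highest first).
#' @param condition_source \code{"true_condition"} (estimand level) or
#'   \code{"reference_result"} (study level, reference standard as proxy).
#' @param spec_version schema version, currently 1.
#' @return an object of class \code{estimand_spec}.
#' @export
estimand_spec <- function(population = list(description = ""),
                          target_condition = list(label = ""),
                          index_test = list(id = "index"),
                          accuracy_measures = c("sensitivity", "specificity"),
                          interfering_events = list(),
                          multi_event_policy = list(policy = "first_event"),
                          condition_source = "true_condition",
                          spec_version = 1L) {
  if (is.character(population)) population <- list(description = population)
  if (is.character(target_condition)) {
    target_condition <- list(label = target_condition)
  }
  if (is.character(index_test)) index_test <- list(id = index_test)
  accuracy_measures <- as.character(accuracy_measures)
  bad <- setdiff(accuracy_measures, measure_names())
  if (length(bad)) {
    stop("unknown accuracy measure(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!length(accuracy_measures)) {
    stop("at least one accuracy measure is required", call. = FALSE)
  }
  condition_source <- match.arg(condition_source,
                                c("true_condition", "reference_result"))

  interfering_events <- as.list(interfering_events)
  if (length(interfering_events) &&
      (is.null(names(interfering_events)) ||
       any(names(interfering_events) == ""))) {
    stop("interfering_events must be a named list (event type -> strategy)",
         call. = FALSE)
  }
  rules <- strategy_option_rules()
  for (ev in names(interfering_events)) {
    entry <- interfering_events[[ev]]
    if (is.character(entry)) entry <- list(strategy = entry)
    if (is.null(entry$strategy)) {
      stop("declared interfering event ", sQuote(ev), " has no strategy; ",
           "the estimand requires one handling strategy per event",
           call. = FALSE)
    }
    if (!entry$strategy %in% strategy_names()) {
      stop("unknown strategy ", sQuote(entry$strategy), " for event ",
           sQuote(ev), call. = FALSE)
    }
    opts <- entry$options %||% list()
    opts <- normalize_strategy_options(opts)
    rule <- rules[[entry$strategy]]
    extra <- setdiff(names(opts), rule$allowed)
    if (length(extra)) {
      stop("option(s) ", paste(sQuote(extra), collapse = ", "),
           " not valid for strategy ", sQuote(entry$strategy),
           " (event ", sQuote(ev), ")", call. = FALSE)
    }
    missing_opts <- setdiff(rule$required, names(opts))
    if (length(missing_opts)) {
      stop("strategy ", sQuote(entry$strategy), " for event ", sQuote(ev),
           " requires option(s) ", paste(sQuote(missing_opts), collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(opts$fixed_result) &&
        !opts$fixed_result %in% c("positive", "negative")) {
      stop("fixed_result must be 'positive' or 'negative'", call. = FALSE)
    }
    if (!is.null(opts$stratum) &&
        !opts$stratum %in% c("event_free", "event_affected")) {
      stop("stratum must be 'event_free' or 'event_affected'", call. = FALSE)
    }
    if (!is.null(opts$imputer)) validate_imputer_spec(opts$imputer)
    interfering_events[[ev]] <- list(strategy = entry$strategy,
                                     options = opts)
  }

  mep <- multi_event_policy
  mep$policy <- match.arg(mep$policy %||% "first_event",
                          c("first_event", "priority"))
  mep$priority <- as.character(mep$priority %||% character())
  if (mep$policy == "priority") {
    miss <- setdiff(names(interfering_events), mep$priority)
    if (length(miss)) {
      stop("priority order must cover all declared event types; missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(mep$priority)) {
      stop("priority order contains duplicates", call. = FALSE)
    }
  }

  structure(list(
    spec_version = as.integer(spec_version),
    population = population,
    target_condition = target_condition,
    index_test = index_test,
    accuracy_measures = accuracy_measures,
    interfering_events = interfering_events,
    multi_event_policy = list(policy = mep$policy, priority = mep$priority),
    condition_source = condition_source
  ), class = "estimand_spec")
}

# imputer option: a name string or list(name = , ...) with name one of the
# registered imputers; normalized to the list form.
normalize_strategy_options <- function(opts) {
  opts <- as.list(opts)
  if (!is.null(opts$imputer) && is.character(opts$imputer)) {
    opts$imputer <- list(name = opts$imputer)
  }
  opts
}

validate_imputer_spec <- function(imp) {
  if (is.null(imp$name)) stop("imputer needs a 'name'", call. = FALSE)
  if (!imp$name %in% imputer_names()) {
    stop("unknown imputer ", sQuote(imp$name), "; registered: ",
         paste(imputer_names(), collapse = ", "), call. = FALSE)
  }
  if (!is.null(imp$scope) &&
      !imp$scope %in% c("all", "diseased", "non_diseased")) {
    stop("imputer scope must be all, diseased, or non_diseased",
         call. = FALSE)
  }
  if (imp$name == "constant" &&
      (is.null(imp$result) || !imp$result %in% c("positive", "negative"))) {
    stop("constant imputer requires result = 'positive' or 'negative'",
         call. = FALSE)
  }
  if (imp$name == "bernoulli" &&
      (is.null(imp$p) || imp$p < 0 || imp$p > 1)) {
    stop("bernoulli imputer requires p in [0, 1]", call. = FALSE)
  }
  invisible(imp)
}

#' @export
print.estimand_spec <- function(x, ...) {
  cat("Diagnostic accuracy estimand (spec_version ", x$spec_version, ")\n",
      sep = "")
  cat("  Population:       ", x$population$description %||% "", "\n", sep = "")
  if (!is.null(x$population$filter)) {
    cat("    filter: ", x$population$filter, "\n", sep = "")
  }
  cat("  Target condition: ", x$target_condition$label %||% "", "\n", sep = "")
  cat("  Index test:       ", x$index_test$id %||% "", "\n", sep = "")
  cat("  Measures:         ", paste(x$accuracy_measures, collapse = ", "),
      "\n", sep = "")
  cat("  Condition source: ", x$condition_source, "\n", sep = "")
  if (length(x$interfering_events)) {
    cat("  Interfering events:\n")
    for (ev in names(x$interfering_events)) {
      e <- x$interfering_events[[ev]]
      optxt <- if (length(e$options)) {
        paste0(" (", paste(names(e$options), collapse = ", "), ")")
      } else ""
      cat("    ", ev, ": ", e$strategy, optxt, "\n", sep = "")
    }
    cat("  Multi-event policy: ", x$multi_event_policy$policy, "\n", sep = "")
  } else {
    cat("  Interfering events: none declared\n")
  }
  invisible(x)
}

#' Read an estimand specification from JSON or YAML
#'
#' Parses and fully validates a five-attribute estimand document. The file
#' format is chosen by extension (\code{.json} vs \code{.yaml}/\code{.yml}).
#'
#' @param path file path.
#' @return a validated \code{\link{estimand_spec}}.
#' @export
read_estimand_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported estimand spec format: .", ext, call. = FALSE)
  }
  known <- c("spec_version", "population", "target_condition", "index_test",
             "accuracy_measures", "interfering_events", "multi_event_policy",
             "condition_source")
  doc <- doc[intersect(known, names(doc))]
  do.call(estimand_spec, doc)
}

#' Write an estimand specification to JSON
#'
#' Serializes with canonical attribute order; writing, re-reading and
#' writing again is byte-identical.
#'
#' @param spec an \code{\link{estimand_spec}}.
#' @param path output path (\code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_estimand_spec <- function(spec, path) {
  stopifnot(inherits(spec, "estimand_spec"))
  out <- unclass(spec)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}
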