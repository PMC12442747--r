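# Subject-level study records. One row per participant. Interfering-event
# (IE) occurrence is stored wide: a logical column `ie_<type>` per declared
# event type, with an optional numeric `ie_<type>_time` ordering key.

reserved_columns <- function() {
  c("subject_id", "true_condition", "reference_result", "index_result",
    "partial_result", "counterfactual_result")
}

#' Construct a validated subject table
#'
#' A \code{subject_table} is a data frame with one row per study participant:
#' an opaque \code{subject_id}; \code{true_condition} (diseased /
#' non_diseased / unknown); the observed \code{index_result} and optional
#' \code{reference_result} (positive / negative / inconclusive / absent);
#' an optional \code{partial_result} derivable from pre-event measurements
#' only (positive / negative / absent); an optional simulator-only
#' \code{counterfactual_result} (the result had no interfering event
#' occurred); one logical \code{ie_<type>} column per declared event type
#' with an optional numeric \code{ie_<type>_time}; and any further columns
#' as covariates.
#'
#' @param x data frame with at least \code{subject_id} and
#'   \code{index_result}, plus \code{true_condition} and/or
#'   \code{reference_result}.
#' @return \code{x} with class \code{subject_table} and attributes
#'   \code{event_types} and \code{covariates}.
#' @examples
#' subject_table(data.frame(
#'   subject_id = c("s1", "s2"),
#'   true_condition = c("diseased", "non_diseased"),
#'   index_result = c("positive", "negative"),
#'   ie_coughing = c(TRUE, FALSE)
#' ))
#' @export
subject_table <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("subject_id", "index_result")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!any(c("true_condition", "reference_result") %in% names(x))) {
    stop("need a true_condition or reference_result column", call. = FALSE)
  }
  x$subject_id <- as.character(x$subject_id)
  if (anyDuplicated(x$subject_id)) {
    stop("duplicate subject_id values", call. = FALSE)
  }

  for (col in c("index_result", "reference_result")) {
    if (col %in% names(x)) {
      x[[col]] <- normalize_result(x[[col]])
      check_vocab(x[[col]], result_levels(), col, "row")
    }
  }
  for (col in c("partial_result", "counterfactual_result")) {
    if (col %in% names(x)) {
      x[[col]] <- normalize_result(x[[col]])
      check_vocab(x[[col]], partial_levels(), col, "row")
    }
  }
  if ("true_condition" %in% names(x)) {
    x$true_condition[is.na(x$true_condition) | x$true_condition == ""] <-
      "unknown"
    check_vocab(x$true_condition, condition_levels(), "true_condition", "row")
  } else {
    x$true_condition <- "unknown"
  }
  if (!"partial_result" %in% names(x)) x$partial_result <- x$index_result
  x$partial_result[x$partial_result == "inconclusive"] <- "absent"

  ev_cols <- grep("^ie_", names(x), value = TRUE)
  time_cols <- grep("^ie_.*_time$", ev_cols, value = TRUE)
  flag_cols <- setdiff(ev_cols, time_cols)
  event_types <- sub("^ie_", "", flag_cols)
  for (col in flag_cols) {
    v <- x[[col]]
    if (is.character(v)) v <- v %in% c("1", "TRUE", "true", "yes")
    v <- as.logical(v)
    v[is.na(v)] <- FALSE
    x[[col]] <- v
  }
  for (col in time_cols) {
    typ <- sub("_time$", "", sub("^ie_", "", col))
    if (!typ %in% event_types) {
      stop("time column ", col, " has no matching ie_", typ, " flag column",
           call. = FALSE)
    }
    x[[col]] <- as.numeric(x[[col]])
    bad <- !is.na(x[[col]]) & x[[col]] < 0
    if (any(bad)) stop("negative event time in ", col, call. = FALSE)
  }

  # A record with no occurred event cannot carry a pre-event partial result
  # that contradicts its full result.
  none <- if (length(flag_cols)) {
    !Reduce(`|`, x[flag_cols])
  } else {
    rep(TRUE, nrow(x))
  }
  bad <- none & x$partial_result != "absent" &
    x$partial_result != x$index_result
  if (any(bad)) {
    stop("partial_result differs from index_result for event-free subject(s) ",
         paste(utils::head(x$subject_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }

  covars <- setdiff(names(x), c(reserved_columns(), ev_cols))
  structure(x, class = c("subject_table", "data.frame"),
            event_types = event_types, covariates = covars)
}

normalize_result <- function(v) {
  v <- as.character(v)
  v[is.na(v) | v == ""] <- "absent"
  v
}

#' Event types declared in a subject table
#' @param records a \code{subject_table}.
#' @return character vector of event-type names.
#' @export
event_types <- function(records) attr(records, "event_types") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Did a given interfering event occur, per subject?
#' @param records a \code{subject_table}.
#' @param event_type declared event-type name.
#' @return logical vector, one element per row.
#' @export
event_occurred <- function(records, event_type) {
  col <- paste0("ie_", event_type)
  if (!col %in% names(records)) {
    stop("event type ", sQuote(event_type), " not present in records",
         call. = FALSE)
  }
  records[[col]]
}

#' Read a subject table from delimited text
#'
#' Reads a UTF-8 CSV with a header row into a validated
#' \code{\link{subject_table}}. Empty cells in result columns map to the
#' \code{absent} state (a decision that never came into being), never to
#' \code{negative}; tokens outside the result vocabulary raise an error with
#' the offending row. The simulator-only \code{counterfactual_result} column
#' is refused in real data unless \code{allow_counterfactual = TRUE}.
#'
#' @param path file path.
#' @param schema optional named character vector mapping internal column
#'   names (names) to file column names (values), e.g.
#'   \code{c(subject_id = "pid")}.
#' @param allow_counterfactual keep a \code{counterfactual_result} column if
#'   present (for tables written by the simulator); default \code{FALSE}.
#' @return a \code{subject_table}.
#' @export
read_subject_table <- function(path, schema = NULL,
                               allow_counterfactual = FALSE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!is.null(schema)) {
    for (internal in names(schema)) {
      file_col <- schema[[internal]]
      if (!file_col %in% names(x)) {
        stop("schema column ", sQuote(file_col), " not found in file",
             call. = FALSE)
      }
      names(x)[names(x) == file_col] <- internal
    }
  }
  need <- c("subject_id", "index_result")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("counterfactual_result" %in% names(x) && !allow_counterfactual) {
    stop("counterfactual_result is a simulator-only column; ",
         "refusing to read it from study data ",
         "(use allow_counterfactual = TRUE for simulated tables)",
         call. = FALSE)
  }
  if (nrow(x) == 0) {
    x$subject_id <- character()
  }
  subject_table(x)
}

#' Write a subject table to CSV
#'
#' Inverse of \code{\link{read_subject_table}}: \code{absent} results are
#' written as empty cells, event flags as 0/1.
#'
#' @param records a \code{subject_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_subject_table <- function(records, path) {
  stopifnot(inherits(records, "subject_table"))
  out <- as.data.frame(records)
  for (col in intersect(c("index_result", "reference_result",
                          "partial_result", "counterfactual_result"),
                        names(out))) {
    out[[col]][out[[col]] == "absent"] <- ""
  }
  for (typ in event_types(records)) {
    col <- paste0("ie_", typ)
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
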