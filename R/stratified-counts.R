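# Counts cross-classified by disease state x IE occurrence x test result:
# the shape of a two-table accuracy report broken down by whether the
# interfering event occurred. Conclusive results (positive/negative) form
# the 2x2x2 core; inconclusive and absent results are carried in overflow
# cells so that nothing is silently dropped.

#' Construct a stratified count table
#'
#' Counts of positive and negative index-test results cross-classified by
#' disease state (diseased / non_diseased) and interfering-event stratum
#' (without_ie / with_ie), plus overflow counts of inconclusive and absent
#' results in the same strata.
#'
#' @param core numeric array \code{2 x 2 x 2} with dimnames
#'   \code{disease = c("diseased","non_diseased")},
#'   \code{ie = c("without_ie","with_ie")},
#'   \code{result = c("positive","negative")}; or \code{NULL} to build from
#'   the six scalar arguments below.
#' @param overflow like \code{core} but with
#'   \code{result = c("inconclusive","absent")}; defaults to all zero.
#' @param event_type name of the stratifying event (informational).
#' @param d_pos_noie,d_neg_noie,d_pos_ie,d_neg_ie counts for diseased
#'   subjects without / with the event.
#' @param h_pos_noie,h_neg_noie,h_pos_ie,h_neg_ie counts for non-diseased
#'   subjects.
#' @return an object of class \code{stratified_counts}.
#' @examples
#' # The worked CT-scan example: 40 diseased, 160 healthy
#' ct <- stratified_counts(
#'   d_pos_noie = 12, d_neg_noie = 4, d_pos_ie = 16, d_neg_ie = 8,
#'   h_pos_noie = 10, h_neg_noie = 110, h_pos_ie = 6, h_neg_ie = 34,
#'   event_type = "coughing"
#' )
#' @export
stratified_counts <- function(core = NULL, overflow = NULL,
                              event_type = "ie",
                              d_pos_noie = 0, d_neg_noie = 0,
                              d_pos_ie = 0, d_neg_ie = 0,
                              h_pos_noie = 0, h_neg_noie = 0,
                              h_pos_ie = 0, h_neg_ie = 0) {
  dn <- list(disease = c("diseased", "non_diseased"),
             ie = c("without_ie", "with_ie"),
             result = c("positive", "negative"))
  if (is.null(core)) {
    core <- array(0, dim = c(2, 2, 2), dimnames = dn)
    core["diseased", "without_ie", ] <- c(d_pos_noie, d_neg_noie)
    core["diseased", "with_ie", ] <- c(d_pos_ie, d_neg_ie)
    core["non_diseased", "without_ie", ] <- c(h_pos_noie, h_neg_noie)
    core["non_diseased", "with_ie", ] <- c(h_pos_ie, h_neg_ie)
  }
  if (is.null(overflow)) {
    overflow <- array(0, dim = c(2, 2, 2),
                      dimnames = list(disease = dn$disease, ie = dn$ie,
                                      result = c("inconclusive", "absent")))
  }
  stopifnot(all(core >= 0), all(overflow >= 0),
            all(core == round(core)), all(overflow == round(overflow)))
  structure(list(core = core, overflow = overflow, event_type = event_type),
            class = "stratified_counts")
}

#' @export
print.stratified_counts <- function(x, ...) {
  cat("Stratified counts (event:", x$event_type, ")\n")
  for (d in dimnames(x$core)$disease) {
    cat("  ", d, ":\n", sep = "")
    m <- t(x$core[d, , ])
    print(m)
    if (any(x$overflow[d, , ] > 0)) {
      cat("   overflow (inconclusive/absent):\n")
      print(t(x$overflow[d, , ]))
    }
  }
  invisible(x)
}

#' Total subject count in a stratified table
#' @param counts a \code{stratified_counts} object.
#' @return integer total including overflow cells.
#' @export
counts_total <- function(counts) {
  sum(counts$core) + sum(counts$overflow)
}

#' Cross-tabulate subject records by disease, event occurrence, and result
#'
#' Collapses subject-level records to a \code{\link{stratified_counts}}
#' table for one declared event type. Conclusive results fill the 2x2x2
#' core; inconclusive and absent index results are counted in overflow
#' cells alongside it. Permutation-invariant and idempotent: cell counts
#' always sum to the number of records.
#'
#' @param records a \code{\link{subject_table}} whose \code{true_condition}
#'   is known for every row (run \code{\link{resolve_condition}} first if
#'   the study supplies only a reference standard).
#' @param event_type declared event-type name to stratify on.
#' @return a \code{stratified_counts} object.
#' @export
tabulate_records <- function(records, event_type) {
  stopifnot(inherits(records, "subject_table"))
  if (any(records$true_condition == "unknown")) {
    stop("records with unknown true_condition; apply reference-standard ",
         "handling (resolve_condition) before tabulating", call. = FALSE)
  }
  occ <- if (nrow(records)) event_occurred(records, event_type) else logical()
  out <- stratified_counts(event_type = event_type)
  if (!nrow(records)) return(out)
  dis <- records$true_condition
  ie <- ifelse(occ, "with_ie", "without_ie")
  res <- records$index_result
  concl <- res %in% c("positive", "negative")
  out$core <- array(
    as.numeric(table(factor(dis[concl], dimnames(out$core)$disease),
                     factor(ie[concl], dimnames(out$core)$ie),
                     factor(res[concl], c("positive", "negative")))),
    dim = dim(out$core), dimnames = dimnames(out$core))
  out$overflow <- array(
    as.numeric(table(factor(dis[!concl], dimnames(out$core)$disease),
                     factor(ie[!concl], dimnames(out$core)$ie),
                     factor(res[!concl], c("inconclusive", "absent")))),
    dim = dim(out$overflow), dimnames = dimnames(out$overflow))
  out
}

#' Expand a stratified count table back into subject records
#'
#' Builds a minimal \code{\link{subject_table}} whose
#' \code{\link{tabulate_records}} reproduces \code{counts} exactly
#' (marginal-preserving inverse; subject ids are generated).
#'
#' @param counts a \code{stratified_counts} object.
#' @return a \code{subject_table} with \code{counts_total(counts)} rows.
#' @export
records_from_counts <- function(counts) {
  stopifnot(inherits(counts, "stratified_counts"))
  rows <- list()
  add <- function(n, dis, ie, res) {
    if (n > 0) {
      rows[[length(rows) + 1L]] <<- data.frame(
        true_condition = rep(dis, n), occ = rep(ie == "with_ie", n),
        index_result = rep(res, n), stringsAsFactors = FALSE)
    }
  }
  for (d in dimnames(counts$core)$disease) {
    for (s in dimnames(counts$core)$ie) {
      for (r in dimnames(counts$core)$result) add(counts$core[d, s, r], d, s, r)
      for (r in dimnames(counts$overflow)[[3]]) {
        add(counts$overflow[d, s, r], d, s, r)
      }
    }
  }
  x <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(true_condition = character(), occ = logical(),
               index_result = character(), stringsAsFactors = FALSE)
  }
  df <- data.frame(
    subject_id = if (nrow(x)) sprintf("s%04d", seq_len(nrow(x))) else character(),
    true_condition = x$true_condition,
    index_result = x$index_result,
    stringsAsFactors = FALSE)
  df[[paste0("ie_", counts$event_type)]] <- x$occ
  subject_table(df)
}
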