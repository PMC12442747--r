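# Comparative accuracy estimands: two tests against one reference. Paired
# designs observe both tests (and both tests' events) on every subject;
# unpaired designs randomize each subject to one test. Contrasts of
# sensitivity and specificity (difference, ratio, odds) with seeded
# nonparametric bootstrap intervals.

#' Construct a comparative study table
#'
#' One row per subject with per-test result columns
#' (\code{index_result}, \code{comparator_result}) and per-test event
#' flags (\code{ie_<type>_index}, \code{ie_<type>_comparator}). In a
#' paired design both tests' fields are present for every subject; in an
#' unpaired design exactly one is, selected by the \code{assignment}
#' column (\code{"index"} or \code{"comparator"}).
#'
#' @param x data frame with \code{subject_id}, \code{true_condition},
#'   result columns as above, and for unpaired designs an
#'   \code{assignment} column.
#' @param design \code{"paired"} or \code{"unpaired"}.
#' @return \code{x} with class \code{comparative_table} and attribute
#'   \code{design}.
#' @export
comparative_table <- function(x, design = c("paired", "unpaired")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("subject_id", "true_condition")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (design == "paired") {
    miss <- setdiff(c("index_result", "comparator_result"), names(x))
    if (length(miss)) {
      stop("paired design requires both tests' result columns; missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  } else {
    if (!"assignment" %in% names(x)) {
      stop("unpaired design requires an assignment column", call. = FALSE)
    }
    check_vocab(x$assignment, c("index", "comparator"), "assignment", "row")
  }
  check_vocab(x$true_condition, condition_levels(), "true_condition", "row")
  for (col in intersect(c("index_result", "comparator_result"), names(x))) {
    x[[col]] <- normalize_result(x[[col]])
    check_vocab(x[[col]], result_levels(), col, "row")
  }
  structure(x, class = c("comparative_table", "data.frame"), design = design)
}

#' Simulate a paired comparative study
#'
#' Both tests on every subject; results conditionally independent given
#' the true state, each test with its own accuracy and its own
#' independently occurring interfering event (degrading accuracy to the
#' \code{*_ie} values when it occurs).
#'
#' @param n subject count.
#' @param prevalence probability of disease.
#' @param sensA,specA,sensB,specB event-free accuracy of the index (A) and
#'   comparator (B) tests.
#' @param ie_rateA,ie_rateB per-test event probabilities (independent).
#' @param sensA_ie,specA_ie,sensB_ie,specB_ie accuracy under the event;
#'   default equal to the event-free values (event without degradation).
#' @param event_type simulated event name.
#' @param seed integer seed.
#' @return a paired \code{\link{comparative_table}}.
#' @export
simulate_paired_study <- function(n, prevalence = 0.2,
                                  sensA = 0.85, specA = 0.9,
                                  sensB = 0.75, specB = 0.9,
                                  ie_rateA = 0, ie_rateB = 0,
                                  sensA_ie = sensA, specA_ie = specA,
                                  sensB_ie = sensB, specB_ie = specB,
                                  event_type = "ie", seed = 1L) {
  withr::with_seed(as.integer(seed), {
    cond <- ifelse(stats::runif(n) < prevalence, "diseased", "non_diseased")
    occA <- stats::runif(n) < ie_rateA
    occB <- stats::runif(n) < ie_rateB
    resA <- draw_result(cond, ifelse(occA, sensA_ie, sensA),
                        ifelse(occA, specA_ie, specA))
    resB <- draw_result(cond, ifelse(occB, sensB_ie, sensB),
                        ifelse(occB, specB_ie, specB))
    df <- data.frame(subject_id = sprintf("p%06d", seq_len(n)),
                     true_condition = cond,
                     index_result = resA, comparator_result = resB,
                     stringsAsFactors = FALSE)
    df[[paste0("ie_", event_type, "_index")]] <- occA
    df[[paste0("ie_", event_type, "_comparator")]] <- occB
    comparative_table(df, "paired")
  })
}

#' Extract one test's arm from a comparative table
#'
#' Returns the records of one test as an ordinary
#' \code{\link{subject_table}} (result and event columns renamed), so each
#' arm can be analyzed under its own estimand -- the two tests of a
#' comparison may legitimately use different strategy maps. For unpaired
#' designs only the subjects assigned to the requested test are returned.
#'
#' @param records a \code{\link{comparative_table}}.
#' @param test \code{"index"} or \code{"comparator"}.
#' @return a \code{subject_table}.
#' @export
extract_test <- function(records, test = c("index", "comparator")) {
  test <- match.arg(test)
  stopifnot(inherits(records, "comparative_table"))
  x <- as.data.frame(records)
  if (attr(records, "design") == "unpaired") {
    x <- x[x$assignment == test, , drop = FALSE]
  }
  res_col <- paste0(test, "_result")
  if (!res_col %in% names(x)) {
    stop("no ", res_col, " column in comparative table", call. = FALSE)
  }
  out <- data.frame(subject_id = x$subject_id,
                    true_condition = x$true_condition,
                    index_result = x[[res_col]],
                    stringsAsFactors = FALSE)
  suffix <- paste0("_", test)
  ev_cols <- grep(paste0("^ie_.*", suffix, "$"), names(x), value = TRUE)
  for (col in ev_cols) {
    out[[sub(paste0(suffix, "$"), "", col)]] <- x[[col]]
  }
  subject_table(out)
}

contrast_fun <- function(contrast) {
  switch(contrast,
         difference = function(a, b) a - b,
         ratio = function(a, b) a / b,
         odds = function(a, b) (a / (1 - a)) / (b / (1 - b)))
}

#' Contrast the accuracy of two tests
#'
#' Difference, ratio, or odds ratio of sensitivities and of specificities
#' between two analyses (each computed under its own, possibly different,
#' strategy map). Confidence intervals come from a seeded nonparametric
#' bootstrap over subjects: joint resampling when the two analysis sets
#' are paired (same subjects), independent resampling of the two
#' disease strata otherwise. Zero denominators yield a flagged infinite
#' estimate rather than an error.
#'
#' @param reportA,reportB \code{accuracy_report} objects from
#'   \code{\link{apply_estimand}} (their attached analysis sets drive the
#'   bootstrap), or plain lists with \code{sensitivity}/\code{specificity}
#'   estimates for a point-only contrast.
#' @param contrast \code{"difference"}, \code{"ratio"}, or \code{"odds"}.
#' @param n_boot bootstrap resamples (default 2000); 0 skips the interval.
#' @param conf_level two-sided level.
#' @param seed integer seed for the bootstrap.
#' @return list of class \code{accuracy_contrast}: per measure the point
#'   contrast, bootstrap CI, and an \code{infinite} flag.
#' @export
compare_accuracy <- function(reportA, reportB,
                             contrast = c("difference", "ratio", "odds"),
                             n_boot = 2000, conf_level = 0.95, seed = 1L) {
  contrast <- match.arg(contrast)
  f <- contrast_fun(contrast)
  est <- function(rep_, m) {
    v <- rep_$measures[[m]]
    if (is.list(v)) v$estimate else v
  }
  out <- list(contrast = contrast, measures = list())
  aA <- attr(reportA, "analysis")
  aB <- attr(reportB, "analysis")
  paired <- !is.null(aA) && !is.null(aB) &&
    setequal(aA$subject_id, aB$subject_id)
  for (m in c("sensitivity", "specificity")) {
    pa <- est(reportA, m)
    pb <- est(reportB, m)
    if (is.null(pa) || is.null(pb)) next
    point <- f(pa, pb)
    inf <- !is.finite(point)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0 && !is.null(aA) && !is.null(aB)) {
      cond <- if (m == "sensitivity") "diseased" else "non_diseased"
      succ <- if (m == "sensitivity") "positive" else "negative"
      keep <- function(a) {
        a[a$true_condition == cond &
            a$decision %in% c("positive", "negative"), , drop = FALSE]
      }
      dA <- keep(aA)
      dB <- keep(aB)
      ci <- withr::with_seed(as.integer(seed), {
        if (paired) {
          ids <- intersect(dA$subject_id, dB$subject_id)
          okA <- (dA$decision == succ)[match(ids, dA$subject_id)]
          okB <- (dB$decision == succ)[match(ids, dB$subject_id)]
          nn <- length(ids)
          idx <- matrix(sample.int(nn, nn * n_boot, replace = TRUE),
                        nrow = nn)
          stat <- f(colMeans(matrix(okA[idx], nrow = nn)),
                    colMeans(matrix(okB[idx], nrow = nn)))
        } else {
          okA <- dA$decision == succ
          okB <- dB$decision == succ
          nA <- length(okA)
          nB <- length(okB)
          iA <- matrix(sample.int(nA, nA * n_boot, replace = TRUE),
                       nrow = nA)
          iB <- matrix(sample.int(nB, nB * n_boot, replace = TRUE),
                       nrow = nB)
          stat <- f(colMeans(matrix(okA[iA], nrow = nA)),
                    colMeans(matrix(okB[iB], nrow = nB)))
        }
        stats::quantile(stat[is.finite(stat)],
                        c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        names = FALSE)
      })
    }
    out$measures[[m]] <- list(estimate = point, ci = ci,
                              estimateA = pa, estimateB = pb,
                              infinite = inf)
  }
  out$paired <- paired
  out$conf_level <- conf_level
  out$n_boot <- n_boot
  class(out) <- "accuracy_contrast"
  out
}

#' @export
print.accuracy_contrast <- function(x, ...) {
  cat("Accuracy contrast (", x$contrast, ", ",
      if (isTRUE(x$paired)) "paired" else "independent", " bootstrap)\n",
      sep = "")
  for (m in names(x$measures)) {
    v <- x$measures[[m]]
    cat(sprintf("  %-12s %.4f (A %.4f vs B %.4f), %d%% CI %.4f-%.4f%s\n",
                m, v$estimate, v$estimateA, v$estimateB,
                round(100 * x$conf_level), v$ci[1], v$ci[2],
                if (v$infinite) " [infinite]" else ""))
  }
  invisible(x)
}

#' Four principal strata of a paired comparative design
#'
#' When the same event type is handled with the principal-stratum strategy
#' for both tests of a paired design, subjects partition into four strata:
#' event in both tests, in neither, only in the index test, only in the
#' comparator. Counts always sum to the number of subjects; per-stratum
#' accuracy is reported for each test. Unpaired designs cannot observe the
#' stratum of the unassigned test; membership would have to be predicted,
#' which this package deliberately does not do.
#'
#' @param records a paired \code{\link{comparative_table}} with
#'   \code{ie_<event_type>_index} and \code{ie_<event_type>_comparator}
#'   flags.
#' @param event_type the shared event type.
#' @return data frame: stratum, n, and per-test sensitivity/specificity
#'   (NA where a stratum holds no subjects of a condition).
#' @export
paired_principal_strata <- function(records, event_type) {
  stopifnot(inherits(records, "comparative_table"))
  if (attr(records, "design") != "paired") {
    stop("principal strata across two tests are observable only in a ",
         "paired design; in an unpaired design the stratum for the ",
         "unassigned test is unknown and must be predicted ",
         "(prediction models are an unimplemented extension point)",
         call. = FALSE)
  }
  colA <- paste0("ie_", event_type, "_index")
  colB <- paste0("ie_", event_type, "_comparator")
  miss <- setdiff(c(colA, colB), names(records))
  if (length(miss)) {
    stop("missing event flag column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  occA <- as.logical(records[[colA]])
  occB <- as.logical(records[[colB]])
  stratum <- ifelse(occA & occB, "both",
                    ifelse(!occA & !occB, "neither",
                           ifelse(occA, "index_only", "comparator_only")))
  acc <- function(sel, test, cond, succ) {
    res <- records[[paste0(test, "_result")]][sel]
    cnd <- records$true_condition[sel]
    d <- res[cnd == cond & res %in% c("positive", "negative")]
    if (!length(d)) NA_real_ else mean(d == succ)
  }
  out <- do.call(rbind, lapply(
    c("both", "neither", "index_only", "comparator_only"),
    function(s) {
      sel <- stratum == s
      data.frame(
        stratum = s, n = sum(sel),
        sens_index = acc(sel, "index", "diseased", "positive"),
        spec_index = acc(sel, "index", "non_diseased", "negative"),
        sens_comparator = acc(sel, "comparator", "diseased", "positive"),
        spec_comparator = acc(sel, "comparator", "non_diseased", "negative"),
        stringsAsFactors = FALSE)
    }))
  stopifnot(sum(out$n) == nrow(records))
  out
}
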