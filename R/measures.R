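# Accuracy measures on derived decisions: sensitivity and specificity as
# proportions with Wilson or Clopper-Pearson intervals, and the derived
# measures (Youden index, likelihood ratios, predictive values) from a
# supplied prevalence.

#' Confidence interval for a binomial proportion
#'
#' Wilson score interval (default; stable at boundary proportions) or exact
#' Clopper-Pearson interval.
#'
#' @param x number of successes.
#' @param n number of trials, \code{n >= 1}.
#' @param conf_level two-sided confidence level, default 0.95.
#' @param method \code{"wilson"} or \code{"clopper_pearson"}.
#' @return numeric \code{c(lower, upper)}.
#' @export
proportion_ci <- function(x, n, conf_level = 0.95,
                          method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    ci <- c(center - half, center + half)
  } else {
    lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    ci <- c(lo, hi)
  }
  pmin(pmax(ci, 0), 1)
}

# Per-subject decisions joined to true condition -> one proportion measure.
# `target` is the condition whose subjects form the denominator and
# `success` the decision counted in the numerator.
conditional_proportion <- function(decisions, target, success,
                                   conf_level = 0.95,
                                   ci_method = "wilson",
                                   inconclusive = c("separate",
                                                    "as_positive",
                                                    "as_negative",
                                                    "exclude_with_warning"),
                                   measure = "accuracy measure") {
  inconclusive <- match.arg(inconclusive)
  stopifnot(all(c("decision", "true_condition") %in% names(decisions)))
  if (any(decisions$decision == "needs_imputation")) {
    bad <- decisions$subject_id[decisions$decision == "needs_imputation"]
    stop("decisions needing imputation remain for subject(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; resolve them before estimating accuracy", call. = FALSE)
  }
  d <- decisions[decisions$true_condition == target &
                   decisions$decision != "excluded", , drop = FALSE]
  n_excluded <- sum(decisions$true_condition == target &
                      decisions$decision == "excluded")
  inc <- d$decision == "inconclusive"
  n_inconclusive <- sum(inc)
  if (n_inconclusive) {
    if (inconclusive == "as_positive") {
      d$decision[inc] <- "positive"
    } else if (inconclusive == "as_negative") {
      d$decision[inc] <- "negative"
    } else {
      if (inconclusive == "exclude_with_warning") {
        warning("excluding ", n_inconclusive, " inconclusive result(s) from ",
                "the ", measure, " denominator; restricting to conclusive ",
                "results could introduce bias (spectrum restriction)",
                call. = FALSE)
      }
      d <- d[!inc, , drop = FALSE]
    }
  }
  denom <- nrow(d)
  if (denom == 0) {
    stop(measure, " is undefined: empty denominator (no eligible subjects ",
         "with condition ", sQuote(target), ")", call. = FALSE)
  }
  num <- sum(d$decision == success)
  list(estimate = num / denom, numerator = num, denominator = denom,
       conf_level = conf_level,
       ci = proportion_ci(num, denom, conf_level, ci_method),
       n_excluded = n_excluded, n_inconclusive = n_inconclusive)
}

#' Sensitivity from derived decisions
#'
#' Proportion of positive decisions among non-excluded diseased subjects:
#' the probability that a diseased patient is correctly identified.
#'
#' @param decisions data frame with columns \code{subject_id},
#'   \code{decision}, \code{true_condition} (derived decisions joined to
#'   condition, as produced by the strategy functions plus the record's
#'   condition column).
#' @param conf_level two-sided confidence level.
#' @param ci_method \code{"wilson"} or \code{"clopper_pearson"}.
#' @param inconclusive how inconclusive decisions enter the estimate:
#'   reported \code{"separate"} (held out of the denominator but counted,
#'   the default), \code{"as_positive"}, \code{"as_negative"}, or
#'   \code{"exclude_with_warning"} (exclusion can introduce bias, hence the
#'   warning).
#' @return list with \code{estimate}, \code{numerator}, \code{denominator},
#'   \code{ci}, \code{n_excluded}, \code{n_inconclusive}.
#' @export
estimate_sensitivity <- function(decisions, conf_level = 0.95,
                                 ci_method = "wilson",
                                 inconclusive = "separate") {
  conditional_proportion(decisions, "diseased", "positive", conf_level,
                         ci_method, inconclusive, "sensitivity")
}

#' Specificity from derived decisions
#'
#' Proportion of negative decisions among non-excluded non-diseased
#' subjects: the probability that a healthy patient is correctly
#' identified.
#'
#' @inheritParams estimate_sensitivity
#' @return as \code{\link{estimate_sensitivity}}.
#' @export
estimate_specificity <- function(decisions, conf_level = 0.95,
                                 ci_method = "wilson",
                                 inconclusive = "separate") {
  conditional_proportion(decisions, "non_diseased", "negative", conf_level,
                         ci_method, inconclusive, "specificity")
}

#' Measures derived from sensitivity, specificity, and prevalence
#'
#' Youden index \code{sens + spec - 1}; positive likelihood ratio
#' \code{sens / (1 - spec)}; negative likelihood ratio
#' \code{(1 - sens) / spec}; and positive/negative predictive values by
#' Bayes' theorem at the supplied prevalence. Zero denominators yield
#' \code{Inf} with an \code{infinite} flag rather than an error (no
#' continuity correction is applied).
#'
#' @param sens,spec proportions in \[0, 1\].
#' @param prevalence prevalence of the target condition in (0, 1); required
#'   for \code{ppv}/\code{npv}, otherwise may be \code{NULL}.
#' @return named list: \code{youden}, \code{lr_positive},
#'   \code{lr_negative}, \code{ppv}, \code{npv} (predictive values
#'   \code{NA} without a prevalence), plus \code{infinite}, the names of
#'   ratio measures that hit a zero denominator.
#' @export
derived_measures <- function(sens, spec, prevalence = NULL) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  infinite <- character()
  lr_pos <- if (spec < 1) sens / (1 - spec) else {
    infinite <- c(infinite, "lr_positive")
    Inf
  }
  lr_neg <- if (spec > 0) (1 - sens) / spec else {
    infinite <- c(infinite, "lr_negative")
    Inf
  }
  ppv <- npv <- NA_real_
  if (!is.null(prevalence)) {
    stopifnot(prevalence > 0, prevalence < 1)
    ppv_den <- sens * prevalence + (1 - spec) * (1 - prevalence)
    npv_den <- (1 - sens) * prevalence + spec * (1 - prevalence)
    ppv <- if (ppv_den > 0) sens * prevalence / ppv_den else NA_real_
    npv <- if (npv_den > 0) spec * (1 - prevalence) / npv_den else NA_real_
  }
  list(youden = sens + spec - 1, lr_positive = lr_pos, lr_negative = lr_neg,
       ppv = ppv, npv = npv, infinite = infinite)
}
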