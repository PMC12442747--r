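# Imputation rules for results that a strategy must fill in: an absent index
# result under the diagnostic policy, the counterfactual result under the
# hypothetical strategy, or a missing true state under setback. Three
# built-ins; covariate-model imputation is an extension point via
# register_imputer().

imputer_registry <- new.env(parent = emptyenv())

#' Register an imputation rule
#'
#' An imputer is a function \code{function(records, imp, seed)} receiving
#' the subset of records to impute, its own option list \code{imp}, and an
#' integer seed; it returns a character vector of results
#' (\code{positive}/\code{negative}), one per row. Built-ins:
#' \describe{
#'   \item{constant}{always \code{imp$result}.}
#'   \item{bernoulli}{positive with probability \code{imp$p}, seeded.}
#'   \item{oracle}{returns the record's \code{counterfactual_result}
#'     (simulation only; errors when counterfactuals are absent).}
#' }
#'
#' @param name imputer name used in estimand specifications.
#' @param fun the imputation function.
#' @return \code{name}, invisibly.
#' @export
register_imputer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = imputer_registry)
  invisible(name)
}

#' Names of registered imputers
#' @return character vector.
#' @export
imputer_names <- function() sort(ls(imputer_registry))

run_imputer <- function(records, imp, seed = NULL) {
  fun <- get(imp$name, envir = imputer_registry)
  res <- fun(records, imp, seed)
  check_vocab(res, c("positive", "negative"),
              paste0("imputed result (imputer ", imp$name, ")"), "row")
  if (any(res == "absent")) {
    stop("imputer ", imp$name, " returned an absent result", call. = FALSE)
  }
  res
}

register_builtin_imputers <- function() {
  register_imputer("constant", function(records, imp, seed) {
    rep(imp$result, nrow(records))
  })
  register_imputer("bernoulli", function(records, imp, seed) {
    draw <- function() {
      ifelse(stats::runif(nrow(records)) < imp$p, "positive", "negative")
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  })
  register_imputer("oracle", function(records, imp, seed) {
    cf <- records$counterfactual_result
    if (is.null(cf) || any(cf == "absent" | is.na(cf))) {
      stop("oracle imputer needs counterfactual_result on every record ",
           "to impute (simulated data only)", call. = FALSE)
    }
    cf
  })
}

.onLoad <- function(libname, pkgname) {
  register_builtin_imputers()
}
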