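---
title: "Estimands for diagnostic accuracy studies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimands for diagnostic accuracy studies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxestimand)
```

## The estimand model

A diagnostic accuracy study targets the agreement between an index test
and a target condition, usually as the co-primary pair sensitivity
$Se = P(T^+ \mid D^+)$ and specificity $Sp = P(T^- \mid D^-)$. What those
probabilities *mean* depends on decisions that are often left implicit:
who the test is for, what counts as diseased, what the test's decision
rule is, which measure summarizes accuracy, and — the piece this package
is built around — what happens when an event interferes with the conduct
of the test. `dxestimand` represents that whole bundle as a declarative
`estimand_spec` with five attributes (population, target condition, index
test, accuracy measures, per-event strategies). Changing any attribute
changes the estimand, hence the question; the engine makes the change
mechanical and auditable.

Two result states are deliberately kept distinct throughout:

* **inconclusive** — a result exists but classifies neither way
  (intermediate or uninterpretable readings both map here, with an
  optional subtype retained in the data);
* **absent** — the decision never came into being because of an event
  (a terminated scan). A value lost *after* collection with no event
  (a deleted image) is also `absent` but carries no event occurrence and
  is handled by missing-data options, never by an event strategy.

Conflating the two would conflate "the test could not decide" with "the
test never happened", which call for different handling.

## The six strategies

Each declared interfering event is assigned exactly one strategy; all six
are pure transformations from a record to a derived decision with
provenance.

* **Diagnostic policy** ignores the event: the observed result stands.
  Its assumption is that the modified, real-world test — artefacts and
  all — is the object of interest. Absent results must be imputed; an
  event that always destroys the result is incompatible with this
  strategy and is reported as a configuration error.
* **Indicative event** folds the event into the decision rule: occurrence
  itself is read as a fixed positive (or negative) result, even when the
  observed result is absent. Sensible when occurrence correlates with the
  disease state.
* **Setback** penalizes the event: affected subjects are scored as
  misclassified relative to their true state, so accuracy decreases in
  the event frequency. It needs the true state for affected subjects; if
  the state is unknown a reference imputer must be configured.
* **Hypothetical** asks what the accuracy would be in a world where the
  event cannot occur: affected results are replaced by an imputed
  counterfactual. The package ships a registry with `constant`,
  `bernoulli(p)` (seeded), and `oracle` (reads the simulator's stored
  counterfactual) imputers; model-based imputation from covariates is a
  registration hook, not a built-in, because no canonical model form
  exists — the choice is substantive and belongs to the analyst.
* **While under monitoring** decides from pre-event measurements only,
  for tests with an observation period. Post-event values are not
  "missing"; they are simply outside the decision rule. A record affected
  by the event must carry a pre-event `partial_result` (or a registered
  `partial_rule`).
* **Principal stratum** restricts the analysis set to the subpopulation
  in whom the event would (or would not) occur. Membership is read from
  the observed occurrence; predicting membership (needed in unpaired
  comparative designs) is a documented, deliberately unimplemented
  extension point.

The first three form the composite family $g(I, E)$: the final decision
depends only on the observed result and the occurrence flag, exposed as
the truth-table function `composite_decision()`. Three exact identities
follow from the definitions and are enforced by property tests on random
tables: setback sensitivity equals indicative-negative sensitivity,
setback specificity equals indicative-positive specificity, and the
diagnostic-policy estimate is the stratum-size-weighted average of the
two principal-stratum estimates. Consequently the orderings
$Se_{IE+} \ge Se_{DP} \ge Se_{SB}$ and
$Sp_{IE-} \ge Sp_{DP} \ge Sp_{SB}$ hold on every dataset.

### Multiple events

A subject is assumed to be governed by a single event. When several
occurred, `resolve_events()` picks one governing event — earliest by
recorded time (`first_event`) or best-ranked under a declared total
priority order — and refuses ties or missing times rather than breaking
them silently. One pragmatic relaxation: under `first_event`, a record
with exactly one occurred event needs no time stamp, since the choice is
forced; times are required only where ambiguity exists.

Principal-stratum events are applied as population-membership filters
*before* the remaining events compete for governance: stratum membership
modifies the population attribute, whereas the other strategies modify
the decision, and the engine keeps those levels separate.

## Engine pipeline and numerical choices

`apply_estimand()` runs: population filter → condition resolution →
principal-stratum membership → event resolution → strategy application →
inconclusive/missing handling → measures. Choices worth knowing:

* **Intervals.** Wilson score by default, exact Clopper–Pearson by
  option. Wilson behaves well at boundary proportions (0/24-style cells
  appear routinely in strategy sweeps); no interval method is canonical
  for this setting, so the robust default won.
* **Inconclusive decisions** default to a separately reported category;
  `as_positive`, `as_negative`, and `exclude_with_warning` are options.
  The exclusion path always warns, because restricting to conclusive
  results narrows the spectrum and tends to overstate accuracy.
* **Zero cells.** Likelihood ratios with a zero denominator are reported
  as `Inf` with an `infinite` flag, not an error and not
  continuity-corrected.
* **Degenerate inputs.** An empty measure denominator is a hard error
  (never a silent zero); decisions still marked `needs_imputation` at
  measure time abort the run listing the subjects; an event that occurred
  but has no declared strategy aborts the run.
* **Determinism.** All stochastic steps (Bernoulli imputers, bootstrap)
  draw through an explicit seed in the options; two runs with identical
  inputs and seed produce byte-identical JSON reports.
* **Reference standard.** With `condition_source = "reference_result"`
  the engine maps the reference to the condition, applies the configured
  policy to inconclusive/absent references (exclude-with-warning or
  seeded Bernoulli imputation at a supplied prevalence), and stamps the
  report with a limitations note: a reference standard is a study-level
  proxy for the target condition, and that substitution is always a
  limitation.

`validate_imputation_plan()` rejects three forbidden patterns before any
estimation: an imputer attached to an event handled with the event-free
principal stratum (results of affected subjects must not be imputed into
a stratum they do not belong to); index-result imputation scoped beyond
the diseased when sensitivity alone is targeted; and reference imputation
restricted to index-positive subjects when the positive predictive value
is targeted (partial verification). These are schema-valid but
substantively wrong plans, which is why they are caught here and not by
the parser.

## Counts-only workflows and the worked example

Every strategy that is a pure function of (disease state, event
occurrence, result) — diagnostic policy, both indicative rules, setback,
both principal strata — runs directly on a `stratified_counts` table,
with no subject-level data. The hypothetical and monitoring rows are not
functions of those cells; on counts they require user-supplied corrected
counts of affected subjects classified correctly, exactly the form in
which such results are reported.

The packaged 200-subject CT study (40 diseased, 160 not; coughing as the
event) fixes those corrections at 18/24 and 37/40 for the hypothetical
row and 12/24 and 28/40 for the monitoring row. One arithmetic note: the
hypothetical specificity cell is 147/160, which is 91.88%; the source
table of the study this example mirrors prints 92.88% for that entry,
which is inconsistent with its own cells. The package reports the
fraction-derived 91.88% and treats the printed value as an erratum.

The worked records also encode a joint assignment of (observed,
counterfactual, partial) results per subject. Only the margins are
constrained by the example; the within-stratum joint assignment is
deterministic (correct counterfactuals assigned to the first subjects of
each block), which leaves every reported fraction unchanged.

## What the simulator emulates

`simulate_study()` draws, per subject: condition from the prevalence,
event occurrence from a state-specific rate (events in diagnostic studies
track the true state — diseased patients terminate more often), a
counterfactual result from baseline accuracy (`sens0`, `spec0`), an
observed result that equals the counterfactual without the event and is
otherwise drawn from degraded accuracy (`sens_ie`, `spec_ie`) or set
absent with probability `p_absent_given_ie`, and a pre-event partial
result from (`partial_sens`, `partial_spec`). Defaults are the worked
study's conditions: n = 200, prevalence 0.2, event rates 0.6 (diseased)
and 0.25 (healthy), sens0 = 0.75, spec0 = 11/12, sens_ie = 2/3,
spec_ie = 0.85, partial accuracies 0.5 and 0.7, and no absent results.

Under this model the strategies have closed-form targets
(`analytic_targets()`): with event rate $r$, the diagnostic policy
estimates $(1-r)\,acc_0 + r\,acc_{ie}$, the oracle-imputed hypothetical
estimates $acc_0$, setback estimates $(1-r)\,acc_0$, the
indicative-positive rule estimates $(1-r)\,Se_0 + r$ for sensitivity and
$(1-r)\,Sp_0$ for specificity, the strata estimate $acc_0$ and
$acc_{ie}$, and monitoring estimates $(1-r)\,acc_0 + r\,acc_{part}$.
`strategy_recovery_experiment()` verifies these by Monte Carlo.

What the simulator does **not** emulate — and therefore what passing
tests do not establish about real data: covariate-driven event mechanisms
(the event depends on the state only), imperfect reference standards (the
simulated reference is the truth), inconclusive results, correlation
between two tests' errors in paired designs beyond what the shared
condition induces, and any structure in *which* subjects are affected
beyond independent Bernoulli draws. Counterfactuals are generated for
every simulated subject because they are free and make the hypothetical
and principal-stratum oracles exact; code paths for real data refuse to
read them.

## Comparative designs

Each arm of a comparison is analyzed under its own estimand — the two
tests may legitimately use different strategy maps — and
`compare_accuracy()` contrasts the resulting sensitivities and
specificities as a difference, ratio, or odds ratio. Intervals come from
a seeded nonparametric bootstrap (2,000 resamples by default): joint
resampling of subjects when the two analysis sets are paired, independent
resampling otherwise. A bootstrap was chosen over closed-form paired
intervals because it covers all three contrast scales uniformly; no
specific interval method is canonical here. When the same event is
handled with the principal-stratum strategy for both tests of a paired
design, `paired_principal_strata()` reports the four observable strata
(event in both, neither, index only, comparator only). In an unpaired
design the stratum for the unassigned test is unobservable and would
need a prediction model; the package raises a documented error instead
of guessing one.

## Problem sizes used by the test suite

The property suites run 1,000 random count tables for the exact
identities, 240 datasets for the ordering chains, one n = 10,000 study
for parameter recovery (three binomial standard errors as the
compatibility bound), and 100 replicates of n = 300 paired studies with
500 bootstrap resamples each for interval coverage — sizes chosen so the
whole suite completes in well under a minute while keeping Monte-Carlo
error far below the effects being checked.

## Known limitations

* No ordinal or continuous index outputs, hence no ROC/AUC machinery.
* No estimation of principal-stratum membership probabilities from
  covariates; unpaired stratum analysis is an explicit stub.
* No composite or differential reference standards beyond a
  user-supplied resolved condition column; the engine only warns about
  the substitution of reference for truth.
* Imputation is rule-based (constant, Bernoulli, oracle, or
  user-registered); no model-based multiple imputation is bundled.
* The estimand itself lives in an idealized setting; the package can
  make the mapping from question to estimate explicit and auditable, but
  it cannot make an unanswerable question answerable.
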