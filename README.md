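# dxestimand

Estimands and interfering-event strategies for diagnostic test accuracy
studies.

## The problem

A diagnostic accuracy study estimates how well an index test detects a
target condition — its sensitivity Se = P(T+ | D+) and specificity
Sp = P(T− | D−) against a reference standard. In practice, events
*interfere* with the test while it is being conducted: a CT scan is cut
short by coughing or a claustrophobic seizure, a sample hemolyzes, a
reading is unblinded. Such an interfering event (IE) either distorts the
test result or leaves no result at all, and the common practice of simply
excluding affected subjects silently changes the question the study
answers and can bias the estimates.

`dxestimand` makes the question explicit. An **estimand** is declared up
front through five attributes — population, target condition, index test,
accuracy measure(s), and one handling strategy per anticipated IE — and is
then applied mechanically to the study data. Six strategies are
implemented:

| Strategy | Decision for an affected subject |
|---|---|
| diagnostic policy | the observed result, event ignored (absent results imputed) |
| indicative event | a fixed positive or negative result, the event is part of the decision rule |
| setback | the opposite of the true state (the event is penalized as a failure) |
| hypothetical | the imputed result had the event not occurred |
| while under monitoring | the decision from pre-event measurements only |
| principal stratum | analysis restricted to the stratum in whom the event would (not) occur |

The first three form a composite-test family `g(I, E)` depending only on
the observed result `I` and event occurrence `E`; they obey exact
identities (setback sensitivity = indicative-negative sensitivity; the
diagnostic-policy estimate is the stratum-size-weighted average of the two
principal-stratum estimates) that the test suite verifies on thousands of
random tables.

The package is for biostatisticians planning or analyzing diagnostic
accuracy studies: it covers subject-level CSV data and counts-only
workflows, Wilson/Clopper–Pearson intervals, comparative (paired and
unpaired) designs with bootstrap contrasts, a guard-rail validator for
forbidden imputation patterns, and a fully counterfactual study simulator.

## Worked example

The packaged example study recruits 200 patients suspected of lung
carcinoma (40 diseased, 160 not) for a CT scan, with coughing during the
scan as the interfering event:

```r
library(dxestimand)
records <- ct_example_records()        # or read_subject_table(...)
sweep_strategies(records, "coughing")
```

```
Strategy comparison (event: coughing )
 Strategy Sens w/o IE Sens w/ IE Sens comb Sensitivity Spec w/o IE Spec w/ IE Spec comb Specificity
       DP       12/16      16/24     28/40         70%     110/120      34/40   144/160         90%
       HY       12/16      18/24     30/40         75%     110/120      37/40   147/160      91.88%
      WUM       12/16      12/24     24/40         60%     110/120      28/40   138/160      86.25%
      PS1       12/16          -     12/16         75%     110/120          -   110/120      91.67%
      PS2           -      16/24     16/24      66.67%           -      34/40     34/40         85%
      IE+       12/16      24/24     36/40         90%     110/120       0/40   110/160      68.75%
      IE-       12/16       0/24     12/40         30%     110/120      40/40   150/160      93.75%
       SB       12/16       0/24     12/40         30%     110/120       0/40   110/160      68.75%
```

Same data, eight different questions: treating every coughing-terminated
scan as positive (IE+) raises sensitivity to 90% at the cost of
specificity (68.75%), while the setback row shows the accuracy when every
event is counted as a failure. (The HY specificity is 147/160 = 91.88%;
see the vignette for a note on this fraction.)

A full estimand run ties a declared specification to an auditable report:

```r
spec <- read_estimand_spec(system.file("extdata", "ct_estimand.yaml",
                                       package = "dxestimand"))
report <- apply_estimand(records_with_three_events, spec)
report$audit   # per subject: governing event, strategy fired, imputation
```

A thin CLI (`exec/dxestimand`) exposes `estimate`, `sweep`, `simulate`,
and `compare` subcommands over the same functions.

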