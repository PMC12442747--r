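# Estimand for the worked CT-scan study: accuracy (sensitivity and
# specificity) of a CT scan in detecting lung carcinoma among suspected
# patients aged 30 and above who can breathe rhythmically; early
# termination counts as a positive result; claustrophobic seizures are
# handled in a hypothetical scenario where they cannot occur.
spec_version: 1
population:
  description: >-
    Suspected lung-carcinoma cases aged 30 and above, at least two
    qualifying symptoms in the week before testing.
  filter: null
target_condition:
  label: lung_carcinoma
  definition: >-
    At least one malignant lesion restricted to the lung area.
index_test:
  id: ct_scan
  description: >-
    Thorax and abdomen CT with contrast agent, images read by a
    radiologist.
accuracy_measures:
  - sensitivity
  - specificity
interfering_events:
  arrhythmical_breathing:
    strategy: principal_stratum
    options:
      stratum: event_free
  early_termination:
    strategy: indicative_event
    options:
      fixed_result: positive
  claustrophobic_seizure:
    strategy: hypothetical
    options:
      imputer:
        name: oracle
multi_event_policy:
  policy: priority
  priority:
    - arrhythmical_breathing
    - early_termination
    - claustrophobic_seizure
condition_source: reference_result
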