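# Depression management in Australian general practice: worked example of a
# filter cascade cost-effectiveness model. Amounts in AUD; proportions are
# literature-derived point estimates.
schema_version: 1
currency: AUD
population:
  label: Australian population aged 18-75 yrs
  size: 15055403
baseline: baseline
steps:
  - label: target_group
    description: Current depression (prevalence)
    proportion: 0.089
  - label: attendance
    description: Proportion of target group attending a GP at least once per annum
    proportion: 0.81
  - label: detection
    description: Proportion detected as at risk by their GP
    proportion: 0.47
  - label: reach
    description: Proportion of detected patients offered evidence-based treatment
    proportion: 0.28
  - label: adherence
    description: Proportion of offered patients adherent to treatment
    proportion: 0.51
  - label: outcome
    description: Proportion achieving remission at 6 months follow-up
    proportion: 0.37
scenarios:
  baseline:
    description: Usual care, no intervention
  filter1:
    description: Routine waiting-room screening for depression (touchscreen questionnaire)
    overrides:
      detection: {proportion: 0.77, unit_cost: 5, is_intervention: true}
  filter2:
    description: GP education and training in depression management
    overrides:
      reach: {proportion: 0.69, unit_cost: 247, is_intervention: true}
  filter3:
    description: Telephone follow-ups to support patient adherence
    overrides:
      adherence: {proportion: 0.65, unit_cost: 98, is_intervention: true}
bounds:
  - scenario: filter1
    step: detection
    field: proportion
    lower: 0.47
    upper: 0.77
report:
  rounding: true
  format: table
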