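# Example run configuration: the default study design.
# Omitted keys fall back to package defaults; unknown keys are rejected.
n_persons: 25
seed: 1
schedule:
  n_days: 21
  slots_per_day: 6
  first_hour: 8
  window_hours: 2
  intervention_start_day: 4
trigger:
  probs: [0.25, 0.25, 0.25, 0.25]
  cutoff: 5
  L: 2
  baseline_end_day: 7
  min_baseline: 7
  max_per_day: 2
population:
  compliance_mean: 0.85
  compliance_sd: 0.16
  careless_prob: 0.015
analysis:
  person_rate_threshold: 0.70
  cohort_share_threshold: 0.70
  careless_threshold: 0.05
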