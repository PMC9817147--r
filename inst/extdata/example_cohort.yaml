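# Example simulated cohort: 12 controls plus 50 patients spread over the
# lesion groups of an acute-stroke study, each patient drawn from a
# response archetype (synthetic stand-ins; no clinical data involved).
n_controls: 12
master_seed: 20260927
tasks: [audiometry, tin, lateralization]
roster:
  - {archetype: categorical,        group: bs_l,    "n": 1}
  - {archetype: side_oriented,      group: bs_l,    "n": 1}
  - {archetype: control,            group: bs_l,    "n": 1}
  - {archetype: side_oriented,      group: bs_r,    "n": 2}
  - {archetype: control,            group: bs_r,    "n": 2}
  - {archetype: shifted,            group: thal_l,  "n": 3}
  - {archetype: lr_confusion,       group: thal_l,  "n": 1}
  - {archetype: control,            group: bg_l,    "n": 7}
  - {archetype: high_variability,   group: bg_r,    "n": 2}
  - {archetype: shifted,            group: bg_r,    "n": 1}
  - {archetype: task_failure,       group: bg_r,    "n": 1}
  - {archetype: high_variability,   group: multi_l, "n": 3}
  - {archetype: control,            group: multi_l, "n": 3}
  - {archetype: task_failure,       group: multi_l, "n": 1}
  - {archetype: high_variability,   group: multi_r, "n": 3}
  - {archetype: task_failure,       group: multi_r, "n": 1}
  - {archetype: shifted,            group: multi_r, "n": 2}
  - {archetype: no_binaural_benefit, group: multi_r, "n": 3}
  - {archetype: flattened_itd,      group: occi_l,  "n": 1}
  - {archetype: control,            group: occi_l,  "n": 2}
  - {archetype: control,            group: cereb_l, "n": 2}
  - {archetype: flattened_itd,      group: cereb_r, "n": 1}
  - {archetype: control,            group: cereb_r, "n": 1}
  - {archetype: high_variability,   group: multi_b, "n": 3}
  - {archetype: categorical,        group: multi_b, "n": 2}
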