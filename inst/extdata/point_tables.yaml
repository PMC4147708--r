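# Default nutrient-profile point tables. A component scores k points when
# its amount strictly exceeds the k-th threshold (increment * k).
energy_kj:
  increment: 335
  cap: 10
saturated_fat_g:
  increment: 1
  cap: 30
sugars_g:
  increment: 4.5
  cap: 10
sodium_mg:
  increment: 90
  cap: 30
protein_g:
  increment: 1.6
  cap: 5
fiber_g:
  increment: 0.9
  cap: 2
v_lookup:
  cuts: [40, 60, 80]
  points: [1, 2, 5]
  full_points: 8
protein_cap_rule:
  enabled: false
  baseline_threshold: 13
  v_required: 5
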