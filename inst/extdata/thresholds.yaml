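# Default traffic-light thresholds. green: value <= green_max;
# red: value > red_exceeds (or, foods only, per-portion amount >
# portion_red_exceeds); amber otherwise. Salt in g salt equivalent.
food:
  total_fat:
    green_max: 3.0
    red_exceeds: 20.0
    portion_red_exceeds: 21.0
  saturated_fat:
    green_max: 1.5
    red_exceeds: 5.0
    portion_red_exceeds: 6.0
  sugars:
    green_max: 5.0
    red_exceeds: 12.5
    portion_red_exceeds: 15.0
  salt:
    green_max: 0.30
    red_exceeds: 1.50
    portion_red_exceeds: 2.40
drink:
  total_fat:
    green_max: 1.5
    red_exceeds: 10.0
  saturated_fat:
    green_max: 0.75
    red_exceeds: 2.5
  sugars:
    green_max: 2.5
    red_exceeds: 6.3
  salt:
    green_max: 0.30
    red_exceeds: 1.50
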