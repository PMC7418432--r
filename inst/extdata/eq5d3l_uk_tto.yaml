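# EQ-5D-3L value set: UK general-population time-trade-off tariff.
# Utility = 1 - constant (if any dimension > level 1)
#             - sum of per-dimension level decrements
#             - n3 (if any dimension at level 3).
# Worst state 33333 scores -0.594; full health 11111 scores exactly 1.
name: uk_tto
constant: 0.081
n3: 0.269
dimensions:
  mobility:
    level2: 0.069
    level3: 0.314
  self_care:
    level2: 0.104
    level3: 0.214
  usual_activities:
    level2: 0.036
    level3: 0.094
  pain_discomfort:
    level2: 0.123
    level3: 0.386
  anxiety_depression:
    level2: 0.071
    level3: 0.236
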