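# Default intervention costing ledger: a 12-session home-based physiotherapy
# programme delivered to 238 participants (2016 GBP).
# Quantity rules are evaluated against n_participants / n_sessions; resolved
# quantities and annuitized unit costs are reported (and multiplied) at 2 d.p.
# Items marked per_visit scale with n_sessions in session-count scenarios.
currency: GBP
base_year: 2016
n_participants: 238
n_sessions: 12
sections:
  therapist_training:
    - label: trainer_time
      unit_cost: 165.00       # lead-therapist day rate
      quantity: 1.75
    - label: room_hire
      unit_cost: 150.00
      quantity: 2
    - label: training_materials
      unit_cost: 3.50
      quantity: 14            # therapists trained
  therapy_sessions:
    - label: therapist_time
      unit_cost: 43.62        # per visit
      quantity_rule: n_participants * n_sessions
      per_visit: true
    - label: consumables
      unit_cost: 1.20         # clinical notes, per visit
      quantity_rule: n_participants * n_sessions
      per_visit: true
    - label: travel
      unit_cost: 8.00         # per visit
      quantity_rule: n_participants * n_sessions
      per_visit: true
  patient_equipment:
    - label: printed_materials
      unit_cost: 2.00
      quantity_rule: n_participants
    - label: dvds
      unit_cost: 0.08
      quantity_rule: n_participants
    - label: weighted_vests
      unit_cost: 54.16
      quantity_rule: (n_participants / 5) / 2   # 1 in 5 used one, shared by two
    - label: balance_pads
      unit_cost: 19.41
      quantity_rule: (n_participants / 2) / 2   # 1 in 2 used one, shared by two
    - label: step_counts
      unit_cost: 11.99
      quantity_rule: n_participants / 15        # 1 in 15 used one
      annuitize:              # equipment outlives the trial: annual equivalent
        rate: 0.035           # discount rate
        lifespan: 2           # years
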