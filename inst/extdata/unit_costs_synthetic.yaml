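# SYNTHETIC unit-cost table (illustrative 2016 GBP values, not sourced from
# any national schedule). Each resource item maps to a costing category for
# perspective totals and to an imputation group (mi_group) for category-level
# missing-data handling: nhs_ex_hosp, hospitalisation, social_care.
# Medication is costed for audit but excluded from analysis totals.
currency: GBP
base_year: 2016
items:
  gp_visit:
    unit_cost: 36.00
    category: primary_care
    mi_group: nhs_ex_hosp
  nurse_visit:
    unit_cost: 11.00
    category: primary_care
    mi_group: nhs_ex_hosp
  physio_visit:
    unit_cost: 53.00
    category: primary_care
    mi_group: nhs_ex_hosp
    routine_physio: true
  ambulance:
    unit_cost: 236.00
    category: secondary_care
    mi_group: nhs_ex_hosp
  outpatient_visit:
    unit_cost: 117.00
    category: secondary_care
    mi_group: nhs_ex_hosp
  hospital_day:
    unit_cost: 586.00
    category: secondary_care
    mi_group: hospitalisation
  home_care_visit:
    unit_cost: 26.00
    category: social_care
    mi_group: social_care
  meals_on_wheels:
    unit_cost: 7.00
    category: social_care
    mi_group: social_care
  medication:
    unit_cost: 15.00
    category: medication
    mi_group: medication
    excluded: true
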