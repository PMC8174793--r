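specs:
- name: census_division
  kind: categorical
  categories:
  - new_england
  - middle_atlantic
  - east_north_central
  - west_north_central
  - south_atlantic
  - east_south_central
  - west_south_central
  - mountain
  - pacific
  reference: new_england
  elicitation_mode: rate_per_category
- name: msa_status
  kind: categorical
  categories:
  - self_representing
  - msa_non_self_rep
  - non_msa
  reference: self_representing
  elicitation_mode: rate_per_category
- name: domain
  kind: categorical
  categories:
  - low_minority
  - moderate_minority
  - high_minority
  reference: low_minority
  elicitation_mode: rate_per_category
- name: age_householder
  kind: categorical
  categories:
  - 18_44
  - 45_59
  - 60_plus
  - missing
  reference: 18_44
  elicitation_mode: rate_per_category
- name: income_10k
  kind: continuous
  elicitation_mode: change_per_unit
- name: mail_delivery
  kind: categorical
  categories:
  - curbline
  - door_slot
  - central
  - other
  reference: curbline
  elicitation_mode: rate_per_category
- name: listing_procedure
  kind: categorical
  categories:
  - on_foot_alone
  - on_foot_pair
  - car_alone
  - car_pair
  reference: on_foot_alone
  elicitation_mode: rate_per_category
- name: non_english_evidence
  kind: categorical
  categories:
  - 'no'
  - 'yes'
  reference: 'no'
  elicitation_mode: rate_per_category
- name: contact_status
  kind: categorical
  categories:
  - never
  - ever
  - previous_attempt
  reference: never
  elicitation_mode: rate_per_category
- name: concerns_status
  kind: categorical
  categories:
  - none
  - ever
  - previous_attempt
  - strong_ever
  reference: none
  elicitation_mode: rate_per_category
- name: attempt_number
  kind: continuous
  elicitation_mode: change_per_unit
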