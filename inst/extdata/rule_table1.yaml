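version: table1
indicators:
- name: prior_back_surgery
  role: including
  field: prior_back_surgery
  comparator: eq
  threshold: yes
  label: 'Prior back surgery: yes'
- name: pain_location
  role: including
  field: pain_location
  comparator: in
  threshold:
  - leg
  - mixed
  label: 'Pain location: leg/mixed'
- name: neuropathic_pain
  role: including
  field: dn4_score
  comparator: gt
  threshold: 3.0
  label: 'Neuropathic pain: DN4 > 3'
- name: pain_duration
  role: including
  field: pain_duration_months
  comparator: ge
  threshold: 3.0
  label: Pain duration >= 3 months
- name: leg_ge_back
  role: including
  field: nprs_leg
  comparator: ge_field
  threshold: nprs_back
  label: Leg pain >= back pain
- name: nprs_leg
  role: including
  field: nprs_leg
  comparator: ge
  threshold: 5.0
  label: NPRS leg >= 5
- name: absolute_contraindication
  role: excluding
  field: absolute_contraindication
  comparator: eq
  threshold: yes
  label: Absolute contraindications
- name: widespread_pain
  role: excluding
  field: widespread_pain
  comparator: eq
  threshold: yes
  label: Widespread pain
- name: substance_abuse
  role: excluding
  field: substance_abuse
  comparator: eq
  threshold: yes
  label: Alcohol/drugs abuse
- name: responded_conservative
  role: excluding
  field: responded_conservative
  comparator: eq
  threshold: yes
  label: Response to PRF/TENS/medication
- name: prior_scs
  role: excluding
  field: prior_scs
  comparator: eq
  threshold: yes
  label: Prior SCS treatment
- name: anatomic_abnormality
  role: excluding
  field: anatomic_abnormality
  comparator: eq
  threshold: yes
  label: Anatomic abnormalities
- name: age_le_18
  role: excluding
  field: age_years
  comparator: le
  threshold: 18.0
  label: Age <= 18 years
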