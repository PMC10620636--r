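# Synthetic cohort: HDL cholesterol in serum (LOINC 14646-4), mmol/L.
# Right-skewed (lognormal) physiology, higher in women, with a
# low-HDL dyslipidemia component linked to E78.* diagnoses.
site_id: lakeside
n_patients: 1500
seed: 71503
age:
  dist: normal
  mean: 58
  sd: 16
  min: 18
  max: 98
sex_props:
  female: 0.54
  male: 0.46
cases_per_patient:
  dist: fixed
  value: 1
measurements_per_case:
  dist: fixed
  value: 1
analytes:
  - loinc: "14646-4"
    unit: mmol/L
    physio:
      family: lognormal
      mu: 0.20
      sigma: 0.28
      sex_offset:
        female: 0.18
        male: 0.0
    patho:
      - fraction: 0.15
        shift: -0.45
        icd_prefix: E78
        p_icd: 0.8
    devices:
      - analyzer_id: GUDID-20144
        kit_id: KIT-HDL-1
        weight: 1.0
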