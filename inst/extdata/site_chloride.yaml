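# Synthetic university-hospital cohort: serum chloride (LOINC 2075-0).
# Gaussian physiology around 101 mmol/L with a hyperchloremia tail linked
# to disorders of fluid/electrolyte balance (E87.*).
site_id: inselweid
n_patients: 2000
seed: 20211
age:
  dist: uniform
  min: 18
  max: 95
sex_props:
  female: 0.49
  male: 0.49
  other: 0.01
  unknown: 0.01
cases_per_patient:
  dist: poisson
  lambda: 0.4
measurements_per_case:
  dist: poisson
  lambda: 0.3
analytes:
  - loinc: "2075-0"
    unit: mmol/L
    physio:
      family: gaussian
      mu: 101.0
      sigma: 2.7
      age_slope: 0.01
    patho:
      - fraction: 0.12
        shift: 8.0
        icd_prefix: E87
        p_icd: 0.75
    devices:
      - analyzer_id: GUDID-00811
        kit_id: KIT-CL-A
        weight: 0.7
      - analyzer_id: GUDID-00812
        kit_id: KIT-CL-B
        weight: 0.3
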