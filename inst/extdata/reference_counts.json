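{
  "description": "Printed area and case counts from the original clinical evaluation of the two-index NL-MPM classifier on colorectal mucosa. Cancer is the positive class.",
  "two_index_classifier": {
    "normal_areas_total": 64,
    "normal_areas_classified_normal": 54,
    "cancer_areas_total": 80,
    "cancer_areas_classified_cancer": 77,
    "cancer_areas_two_index_pattern": 61
  },
  "pathologist_reading": {
    "normal_cases_total": 16,
    "normal_cases_called_normal": 16,
    "cancer_cases_total": 20,
    "cancer_cases_called_cancer": 20
  },
  "shg_loss": {
    "cancer_patients_with_diminished_shg": 19,
    "cancer_patients_total": 20
  }
}
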