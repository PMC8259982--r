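# published per-patient clinical feature sets encoded as term identifiers
patient_id	terms
PMS1	dev_delay;language_delay;seizures;hypotonia;sleep_issues;gi_issues;head_shape;periorbital_puffiness;eye_abnormalities;ear_abnormalities;broad_nasal_tip;behavioral_issues;kidney_reflux;skeletal_abnormalities;hyperconvex_fingernails
PMS2	dev_delay;language_delay;seizures;hypotonia;sleep_issues;gi_issues;eye_abnormalities;ear_abnormalities;broad_nasal_tip;behavioral_issues;skeletal_abnormalities
PMS3	dev_delay;language_delay;hypotonia;head_shape;periorbital_puffiness;eye_abnormalities;ear_abnormalities;broad_nasal_tip;behavioral_issues;kidney_reflux;hyperconvex_fingernails
PMS4	dev_delay;language_delay;behavioral_issues
PMS5	dev_delay;language_delay;seizures;hypotonia;sleep_issues;gi_issues;head_shape;ear_abnormalities;broad_nasal_tip;behavioral_issues
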