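# Code-list vocabulary for the RA and T2DM phenotype algorithms.
# These are placeholder clinical vocabularies standing in for institutional
# code sets (the algorithm roles are fixed; the codes are configuration).
# Pattern dialect: exact codes, or a trailing "*" prefix wildcard; "." is
# literal; matching is case-insensitive.
ra_dx:
  - system: ICD9CM
    codes: ["714.*"]
  - system: ICD10CM
    codes: ["M05.*", "M06.*"]
sle_dx:
  - system: ICD9CM
    codes: ["710.0"]
  - system: ICD10CM
    codes: ["M32.*"]
pa_dx:
  - system: ICD9CM
    codes: ["696.0"]
  - system: ICD10CM
    codes: ["L40.5*"]
ra_exclusion:
  # other inflammatory arthritides / connective-tissue disease that
  # disqualify a patient from the RA control pool
  - system: ICD9CM
    codes: ["710.*", "696.*", "720.0"]
  - system: ICD10CM
    codes: ["M32.*", "L40.*", "M45.*"]
rf_lab:
  - system: LAB
    codes: ["RF"]
t1dm_dx:
  - system: ICD9CM
    codes: ["250.01", "250.03", "250.11", "250.13"]
  - system: ICD10CM
    codes: ["E10.*"]
t2dm_dx:
  - system: ICD9CM
    codes: ["250.00", "250.02", "250.10", "250.12", "250.40", "250.60"]
  - system: ICD10CM
    codes: ["E11.*"]
t1dm_med:
  - system: MED
    codes: ["INSULIN*"]
t2dm_med:
  - system: MED
    codes: ["METFORMIN", "GLIPIZIDE", "GLYBURIDE", "PIOGLITAZONE", "SITAGLIPTIN"]
dm_related_dx:
  # any diabetes-adjacent diagnosis that disqualifies a T2DM control:
  # all diabetes codes, abnormal-glucose findings, gestational diabetes
  - system: ICD9CM
    codes: ["250.*", "790.2*", "648.8*"]
  - system: ICD10CM
    codes: ["E08.*", "E09.*", "E10.*", "E11.*", "E13.*", "R73.*", "O24.*"]
dm_supplies:
  - system: MED
    codes: ["TEST-STRIPS", "LANCETS", "GLUCOMETER"]
glucose_lab:
  - system: LAB
    codes: ["GLU-F", "GLU-R"]
fasting_glucose_lab:
  # subset of glucose_lab to which the fasting threshold applies
  - system: LAB
    codes: ["GLU-F"]
hba1c_lab:
  - system: LAB
    codes: ["HBA1C"]
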