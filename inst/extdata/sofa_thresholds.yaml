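# Six-organ-system SOFA subscore thresholds (Sepsis-3 convention), version 1.
# Each component maps a raw measurement to an integer subscore 0-4.
# "cutoffs" are read in order; for direction "below" the subscore is the
# number of cutoffs the value falls strictly below, for "at_or_above" the
# number of cutoffs the value meets or exceeds.
version: 1
respiration:
  measurement: pao2_fio2
  unit: mmHg
  direction: below
  cutoffs: [400, 300, 200, 100]
  # Subscores 3-4 additionally require respiratory support; without an
  # on_ventilation flag the respiration subscore is capped at this value.
  cap_without_support: 2
coagulation:
  measurement: platelets
  unit: 10^3/uL
  direction: below
  cutoffs: [150, 100, 50, 20]
liver:
  measurement: bilirubin
  unit: mg/dL
  direction: at_or_above
  cutoffs: [1.2, 2.0, 6.0, 12.0]
cardiovascular:
  measurement: map
  unit: mmHg
  direction: below
  cutoffs: [70]
  # Vasopressor dose tiers are collapsed to presence/absence: any
  # vasopressor support scores this value regardless of MAP.
  vasopressor_score: 2
cns:
  measurement: gcs
  unit: GCS points
  direction: below
  cutoffs: [15, 13, 10, 6]
renal:
  measurement: creatinine
  unit: mg/dL
  direction: at_or_above
  cutoffs: [1.2, 2.0, 3.5, 5.0]
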