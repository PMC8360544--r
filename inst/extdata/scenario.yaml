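# Default scenario configuration for the mouthwash cost-effectiveness model.
# All monetary values are 2020 international dollars unless noted.
rrr: 0.30                  # relative risk reduction applied to the mouthwash arm
covid:
  mode: absolute_pp        # absolute_pp or calibrated
  pneumonia_increment: 0.018
  calibrated_increment: 0.0028
  per_patient_cost: 254
wtp:
  min: 0
  max: 30000
  step: 250
psa:
  n_iterations: 10000
  seed: 20210812
  cost_cv: 0.2             # coefficient of variation for gamma cost draws
  mv_effective_n: 39       # effective sample size for the expert-opinion MV beta
display:
  zar_per_intl_usd: 17.35
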