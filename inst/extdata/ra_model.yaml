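# RA scoring model: logit = intercept + sum(weight * log1p(count)).
# Weights are configuration (the published algorithm does not print its
# fitted coefficients); signs follow the documented structure and the
# cutoff is the published 0.632.
intercept: -4.2
weights:
  n_ra_dx: 2.2
  n_sle_dx: -1.3
  n_pa_dx: -1.1
  n_rf_lab: 0.1
  n_rf_positive: 1.4
  n_encounters: -0.25
transform: log1p
cutoff: 0.632
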