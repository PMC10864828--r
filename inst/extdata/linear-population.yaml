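# Linear growth population: mean trajectory 3 + 0.2 t over five yearly
# waves, intercept-slope correlation 0.3, 50% explained variance per wave,
# and an external covariate W correlated with intercept and slope.
form: linear
alpha: [3.0, 0.2]
psi: [1.0, 0.15, 0.25]   # lower triangle, row by row
time_codes: [0, 1, 2, 3, 4]
r2: 0.5
covariate:
  r_intercept: 0.2
  r_slope: -0.1
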