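# Phenotypic-age (PhenoAge) linear-predictor weights, version 1.
# Source: published phenotypic-age training coefficients (NHANES III,
# Gompertz mortality model); units are the training units and must be
# matched via harmonize_units() before scoring.  transform = log means the
# natural log is applied to the marker before weighting.
# The Gompertz constants used with these weights: gamma = 0.0076927 per
# month, horizon = 120 months, outer constants 141.50225, -0.00553,
# 0.090165.
marker,transform,unit,weight
intercept,identity,,-19.9067
chronological_age,identity,years,0.0804
albumin,identity,g/L,-0.0336
creatinine,identity,umol/L,0.0095
glucose,identity,mmol/L,0.1953
crp,log,mg/dL,0.0954
lymph_pct,identity,percent,-0.0120
mcv,identity,fL,0.0268
rdw,identity,percent,0.3306
alp,identity,U/L,0.00188
wbc,identity,1e9/L,0.0554
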