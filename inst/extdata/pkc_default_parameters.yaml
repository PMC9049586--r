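# Shipped default parameterization of the PKC life-cycle model.
# Units: first-order rate constants in s^-1; bimolecular constants per
# concentration unit of the partner (ng/ml, nM for the activator, model
# units for clamped levels) per second. lambda4 equals 0.00008 per minute
# expressed in per-second units (mature pool half-life about six days).
# k3 and k15 are frozen from the deterministic calibration against the
# printed anchors (73 ng/ml post-synthesis plateau; 10 ng/ml first
# sequential-pulse drop); see calibrateDefaults().
parameters:
  k1: 0.2
  k2: 0.001
  k3: 0.09333353556
  k4: 0.04
  k5: 0.001
  k6: 0.05
  k7: 0.02
  k8: 0.001
  k9: 2.0e-05
  k10: 0.001
  k11: 0.05
  k12: 4.0e-05
  k13: 0.001
  k14: 0.05
  k15: 8.067354827
  k16: 2.0
  k17: 0.008
  k18: 5.0e-07
  k19: 1.0e-04
  k20: 5.0e-04
  lambda1: 0.001
  lambda2: 1.0e-04
  lambda3: 0.001
  lambda4: 1.3333333333333334e-06
  lambda5: 0.0
  T: 1.0
  PDK1: 1.0
  mTORC2: 1.0
  HSP70: 1.0
  mRNA0: 2.0
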