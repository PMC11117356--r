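# Final covariate model for meropenem in neonatal/pediatric ECMO +/- CRRT.
# One-compartment; CL and V scale proportionally with body weight
# (reference 7.88 kg); CRRT multiplies V by (1 + theta_crrt).
# IIV variances are log-scale (NONMEM convention); residual error is
# proportional with variance sigma2_prop.
clp: 1.09          # L/h at 7.88 kg
vp: 3.98           # L at 7.88 kg, off CRRT
theta_crrt: 1.04   # fractional V increase on CRRT
omega2_cl: 0.0887
omega2_v: 0.916
sigma2_prop: 0.17
bw_ref: 7.88       # kg
rse_percent:
  clp: 8
  vp: 14
  theta_crrt: 76
  omega2_cl: 48
  omega2_v: 68
  sigma2_prop: 17
bootstrap_ci:
  clp: [0.98, 1.21]
  vp: [2.22, 7.30]
  theta_crrt: [0.14, 2.20]
  omega2_cl: [0.0429, 0.1510]
  omega2_v: [0.060, 1.729]
  sigma2_prop: [0.119, 0.225]
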