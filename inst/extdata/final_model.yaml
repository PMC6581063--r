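# Final population-model parameters (one-compartment IV infusion,
# CrCl-on-clearance, weight-scaled volume).  Any key may be overridden;
# omitted keys keep these defaults.
tvcl: 1.30          # typical clearance at the reference CrCl, L/h
theta_crcl: 0.023   # clearance slope, L/h per ml/min of CrCl
crcl_ref: 33.8      # reference (derivation-cohort mean) CrCl, ml/min
tvv: 1.23           # typical volume of distribution, L/kg
omega_cl: 0.544     # SD of the log-scale random effect on clearance
omega_v: 0.225      # SD of the log-scale random effect on volume
sigma_add: 2.46     # additive residual SD, mg/L
sigma_prop2: 0.001  # proportional residual variance
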