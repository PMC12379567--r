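{
  "renal_extraction": 0.0573309730355052,
  "k_brain_in": 0.0132108930523321,
  "kappa_bone": 0.00375565240605803,
  "k_in": {
    "liver": 3.0024762389348,
    "kidney": 0.500196880934499,
    "rest": 4
  },
  "k_out": {
    "liver": 0.003,
    "kidney": 0.00509,
    "rest": 0.00133
  },
  "birth_amounts": {
    "plasma": 0.65,
    "bone": 90,
    "brain": 72,
    "liver": 39,
    "kidney": 5,
    "rest": 100
  },
  "scale_uptake_with_mass": true,
  "provenance": {
    "calibrated": ["renal_extraction", "k_brain_in", "kappa_bone", "k_in.liver", "k_in.kidney"],
    "method": "calibrate() against adult dietary-background tissue levels of the typical individual (see calibration_targets())",
    "fixed_by_convention": ["k_in.rest", "k_out", "birth_amounts"],
    "literature_constants_elsewhere": "dietary intake tiers, oral bioavailability, depot release rates, dw/ww conversion factors and thresholds are literature-anchored and live in dosing/assessment modules"
  }
}
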