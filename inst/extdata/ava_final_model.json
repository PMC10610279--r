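{
  "Tlag_pop": 0.17,
  "Tk0_pop": 1.35,
  "CL_pop": 56.15,
  "V1_pop": 208.34,
  "Q_pop": 14.63,
  "V2_pop": 76.15,
  "beta_Tk0_Formulation#2": -0.4,
  "beta_Tk0_Formulation#3": -0.68,
  "beta_V1_Formulation#2": -1.26,
  "beta_V1_Formulation#3": -1.24,
  "omega_Tlag": 0.38,
  "omega_Tk0": 0.24,
  "omega_CL": 0.21,
  "omega_V1": 0.15,
  "omega_Q": 0.47,
  "omega_V2": 0.24,
  "corr_V1_CL": 0.72,
  "b": 0.14,
  "reference_category": "#1"
}
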