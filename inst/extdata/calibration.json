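{
  "circuit": {
    "K_sat": 0.2,
    "hill": 3,
    "tau_cic": 0.3,
    "theta_tll": 2.2,
    "theta_hkb": 19,
    "tau_latency": 0.8,
    "k_prod_T": 1,
    "k_dec_T": 0.02,
    "k_prod_H": 1,
    "k_dec_H": 0,
    "theta_T_on": 5,
    "theta_H_off": 33.5,
    "window_close": 15,
    "e_maint": 0.02
  },
  "spatial": {
    "D": 125,
    "alpha": 0.8,
    "beta": 0.2,
    "dx": 1,
    "safety": 0.4
  },
  "sweep_bottom": 0.3525,
  "note": "Defaults produced by calibrate_circuit() on the default grid; integrator state persists through mitosis (no reset)."
}
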