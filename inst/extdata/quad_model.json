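{
  "quad": {
    "type": "quad",
    "alpha1": 9,
    "beta1": 1,
    "beta2": 2,
    "k3": 1,
    "gamma1": 9,
    "sigma1": 1,
    "sigma2": 2,
    "k4": 1,
    "a1": 1.8,
    "b1": 0.1,
    "b2": 2,
    "k1": 1,
    "d2": 3,
    "alpha0": 0.02,
    "gamma0": 0.02,
    "a0": 0.02,
    "d_star": 0.01
  },
  "schedule": {
    "type": "schedule",
    "k0_star": 0.52,
    "t1": 500,
    "t2": 3500,
    "psi": 0.0005
  },
  "noise": {
    "type": "noise",
    "omega1": 0.04,
    "omega2": 0.08,
    "omega3": 0.08
  }
}
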