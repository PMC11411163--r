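{
  "gamma0": 1.57,
  "rho_s": 0.33,
  "alpha0": 1.39,
  "K": 3.29,
  "n": 4.46,
  "beta0": 6.1,
  "k": 19,
  "m": 1,
  "delta": 0.1,
  "mu": 1e-07,
  "r_s": 4.17,
  "K_s": 0.1,
  "d": 0
}
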