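# Reference simulation parameter set: burst Q = 100, trafficking time 2 s
label: table1_q100_mu2
geometry:
  Rr_um: 2.5
  rs_nm: 4.0
  n: 10000
  d_um: 26.5
medium:
  D_m2s: 1.18e-10
  rm_nm: 1.75
emission:
  Q: 100
  delta_t_ms: 10.0
  t_end_s: 10.0
kinetics:
  trafficking_time_s: 2.0
numerics:
  dt_particle_ns: 100.0
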