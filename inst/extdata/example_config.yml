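# Example run configuration: every key is optional and falls back to the
# package default. Units: ps, Angstrom, cubic Angstrom, m/s, kg/m^3.
seed: 1
outdir: trxss_run
schedule:
  delays: [-3, -1, 0, 0.5, 1, 1.5, 2, 3, 5, 8, 10, 20, 50, 100]
  repetitions: 50
  reference_delay: -100
  reference_interval: 7
trajectory:
  dRg_step: 1.0
  dVp_step: 220
  T_osc: 3.6
  tau_osc: 6
  irf_fwhm: 0.5
noise:
  sigma_rel: 0.001
  outlier_fraction: 0.2
  outlier_scale: 0.02
reduction:
  center: 1.4
  half_width: 0.1
  threshold: 2.0
guinier:
  Ne: 9900
  rho_b: 0.34
  Rg0: 17
  Vp0: 23000
  q_range: [0.02, 0.08]
kinetics:
  irf_fwhm: 0.5
sphere:
  v_l: 2000
  v_t: 1000
  d_P: 1350
  R: 21.95
  d_m: 1000
  v_m: 1483
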