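# Forced-degradation design: untreated control, a moderate base-stress
# arm (pH 10-like: shifts only) and a strong oxidative-stress arm
# (H2O2-like: large shifts plus disappearing spin systems), three
# replicates each. Shift scales are set so expected average CCSDs are
# roughly 2 / 8 / 12 ppb (E[CCSD] = 886 * sigma_H ppb when the scaled
# 13C scale matches the 1H scale).
name: stress_demo
seed: 20220902
simulate:
  n_peaks: 110
  reference_batch: batch_ref
  noise_sd: 0.005
  grid: [256, 128]
  lineshape: {fwhm_h: 0.02, fwhm_c: 0.2, shape: gaussian}
  arms:
    - label: control
      n_replicates: 3
      model: {shift_sd_h: 0.002, shift_sd_c: 0.008, shift_magnitude_mode: gaussian,
              p_disappear: 0.0, intensity_jitter_cv: 0.05}
    - label: ph10
      n_replicates: 3
      model: {shift_sd_h: 0.009, shift_sd_c: 0.0359, shift_magnitude_mode: gaussian,
              p_disappear: 0.0, intensity_jitter_cv: 0.05}
    - label: h2o2
      n_replicates: 3
      model: {shift_sd_h: 0.0135, shift_sd_c: 0.0538, shift_magnitude_mode: gaussian,
              p_disappear: 0.12, intensity_jitter_cv: 0.10}
ccsd:
  tol_h: 0.02
  tol_c: 0.2
  scaling_c: 0.251
  by_label: true
chemometrics:
  n_components: 2
comparison:
  reference: control_r1
  comparisons:
    - {query: ph10_r1, kind: stress}
    - {query: h2o2_r1, kind: stress}
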