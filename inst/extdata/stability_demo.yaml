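# Long-term stability design: one batch followed over four time points,
# compared against the T0 reference peak list. Perturbation scales grow
# mildly with time, giving average CCSDs of a few ppb.
name: stability_demo
seed: 20220901
simulate:
  n_peaks: 110
  reference_batch: batch_ref
  noise_sd: 0.005
  grid: [256, 128]
  lineshape: {fwhm_h: 0.02, fwhm_c: 0.2, shape: gaussian}
  arms:
    - label: T0
      n_replicates: 1
      model: {shift_sd_h: 0.002, shift_sd_c: 0.008, shift_magnitude_mode: gaussian,
              p_disappear: 0.0, intensity_jitter_cv: 0.05}
    - label: T7
      n_replicates: 1
      model: {shift_sd_h: 0.003, shift_sd_c: 0.012, shift_magnitude_mode: gaussian,
              p_disappear: 0.0, intensity_jitter_cv: 0.05}
    - label: T30
      n_replicates: 1
      model: {shift_sd_h: 0.004, shift_sd_c: 0.016, shift_magnitude_mode: gaussian,
              p_disappear: 0.0, intensity_jitter_cv: 0.05}
    - label: T60
      n_replicates: 1
      model: {shift_sd_h: 0.005, shift_sd_c: 0.020, shift_magnitude_mode: gaussian,
              p_disappear: 0.0, intensity_jitter_cv: 0.05}
ccsd:
  tol_h: 0.02
  tol_c: 0.2
  scaling_c: 0.251
  by_label: true
chemometrics:
  n_components: 2
comparison:
  reference: T0_r1
  comparisons:
    - {query: T7_r1, kind: timepoint}
    - {query: T30_r1, kind: timepoint}
    - {query: T60_r1, kind: timepoint}
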