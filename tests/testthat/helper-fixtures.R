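# Small in-code fixtures shared across test files.

# three-peak toy list with hand-chosen shifts
toy_peaklist <- function(id = "toy") {
  peaklist(c("ssA", "ssB", "ssC"),
           delta_h = c(0.512, -0.250, 1.300),
           delta_c = c(12.345, 19.800, 23.100),
           intensity = c(1.5, 0.8, 2.0),
           spectrum_id = id)
}

# shift every peak of a list by fixed ppm offsets, keeping labels
shift_peaklist <- function(pl, dh = 0, dc = 0, id = "shifted") {
  peaklist(pl$label, pl$delta_h + dh, pl$delta_c + dc, pl$intensity,
           spectrum_id = id)
}

# tiny 4 x 5 spectrum with known values
toy_spectrum <- function() {
  spectrum2d(axis_h = c(0.0, 0.1, 0.2, 0.3, 0.4),
             axis_c = c(10, 11, 12, 13),
             intensities = matrix(seq_len(20), nrow = 4, byrow = TRUE))
}

# logical index of axis points inside [lo, hi]
in_region_idx <- function(axis, lo, hi) axis >= lo & axis <= hi

# independent computation of the flat bin index (13C major, 1H minor)
# for a point, mirroring half-open cells with a closed upper boundary
expected_bin_index <- function(region, h, c) {
  bh <- min(floor((h - region$h_min) / region$bin_h) + 1, region$n_bins_h)
  bc <- min(floor((c - region$c_min) / region$bin_c) + 1, region$n_bins_c)
  (bc - 1) * region$n_bins_h + bh
}

# three-arm forced-degradation scenario used by chemometrics and
# acceptance tests (control / moderate shifts / large shifts + drops)
stress_scenario <- function(seed = 20220902L, n_replicates = 3L) {
  scenario(
    name = "stress",
    arms = list(
      scenario_arm("control",
                   perturbation_model(0.002, 0.008,
                                      intensity_jitter_cv = 0.05),
                   n_replicates),
      scenario_arm("ph10",
                   perturbation_model(0.009, 0.0359,
                                      intensity_jitter_cv = 0.05),
                   n_replicates),
      scenario_arm("h2o2",
                   perturbation_model(0.0135, 0.0538, p_disappear = 0.12,
                                      intensity_jitter_cv = 0.10),
                   n_replicates)),
    noise_sd = 0.005, grid = c(256L, 128L), n_peaks = 110L, seed = seed)
}
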