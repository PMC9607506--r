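# hosnmr

Comparability analysis of the higher-order structure (HOS) of protein
therapeutics from 2D ¹H-¹³C methyl NMR fingerprints.

Monoclonal antibodies and other biologics are routinely fingerprinted by
2D methyl-region NMR (e.g. ¹H-¹³C HMQC at natural abundance): every
resolved methyl cross-peak reports on its local structural environment,
so batch-to-batch, stability and forced-degradation comparisons reduce
to statistics on these fingerprints. `hosnmr` implements the two
complementary analysis routes used in that workflow, plus a synthetic
spectrum generator with known ground truth so the whole pipeline can be
validated without instrument data.

## The statistics

**Peak level.** Corresponding cross-peaks of two spectra are matched (by
shared label, or by nearest neighbor within tolerances) and each pair is
scored by the combined chemical shift difference

    CCSD = 1000 · sqrt( ½ [ Δδ_H² + (0.251 · Δδ_C)² ] )   (ppb)

with shifts in ppm; the 0.251 factor rescales the ¹³C dispersion to the
¹H scale. A comparison is summarized by the average CCSD over matched
spin systems with the normal-approximation error `1.96 · s / √n` (`s` =
sample standard deviation of the per-peak CCSDs), by the pairwise
average-CCSD matrix across batches or time points, and by the set of
*disappeared* spin systems — reference peaks with no counterpart within
tolerance, the signature of strong local perturbation or line broadening
(e.g. after oxidative stress).

**Spectrum level (chemometrics).** Gridded spectra are bucketed over the
methyl region −1.0…2.8 ppm (¹H) × 8.0…26.0 ppm (¹³C) in 0.01 × 0.1 ppm
bins (380 × 180 = 68,400 buckets), total-area normalized, and compared
by unsupervised PCA (mean-centered, no variance scaling) and by
Euclidean distances between bin vectors.

## Worked example

Simulate a 110-peak reference fingerprint, apply an oxidative-stress-like
perturbation (large shifts, 12 % of spin systems lost), and compare:

```r
library(hosnmr)

ref <- generate_reference_peaklist(110, seed = 7)
stressed <- perturb_peaklist(ref, perturbation_model(
  shift_sd_h = 0.0135, shift_sd_c = 0.0538,
  p_disappear = 0.12, seed = 42))
profile <- ccsd_profile(match_peaks(ref, stressed$peaks))
profile
#> CCSD profile: 'perturbed' vs reference 'reference'
#>   average CCSD = 11.55 +/- 1.34 ppb (n = 98)
#>   disappeared spin systems: 12 (ss010, ss022, ss024, ss025, ss032)

ccsd_matrix(list(reference = ref, stressed = stressed$peaks))
#> Average CCSD matrix (ppb):
#>           reference stressed
#> reference      0.00    11.55
#> stressed      11.55     0.00
```

The average CCSD of ~12 ppb with a dozen lost spin systems is the
profile of a strongly perturbed sample; an unstressed replicate of the
same material scores a few ppb with nothing lost, and any list compared
against itself scores exactly 0.00 ppb (the matrix diagonal).

End-to-end runs are driven by a YAML configuration:

```r
cfg <- system.file("extdata", "stress_demo.yaml", package = "hosnmr")
res <- run_pipeline(cfg, out_dir = "stress_out")
```

which writes CCSD profiles and summary, the average-CCSD matrix, PCA
scores, Euclidean distance tables and the disappeared-peak report, plus
a run log. `plot_ccsd_profile()`, `plot_pca_scores()` and
`plot_distance_bars()` render the standard figures. A thin CLI wrapper
for shell use ships in `inst/cli/hosnmr.R`.

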