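---
title: "Methyl NMR comparability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methyl NMR comparability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hosnmr)
```

## The problem

The higher-order structure of a protein therapeutic is a critical
quality attribute, and 2D ¹H-¹³C methyl NMR is one of the few assays
that probes it residue-by-residue at natural abundance: each resolved
methyl cross-peak's position (δ_H, δ_C) fingerprints its local
environment. Comparability questions — are two production batches
structurally equivalent? is the molecule stable over storage? how does
the fingerprint respond to forced degradation? — then become statistics
on peak lists and on the binned spectra themselves. This package
implements both statistical routes and a simulator that generates
fingerprints with known ground truth.

## Peak-level model

### The CCSD statistic

For a matched pair of cross-peaks the combined chemical shift
difference is

$$\mathrm{CCSD} = 1000\sqrt{\tfrac12\left[\Delta\delta_H^2 +
(0.251\,\Delta\delta_C)^2\right]}\quad\text{(ppb)},$$

with shifts in ppm and `scaling_c = 0.251` rescaling the ¹³C dispersion
onto the ¹H scale — the standard weighted chemical-shift-perturbation
form. The square root is essential: without it the statistic is a
quadratic form whose values would be far below the ppb scale on which
methyl comparability results are reported (a pure 10-ppb ¹H displacement
gives CCSD = 7.07 ppb; squared it would be ~5·10⁻⁵). The function is
non-negative, symmetric under joint sign flips and absolutely
homogeneous; all outputs are in ppb (1 ppm = 1000 ppb), all inputs in
ppm.

### Averages and confidence intervals

A comparison is summarized by the arithmetic mean of the per-spin-system
CCSDs with halfwidth $z\,s/\sqrt n$, where $s$ is the sample standard
deviation (denominator $n-1$) and $z = 1.96$ by default. Two readings of
$n$ are defensible: the number of per-peak CCSD values entering the mean
(the statistically natural choice, the package default `ci_n =
"peaks"`), or the number of compared spectra. The default follows the
data actually being averaged — roughly 110 per-peak values — and the
switch `ci_n = "spectra"` preserves the alternative reading. With one
matched pair the CI is undefined and reported as `NA` with a warning;
with zero pairs the profile errors rather than fabricating a value.

### Matching

The reference workflow picks one curated peak list and reuses it for all
spectra, so the default pairing is by identical label, with the
tolerances applied afterwards only to *flag* out-of-tolerance pairs
(they stay in the average — dropping them would censor exactly the
most-perturbed spin systems). For unlabeled inputs a greedy one-to-one
nearest-neighbor matcher in the scaled metric
$d = \sqrt{\Delta\delta_H^2 + (0.251\Delta\delta_C)^2}$ accepts pairs
within `tol_h` and `tol_c`, breaking ties by smaller distance then
lexicographically smaller reference label, so matching is fully
deterministic. Default tolerances are `tol_h = 0.02` ppm and `tol_c =
0.2` ppm — about two bucket widths in each dimension, and equal to the
simulator's minimum-separation constraint, so matching ground truth is
unambiguous.

A *disappeared* spin system is a reference peak left unmatched within
tolerance. An intensity-based criterion (matched but attenuated below a
fraction of the reference intensity) is a plausible alternative but is
off by default, since no established threshold exists; disappearance by
absence is the conservative reading.

## Spectrum-level (chemometric) model

Spectra are bucketed over the methyl analysis region −1.0…2.8 ppm (¹H) ×
8.0…26.0 ppm (¹³C) into 0.01 × 0.1 ppm cells — 380 × 180 = 68,400 bins.
Cells are half-open $[lo, hi)$ with the uppermost cells closed, anchored
at the region bounds, so every in-region grid point is assigned to
exactly one bin and boundary points are handled deterministically. The
default bin integral is the plain sum of grid-point intensities: it is
exactly conservative (the bin totals equal the in-region grid sum) and
any quadrature constant cancels under total-area normalization. For
sensitivity analyses `area_weighted = TRUE` instead integrates the
bilinear interpolant of the grid exactly over each bin rectangle, which
converges quadratically under grid refinement. Negative intensities
(noise) are kept, not clipped: clipping would bias the total-area
normalization upward in noise-only regions.

Normalization divides by the grand total (sum of output = 1,
idempotent; a non-positive total is an error, not a silent pass-through).
PCA is computed on the mean-centered bin table by singular value
decomposition with **no** variance scaling — bucket tables are on a
common intensity scale and unit-variance scaling would inflate
noise-only bins. Component signs are fixed (largest-magnitude loading
element positive) so score plots are reproducible. Euclidean distances
are computed on the full normalized bin vectors with no feature
filtering. PCA is recomputed per input set (re-centering each time),
which covers both joint and per-field analyses.

## The synthetic-data generator

The generator emulates the study designs this analysis serves:

* **Reference fingerprint**: `n_peaks = 110` methyl cross-peaks (the
  typical count for an IgG methyl region at 700 MHz), placed by
  rejection sampling in a sub-box (¹H −0.5…1.5 ppm, ¹³C 10…25 ppm)
  chosen strictly inside the analysis region so rendered wings never
  clip at the region edges. A minimum separation (0.02 ppm ¹H *and/or*
  0.2 ppm ¹³C: two peaks may sit close in one dimension if they are
  resolved in the other) emulates a manually curated, unambiguous list;
  packing failure is signalled explicitly. Intensities are log-normal
  (median 1, `sdlog = 0.5`), a realistic right-skewed spread of methyl
  peak volumes.
* **Perturbations**: per-peak random displacements (Gaussian, or fixed
  magnitude with random sign — the latter makes every pair's CCSD equal,
  a closed-form ground truth), independent disappearance with
  probability `p_disappear`, and multiplicative log-normal intensity
  jitter with unit mean and a chosen CV.
* **Study structure**: each arm's model is applied **once** — it is the
  systematic structural effect of that batch, time point or treatment —
  and a small replicate-level model (defaults 0.0005 ppm ¹H, 0.002 ppm
  ¹³C, 2 % intensity CV, no drops) is then applied independently per
  replicate. This separation is what makes replicates cluster and arms
  separate in PCA, as real treated-vs-untreated spectra do; drawing each
  replicate's perturbation independently would scatter same-arm
  replicates as far from each other as from the controls.
* **Rendering**: separable Gaussian/Lorentzian/pseudo-Voigt lineshapes
  (defaults 0.02 ppm ¹H and 0.2 ppm ¹³C FWHM, typical processed methyl
  linewidths for a large protein) summed on a rectangular ppm grid, plus
  i.i.d. additive Gaussian noise. Real processed spectra have
  apodization-correlated noise and t₁-noise ridges; those are not
  modeled, so passing chemometric tests demonstrates correctness of the
  statistics, not robustness to every instrumental artifact. No
  time-domain synthesis (FIDs, apodization, linear prediction) is
  attempted.

Determinism: one master seed expands into per-stage child seeds by a
documented rule (seed a Mersenne-Twister stream with the master seed and
draw the children in a fixed order: reference list, then one per arm,
then two per replicate), so identical configurations reproduce
bit-identical peak lists and any arm can be regenerated independently.

### Stress-arm calibration

For pure-¹H Gaussian displacements of scale $\sigma_H$ the expected
per-peak CCSD is $1000\,\sigma_H\sqrt{1/\pi}$ (folded normal); when the
scaled ¹³C scale matches ($0.251\,\sigma_C = \sigma_H$) it is
$1000\,\sigma_H\sqrt{\pi}/2 \approx 886\,\sigma_H$. The bundled
forced-degradation scenario uses this closed form to place its arms at
the magnitudes reported for oxidative and base stress of an IgG:
oxidative-like $\sigma_H = 0.0135$ ppm with 12 % disappearance (~12
ppb), base-stress-like $\sigma_H = 0.009$ ppm without drops (~8 ppb),
and controls at $\sigma_H = 0.002$ ppm (~2 ppb, the batch/stability
scale). These defaults were fixed from the closed form once; the
acceptance checks on the scenario assert orderings and cluster
separation, not the exact averages, because per-peak shift distributions
of real degraded antibodies are not published.

## File formats

Peak lists: a self-describing TSV (`label delta_h_ppm delta_c_ppm
intensity`, header line, ≥ 17 significant digits on write) and a
Sparky-style `.list` (assignment token used only as the label, shifts
positional). Grids: CSV-with-header (first row the ¹H axis, first column
the ¹³C axis) and a JSON container with `axis_h`, `axis_c`,
`intensities`, `metadata` datasets. Axes may be stored descending (NMR
convention); computation normalizes to ascending and records the
original orientation. Round-trips are exact for peak lists and ≤ 1e-12
relative for grids.

## Numerical choices and degenerate inputs

* Bin commensurability: region widths must be integer multiples of the
  bin widths within 1e-9 — the standard region is exactly commensurate.
* `ccsd_matrix` forces a zero diagonal, computes both triangles, and
  warns if label-based asymmetry exceeds 1e-9 ppb; a pair with no
  matches yields `NA` with a warning, never a silent 0.
* PCA on identical spectra returns zero scores and zero explained
  variance (rank-0 guard rather than division by zero).
* All-zero bins cannot be normalized; empty regions, packing failures,
  and out-of-region peaks (clip-with-warning or error, per flag) fail
  loudly.

## Problem sizes

The test suite and acceptance checks run at the scale the statistics
need, not larger: 110-peak lists throughout; 50 independent
perturbations for the folded-normal recovery (≈ 5,500 per-peak values);
400 draws for the binomial disappearance check; 256 × 128 rendering
grids for the nine-spectrum forced-degradation scenario and 512 × 512
for the bin-conservation check; refinement checks at 512 × 256 vs
1024 × 512. The full suite completes in well under a minute on one CPU.

## Known limitations

* Absolute Euclidean distances depend on the integration units of the
  binning software, so only *relative* distance comparisons are
  meaningful across implementations; no attempt is made to match any
  particular tool's absolute scale.
* Whether published average CCSDs include or exclude weak unassigned
  peaks varies; the package averages exactly the matched set.
* No peak picking from grids, no spectral alignment/warping before
  binning, no supervised chemometrics (PLS-DA), and no equivalence
  margins — the package quantifies differences; judging them is a
  product-specific decision.
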