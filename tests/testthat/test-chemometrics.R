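test_that("binning uses the fixed layout and conserves in-region intensity", {
  region <- spectral_region()
  s <- render_spectrum(generate_reference_peaklist(20, seed = 18),
                       region, grid = c(256L, 128L),
                       noise_sd = 0.01, seed = 3)
  b <- bin_spectrum(s, region)
  expect_length(b$values, 380L * 180L)
  inside <- s$intensities[in_region_idx(s$axis_c, region$c_min, region$c_max),
                          in_region_idx(s$axis_h, region$h_min, region$h_max)]
  expect_identical(sum(b$values), sum(inside))
  expect_false(b$normalized)
})

test_that("a single grid point lands in exactly the covering bin", {
  region <- spectral_region()
  # minimal grid holding one hot point at (1.005, 12.05)
  axis_h <- c(0.5, 1.005, 2.0)
  axis_c <- c(11.0, 12.05, 14.0)
  m <- matrix(0, 3, 3); m[2, 2] <- 3
  b <- bin_spectrum(spectrum2d(axis_h, axis_c, m), region)
  hit <- which(b$values != 0)
  expect_equal(b$values[hit[
    which(hit == expected_bin_index(region, 1.005, 12.05))]], 3)
  # all other nonzero bins come from the surrounding zero points summing to 0
  expect_equal(sum(b$values), 3)
  expect_true(expected_bin_index(region, 1.005, 12.05) %in% hit)
  # the covering cell is [1.00, 1.01) x [12.0, 12.1)
  idx <- expected_bin_index(region, 1.005, 12.05)
  expect_equal(idx, expected_bin_index(region, 1.0001, 12.0001))
})

test_that("upper region boundary points fold into the last bin", {
  region <- spectral_region()
  axis_h <- c(2.7, 2.75, 2.8)
  axis_c <- c(25.8, 25.9, 26.0)
  m <- matrix(1, 3, 3)
  b <- bin_spectrum(spectrum2d(axis_h, axis_c, m), region)
  expect_equal(sum(b$values), 9)
  expect_equal(b$values[expected_bin_index(region, 2.8, 26.0)],
               b$values[expected_bin_index(region, 2.7999, 25.9999)])
})

test_that("binning errors when no grid point is inside the region", {
  region <- spectral_region()
  s <- spectrum2d(c(5, 6), c(50, 60), matrix(1, 2, 2))
  expect_error(bin_spectrum(s, region), "no grid points inside")
})

test_that("area-weighted bin integrals are stable under grid refinement", {
  region <- spectral_region()
  pl <- generate_reference_peaklist(20, seed = 19)
  # lineshapes resolved by several bins, i.e. smooth at the bin scale
  ls <- lineshape_params(fwhm_h = 0.1, fwhm_c = 1.0)
  b1 <- bin_spectrum(render_spectrum(pl, region, grid = c(512L, 256L),
                                     lineshape = ls, noise_sd = 0), region,
                     area_weighted = TRUE)
  b2 <- bin_spectrum(render_spectrum(pl, region, grid = c(1024L, 512L),
                                     lineshape = ls, noise_sd = 0), region,
                     area_weighted = TRUE)
  keep <- b1$values > max(b1$values) * 1e-2  # bins carrying real signal
  rel <- abs(b2$values[keep] - b1$values[keep]) / b1$values[keep]
  expect_lt(max(rel), 0.02)
  # the weighted integral over the region matches the analytic peak
  # volume (all peaks well inside the region)
  analytic <- sum(pl$intensity) * 0.1 * 1.0 * pi / (4 * log(2))
  expect_equal(sum(b1$values), analytic, tolerance = 1e-4)
})

test_that("total-area normalization sums to one, is idempotent and errors on degenerate input", {
  region <- spectral_region(0, 1, 10, 11, 0.5, 0.5)
  mk <- function(v) structure(list(spectrum_id = "x", region = region,
                                   values = v, normalized = FALSE),
                              class = "binned_spectrum")
  n <- normalize_total_area(mk(c(1, 1, 1, 1)))
  expect_equal(n$values, rep(0.25, 4))
  expect_true(n$normalized)
  r <- normalize_total_area(mk(runif(4)))
  expect_equal(sum(r$values), 1, tolerance = 1e-12)
  expect_equal(normalize_total_area(r)$values, r$values)  # idempotent
  expect_error(normalize_total_area(mk(rep(0, 4))), "non-positive total")
})

test_that("normalized bins are invariant to a global intensity rescaling", {
  region <- spectral_region()
  pl <- generate_reference_peaklist(20, seed = 20)
  pl2 <- peaklist(pl$label, pl$delta_h, pl$delta_c, pl$intensity * 2,
                  spectrum_id = "x2")
  b1 <- normalize_total_area(bin_spectrum(
    render_spectrum(pl, region, grid = c(128L, 64L), noise_sd = 0), region))
  b2 <- normalize_total_area(bin_spectrum(
    render_spectrum(pl2, region, grid = c(128L, 64L), noise_sd = 0), region))
  expect_lt(max(abs(b1$values - b2$values)), 1e-9)
  expect_lt(euclidean_distance(b1, b2), 1e-9)
})

test_that("PCA satisfies the projection identity, centering invariance and sign convention", {
  region <- spectral_region(0, 1, 10, 12, 0.1, 0.5)
  set.seed(31)
  mk <- function(v, id) structure(list(spectrum_id = id, region = region,
                                       values = v / sum(v),
                                       normalized = TRUE),
                                  class = "binned_spectrum")
  nb <- region$n_bins_h * region$n_bins_c
  binned <- lapply(1:6, function(i) mk(runif(nb) + 0.1, paste0("s", i)))
  names(binned) <- paste0("s", 1:6)
  p <- spectra_pca(binned, n_components = 3L)
  # loadings orthonormal
  g <- t(p$loadings) %*% p$loadings
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  # explained variance non-increasing, sums <= 1
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
  # scores reproduce centered data projected on loadings
  x <- do.call(rbind, lapply(binned, `[[`, "values"))
  xc <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(xc %*% p$loadings - p$scores)), 1e-8)
  # sign convention: max-magnitude loading element positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # adding a constant to one bin across all spectra leaves scores unchanged
  shifted <- lapply(binned, function(b) { b$values[7] <- b$values[7] + 5; b })
  p2 <- spectra_pca(shifted, n_components = 3L)
  expect_equal(p2$scores, p$scores, tolerance = 1e-8)
  # permuting sample order permutes score rows identically
  perm <- c(4, 2, 6, 1, 3, 5)
  p3 <- spectra_pca(binned[perm], n_components = 3L)
  expect_equal(unname(p3$scores), unname(p$scores[perm, ]), tolerance = 1e-8)
})

test_that("identical spectra give zero scores and explained variance", {
  region <- spectral_region(0, 1, 10, 12, 0.1, 0.5)
  v <- runif(region$n_bins_h * region$n_bins_c) + 0.5
  mk <- function(id) structure(list(spectrum_id = id, region = region,
                                    values = v / sum(v), normalized = TRUE),
                               class = "binned_spectrum")
  p <- spectra_pca(list(a = mk("a"), b = mk("b"), c = mk("c")))
  expect_lt(max(abs(p$scores)), 1e-10)
  expect_equal(sum(p$explained_variance_ratio), 0)
})

test_that("PC1 separates two well-separated simulated groups", {
  sc <- scenario(
    name = "two-group",
    arms = list(
      scenario_arm("untreated", perturbation_model(0.001, 0.004), 4L),
      scenario_arm("treated", perturbation_model(0.015, 0.06, seed = 1), 4L)),
    noise_sd = 0.005, grid = c(128L, 64L), n_peaks = 60L, seed = 77L)
  bundle <- simulate_study(sc)
  binned <- lapply(bundle$spectra, function(s)
    normalize_total_area(bin_spectrum(s, sc$region)))
  p <- spectra_pca(binned)
  grp <- sub("_r\\d+$", "", p$ids)
  s1 <- p$scores[grp == "untreated", 1]
  s2 <- p$scores[grp == "treated", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("euclidean distance matches the brute-force definition and the metric axioms", {
  region <- spectral_region(0, 1, 10, 12, 0.1, 0.5)
  nb <- region$n_bins_h * region$n_bins_c
  mk <- function(v, id) structure(list(spectrum_id = id, region = region,
                                       values = v / sum(v),
                                       normalized = TRUE),
                                  class = "binned_spectrum")
  # toy: (1,0) vs (0,1) -> sqrt(2), via a 2-bin layout
  r2 <- spectral_region(0, 1, 10, 11, 0.5, 1)
  a <- structure(list(spectrum_id = "a", region = r2, values = c(1, 0),
                      normalized = TRUE), class = "binned_spectrum")
  b <- structure(list(spectrum_id = "b", region = r2, values = c(0, 1),
                      normalized = TRUE), class = "binned_spectrum")
  expect_equal(euclidean_distance(a, b), sqrt(2))
  expect_equal(euclidean_distance(a, a), 0)
  set.seed(41)
  binned <- lapply(1:10, function(i) mk(runif(nb) + 0.05, paste0("s", i)))
  names(binned) <- paste0("s", 1:10)
  # brute-force loop equals vectorized result
  brute <- function(u, v) { s <- 0
    for (k in seq_along(u)) s <- s + (u[k] - v[k])^2
    sqrt(s) }
  d <- distance_matrix(binned)
  for (i in 1:10) for (j in 1:10)
    expect_equal(unname(d$values[i, j]),
                 brute(binned[[i]]$values, binned[[j]]$values),
                 tolerance = 1e-12)
  # metric axioms: symmetry, zero diagonal, triangle inequality
  expect_equal(d$values, t(d$values))
  expect_equal(unname(diag(d$values)), rep(0, 10))
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(d$values[i, j], d$values[i, k] + d$values[k, j] + 1e-12)
})

test_that("distance and PCA refuse unnormalized or mismatched inputs", {
  region <- spectral_region(0, 1, 10, 12, 0.1, 0.5)
  raw <- structure(list(spectrum_id = "raw", region = region,
                        values = rep(1, region$n_bins_h * region$n_bins_c),
                        normalized = FALSE), class = "binned_spectrum")
  expect_error(euclidean_distance(raw, raw), "normalized")
  other <- structure(list(spectrum_id = "o",
                          region = spectral_region(0, 1, 10, 12, 0.5, 0.5),
                          values = rep(1, 8), normalized = TRUE),
                     class = "binned_spectrum")
  norm <- normalize_total_area(raw)
  expect_error(euclidean_distance(norm, other), "region layout")
})
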