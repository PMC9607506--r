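#' Bin a 2D spectrum on a fixed chemical-shift grid
#'
#' Segments the spectrum over the analysis region into rectangular
#' buckets (`region$bin_h` x `region$bin_c` ppm) and integrates each
#' bucket as the plain sum of the grid-point intensities falling in its
#' half-open cell `[lo, hi)`; cells on the upper region boundary are
#' closed so every in-region point is assigned exactly once. Grid points
#' outside the region are ignored. The bin vector is row-major with
#' \eqn{^{13}}C the major axis and \eqn{^1}H the minor axis. The sum of
#' the unnormalized bins equals the sum of in-region grid intensities
#' exactly.
#'
#' With `area_weighted = TRUE` bin values are exact integrals of the
#' bilinear interpolant of the grid over each bin rectangle (computed
#' via per-axis integrals of the linear hat basis), so bin integrals
#' converge quadratically under grid refinement.
#'
#' @param s a [spectrum2d()].
#' @param region a [spectral_region()].
#' @param area_weighted weight points by grid cell area (default off;
#'   plain sums are exactly conservative and sufficient under total-area
#'   normalization).
#' @return A list of class `binned_spectrum`: `spectrum_id`, `region`,
#'   `values` (length `n_bins_h * n_bins_c`), `normalized = FALSE`.
#' @export
bin_spectrum <- function(s, region = spectral_region(),
                         area_weighted = FALSE) {
  stopifnot(is_spectrum2d(s), inherits(region, "spectral_region"))
  h <- s$axis_h; c_ <- s$axis_c
  hin <- h >= region$h_min & h <= region$h_max
  cin <- c_ >= region$c_min & c_ <= region$c_max
  if (!any(hin) || !any(cin))
    stop("bin_spectrum: no grid points inside the region")
  mat <- s$intensities[cin, hin, drop = FALSE]
  nbh <- region$n_bins_h; nbc <- region$n_bins_c
  values <- numeric(nbh * nbc)
  if (!area_weighted) {
    # half-open cell index, upper boundary folded into the last bin
    idx <- function(x, lo, w, nb) pmin(floor((x - lo) / w) + 1L, nb)
    bh <- idx(h[hin], region$h_min, region$bin_h, nbh)
    bc <- idx(c_[cin], region$c_min, region$bin_c, nbc)
    flat_bin <- (rep(bc, times = length(bh)) - 1L) * nbh +
      rep(bh, each = length(bc))
    acc <- tapply(as.vector(mat), flat_bin, sum)
    values[as.integer(names(acc))] <- as.numeric(acc)
  } else {
    # W[i, b] = integral over bin b of the linear hat basis function at
    # grid point i; t(Wc) I Wh then integrates the bilinear interpolant
    # of the grid exactly over every bin rectangle
    hat_weights <- function(x, lo, w, nb) {
      n <- length(x)
      a <- matrix(0, n, nb)
      # integral of a linear ramp over [u0, u1]: rising 0 -> 1 on
      # [x0, x1], or falling 1 -> 0
      ramp <- function(u0, u1, x0, x1, rising) {
        if (u1 <= u0 || x1 <= x0) return(0)
        if (rising) ((u1 - x0)^2 - (u0 - x0)^2) / (2 * (x1 - x0))
        else ((x1 - u0)^2 - (x1 - u1)^2) / (2 * (x1 - x0))
      }
      for (i in seq_len(n)) {
        xm <- if (i > 1L) x[i - 1L] else x[i]
        xp <- if (i < n) x[i + 1L] else x[i]
        b0 <- max(1L, min(nb, floor((xm - lo) / w) + 1L))
        b1 <- max(1L, min(nb, floor((xp - lo) / w * (1 - 1e-15)) + 1L))
        for (b in b0:b1) {
          blo <- lo + (b - 1L) * w; bhi <- lo + b * w
          v <- 0
          if (i > 1L)
            v <- v + ramp(max(blo, xm), min(bhi, x[i]), xm, x[i], TRUE)
          if (i < n)
            v <- v + ramp(max(blo, x[i]), min(bhi, xp), x[i], xp, FALSE)
          a[i, b] <- v
        }
      }
      a
    }
    wc <- hat_weights(c_[cin], region$c_min, region$bin_c, nbc)
    wh <- hat_weights(h[hin], region$h_min, region$bin_h, nbh)
    binned <- t(wc) %*% mat %*% wh        # n_bins_c x n_bins_h
    values <- as.vector(t(binned))        # 13C major, 1H minor
  }
  structure(list(spectrum_id = if (!is.null(s$metadata$spectrum_id))
                   s$metadata$spectrum_id else "unnamed",
                 region = region, values = values, normalized = FALSE),
            class = "binned_spectrum")
}

#' Total-area normalization of a binned spectrum
#'
#' Divides every bin by the grand total so the normalized profile sums
#' to 1, making spectra comparable across concentrations and receiver
#' gains. Idempotent. Fails on a non-positive total (degenerate or empty
#' spectrum).
#'
#' @param b a [bin_spectrum()] result.
#' @return The normalized `binned_spectrum` (`normalized = TRUE`).
#' @export
normalize_total_area <- function(b) {
  stopifnot(inherits(b, "binned_spectrum"))
  total <- sum(b$values)
  if (!is.finite(total) || total <= 0)
    stop("normalize_total_area: non-positive total area (", total,
         "); cannot normalize a degenerate spectrum")
  b$values <- b$values / total
  b$normalized <- TRUE
  b
}

# internal: stack binned spectra into a samples x bins matrix after
# checking shared region layout and normalization
binned_matrix <- function(binned, require_normalized = TRUE) {
  stopifnot(length(binned) >= 1L,
            all(vapply(binned, inherits, logical(1), "binned_spectrum")))
  r0 <- binned[[1L]]$region
  same <- vapply(binned, function(b) {
    r <- b$region
    isTRUE(all.equal(unclass(r)[c("h_min", "h_max", "c_min", "c_max",
                                  "bin_h", "bin_c")],
                     unclass(r0)[c("h_min", "h_max", "c_min", "c_max",
                                   "bin_h", "bin_c")]))
  }, logical(1))
  if (!all(same))
    stop("all binned spectra must share the same region layout")
  if (require_normalized && !all(vapply(binned, `[[`, logical(1), "normalized")))
    stop("all binned spectra must be total-area normalized first")
  ids <- names(binned)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(binned, `[[`, character(1), "spectrum_id")
  x <- do.call(rbind, lapply(binned, `[[`, "values"))
  rownames(x) <- ids
  x
}

#' Principal component analysis of binned spectra
#'
#' Unsupervised PCA of the bin table (samples x bins): columns are
#' mean-centered, no variance scaling (conventional for spectral bucket
#' tables), decomposition by singular values. Component signs are fixed
#' so each loading vector's maximal-magnitude element is positive, making
#' score plots reproducible.
#'
#' @param binned list of normalized [bin_spectrum()] results sharing one
#'   region layout (>= 2).
#' @param n_components number of components to keep (capped at the
#'   matrix rank).
#' @return A list of class `pca_result`: `ids`, `scores` (samples x
#'   components), `loadings` (bins x components, orthonormal columns),
#'   `explained_variance_ratio`.
#' @export
spectra_pca <- function(binned, n_components = 2L) {
  if (length(binned) < 2L) stop("spectra_pca: need at least 2 spectra")
  x <- binned_matrix(binned)
  centers <- colMeans(x)
  xc <- sweep(x, 2L, centers)
  sv <- svd(xc)
  total_var <- sum(sv$d^2)
  k <- min(as.integer(n_components), sum(sv$d > max(sv$d[1], 1) * 1e-12),
           nrow(x) - 1L)
  k <- max(k, 1L)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: largest-magnitude loading element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- if (total_var > 0) sv$d[seq_len(k)]^2 / total_var else rep(0, k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(ids = rownames(x), scores = scores, loadings = loadings,
                 explained_variance_ratio = evr, centers = centers),
            class = "pca_result")
}

#' Euclidean distance between two binned spectra
#'
#' \eqn{\sqrt{\sum_i (a_i - b_i)^2}} over the full normalized bin
#' vectors. Both spectra must share the region layout and be total-area
#' normalized (distances are computed after normalization).
#'
#' @param a,b normalized [bin_spectrum()] results.
#' @return A non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  x <- binned_matrix(list(a, b))
  sqrt(sum((x[1L, ] - x[2L, ])^2))
}

#' Pairwise Euclidean distance matrix of binned spectra
#'
#' All pairwise distances between normalized bin vectors, the input to
#' the bar-plot comparisons (time point vs. T0 per batch, batch vs.
#' batch, treated vs. reference). Symmetric with zero diagonal; the
#' triangle inequality holds as for any Euclidean embedding.
#'
#' @param binned list of >= 2 normalized [bin_spectrum()] results.
#' @return A list of class `distance_matrix`: `ids` and `values`.
#' @export
distance_matrix <- function(binned) {
  if (length(binned) < 2L) stop("distance_matrix: need at least 2 spectra")
  x <- binned_matrix(binned)
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(rownames(x), rownames(x))
  structure(list(ids = rownames(x), values = d), class = "distance_matrix")
}

#' Grouped distance summary for comparison bar plots
#'
#' Summarizes a [distance_matrix()] against one reference spectrum:
#' the distance of every other spectrum to the reference, ordered as
#' given — the layout of the distance bar plots.
#'
#' @param dm a [distance_matrix()].
#' @param reference_id id of the reference spectrum.
#' @return data.frame with `id` and `distance_to_reference`.
#' @export
distances_to_reference <- function(dm, reference_id) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (!reference_id %in% dm$ids)
    stop("distances_to_reference: unknown reference id '", reference_id, "'")
  others <- setdiff(dm$ids, reference_id)
  data.frame(id = others,
             distance_to_reference = dm$values[others, reference_id],
             row.names = NULL, stringsAsFactors = FALSE)
}
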