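#' Construct a gridded 2D spectrum
#'
#' A frequency-domain 2D spectrum on a rectangular ppm grid: a
#' \eqn{^1}H axis, a \eqn{^{13}}C axis, and an intensity matrix with one
#' row per \eqn{^{13}}C grid point and one column per \eqn{^1}H grid
#' point. Axes must be strictly monotone; NMR convention often stores ppm
#' axes descending, so both orientations are accepted and normalized to
#' ascending order internally, with the original orientation recorded in
#' `metadata$orientation_h` / `metadata$orientation_c`.
#'
#' @param axis_h numeric \eqn{^1}H ppm vector, strictly monotone.
#' @param axis_c numeric \eqn{^{13}}C ppm vector, strictly monotone.
#' @param intensities numeric matrix, `length(axis_c)` rows x
#'   `length(axis_h)` columns.
#' @param metadata named list of free-form metadata.
#' @return An object of class `spectrum2d`.
#' @export
spectrum2d <- function(axis_h, axis_c, intensities, metadata = list()) {
  axis_h <- as.numeric(axis_h)
  axis_c <- as.numeric(axis_c)
  if (length(axis_h) < 2L || length(axis_c) < 2L)
    stop("spectrum2d: each axis needs at least 2 points")
  if (!all(is.finite(axis_h)) || !all(is.finite(axis_c)))
    stop("spectrum2d: axes must be finite")
  dh <- diff(axis_h); dc <- diff(axis_c)
  if (!(all(dh > 0) || all(dh < 0)))
    stop("spectrum2d: axis_h must be strictly monotone")
  if (!(all(dc > 0) || all(dc < 0)))
    stop("spectrum2d: axis_c must be strictly monotone")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(axis_c) || ncol(intensities) != length(axis_h))
    stop(sprintf(
      "spectrum2d: intensity matrix is %d x %d but axes imply %d x %d",
      nrow(intensities), ncol(intensities), length(axis_c), length(axis_h)))
  storage.mode(intensities) <- "double"
  metadata$orientation_h <- if (all(dh > 0)) "ascending" else "descending"
  metadata$orientation_c <- if (all(dc > 0)) "ascending" else "descending"
  if (metadata$orientation_h == "descending") {
    axis_h <- rev(axis_h)
    intensities <- intensities[, rev(seq_along(axis_h)), drop = FALSE]
  }
  if (metadata$orientation_c == "descending") {
    axis_c <- rev(axis_c)
    intensities <- intensities[rev(seq_along(axis_c)), , drop = FALSE]
  }
  structure(list(axis_h = axis_h, axis_c = axis_c,
                 intensities = intensities, metadata = metadata),
            class = "spectrum2d")
}

#' Test for a 2D spectrum
#' @param x object to test.
#' @return `TRUE` for objects created by [spectrum2d()].
#' @export
is_spectrum2d <- function(x) inherits(x, "spectrum2d")

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("2D spectrum: %d (13C) x %d (1H) grid\n",
              length(x$axis_c), length(x$axis_h)))
  cat(sprintf("  1H axis: [%.3f, %.3f] ppm; 13C axis: [%.3f, %.3f] ppm\n",
              min(x$axis_h), max(x$axis_h), min(x$axis_c), max(x$axis_c)))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}
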