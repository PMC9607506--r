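#' Define a rectangular spectral region with a bin grid
#'
#' A spectral region is the rectangle of chemical-shift space over which
#' spectra are binned and compared, together with the bin widths of the
#' bucketing grid. The default is the methyl fingerprint region used for
#' 2D \eqn{^1}H-\eqn{^{13}}C comparability work: \eqn{-1.0} to 2.8 ppm in
#' the \eqn{^1}H dimension and 8.0 to 26.0 ppm in \eqn{^{13}}C, segmented
#' into 0.01 ppm and 0.1 ppm bins respectively (380 x 180 = 68,400 bins).
#'
#' Bin widths must tile the region exactly: `(h_max - h_min) / bin_h` and
#' `(c_max - c_min) / bin_c` must be integers (within 1e-9).
#'
#' @param h_min,h_max \eqn{^1}H bounds in ppm (`h_min < h_max`).
#' @param c_min,c_max \eqn{^{13}}C bounds in ppm (`c_min < c_max`).
#' @param bin_h,bin_c bin widths in ppm, > 0.
#' @return An object of class `spectral_region`: a list with the six
#'   fields plus derived bin counts `n_bins_h`, `n_bins_c`.
#' @examples
#' r <- spectral_region()
#' r$n_bins_h * r$n_bins_c  # 68400
#' @export
spectral_region <- function(h_min = -1.0, h_max = 2.8,
                            c_min = 8.0, c_max = 26.0,
                            bin_h = 0.01, bin_c = 0.1) {
  stopifnot(is.numeric(h_min), is.numeric(h_max),
            is.numeric(c_min), is.numeric(c_max),
            is.numeric(bin_h), is.numeric(bin_c))
  if (!(h_min < h_max)) stop("spectral_region: h_min must be < h_max")
  if (!(c_min < c_max)) stop("spectral_region: c_min must be < c_max")
  if (bin_h <= 0 || bin_c <= 0) stop("spectral_region: bin widths must be > 0")
  nh <- (h_max - h_min) / bin_h
  nc <- (c_max - c_min) / bin_c
  if (abs(nh - round(nh)) > 1e-9 * max(1, abs(nh)))
    stop("spectral_region: bin_h does not tile [h_min, h_max] into an integer number of bins")
  if (abs(nc - round(nc)) > 1e-9 * max(1, abs(nc)))
    stop("spectral_region: bin_c does not tile [c_min, c_max] into an integer number of bins")
  structure(
    list(h_min = h_min, h_max = h_max, c_min = c_min, c_max = c_max,
         bin_h = bin_h, bin_c = bin_c,
         n_bins_h = as.integer(round(nh)), n_bins_c = as.integer(round(nc))),
    class = "spectral_region"
  )
}

#' @export
print.spectral_region <- function(x, ...) {
  cat(sprintf("Spectral region: 1H [%g, %g] ppm x 13C [%g, %g] ppm\n",
              x$h_min, x$h_max, x$c_min, x$c_max))
  cat(sprintf("Bins: %d x %d = %d (widths %g / %g ppm)\n",
              x$n_bins_h, x$n_bins_c, x$n_bins_h * x$n_bins_c,
              x$bin_h, x$bin_c))
  invisible(x)
}

# internal: TRUE where (h, c) lies inside the region (closed rectangle)
in_region <- function(region, h, c) {
  h >= region$h_min & h <= region$h_max &
    c >= region$c_min & c <= region$c_max
}
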