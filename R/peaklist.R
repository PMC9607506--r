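#' Construct a 2D peak list
#'
#' A peak list is the unit of CCSD analysis: a set of labelled methyl
#' cross-peaks, each with a \eqn{^1}H and a \eqn{^{13}}C chemical shift in
#' ppm and an optional intensity. Labels identify spin systems and must be
#' unique within a list; matching across spectra is label-based when the
#' same manually defined peak list was used for all spectra.
#'
#' @param label character vector of spin-system identifiers (unique,
#'   non-empty).
#' @param delta_h numeric vector of \eqn{^1}H shifts in ppm (finite).
#' @param delta_c numeric vector of \eqn{^{13}}C shifts in ppm (finite).
#' @param intensity optional numeric vector of peak intensities (> 0);
#'   defaults to 1 for every peak.
#' @param spectrum_id identifier of the spectrum the list was picked from.
#' @param metadata named list of free-form metadata (batch, timepoint,
#'   field_mhz, treatment, ...).
#' @return A `peaklist`: a data.frame with columns `label`, `delta_h`,
#'   `delta_c`, `intensity` and attributes `spectrum_id`, `metadata`.
#' @export
peaklist <- function(label, delta_h, delta_c, intensity = NULL,
                     spectrum_id = "unnamed", metadata = list()) {
  label <- as.character(label)
  n <- length(label)
  if (n == 0L) stop("peaklist: at least one peak required")
  if (length(delta_h) != n || length(delta_c) != n)
    stop("peaklist: label, delta_h, delta_c must have equal length")
  if (any(!nzchar(label))) stop("peaklist: empty labels are not allowed")
  dup <- label[duplicated(label)]
  if (length(dup))
    stop("peaklist: duplicate label(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(delta_h)) || !all(is.finite(delta_c)))
    stop("peaklist: chemical shifts must be finite")
  if (is.null(intensity)) intensity <- rep(1, n)
  if (length(intensity) != n)
    stop("peaklist: intensity must have one value per peak")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("peaklist: intensities must be finite and > 0")
  df <- data.frame(label = label,
                   delta_h = as.numeric(delta_h),
                   delta_c = as.numeric(delta_c),
                   intensity = as.numeric(intensity),
                   stringsAsFactors = FALSE)
  structure(df, spectrum_id = as.character(spectrum_id),
            metadata = metadata,
            class = c("peaklist", "data.frame"))
}

#' Test for a peak list
#' @param x object to test.
#' @return `TRUE` for objects created by [peaklist()].
#' @export
is_peaklist <- function(x) inherits(x, "peaklist")

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Peak list '%s': %d cross-peaks\n",
              attr(x, "spectrum_id"), nrow(x)))
  cat(sprintf("  1H range: [%.3f, %.3f] ppm; 13C range: [%.3f, %.3f] ppm\n",
              min(x$delta_h), max(x$delta_h), min(x$delta_c), max(x$delta_c)))
  NextMethod()
}

#' Spectrum identifier of a peak list
#' @param pl a [peaklist()].
#' @return the `spectrum_id` attribute (character scalar).
#' @export
spectrum_id <- function(pl) {
  stopifnot(is_peaklist(pl))
  attr(pl, "spectrum_id")
}
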