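#' Combined chemical shift difference (CCSD)
#'
#' The scalar distance between corresponding cross-peaks of two 2D
#' \eqn{^1}H-\eqn{^{13}}C spectra:
#' \deqn{CCSD = 1000 \sqrt{\tfrac{1}{2}\left[\Delta\delta_H^2 +
#'   (0.251\,\Delta\delta_C)^2\right]} \;\; \mathrm{(ppb)}}
#' where the shifts are in ppm and the 0.251 factor rescales the
#' \eqn{^{13}}C dispersion onto the \eqn{^1}H scale. The result is
#' non-negative, symmetric in the sign of both inputs, and absolutely
#' homogeneous in (\eqn{\Delta\delta_H}, scaled \eqn{\Delta\delta_C}).
#'
#' @param ddh \eqn{\Delta\delta_H} in ppm (vectorized).
#' @param ddc \eqn{\Delta\delta_C} in ppm (vectorized).
#' @param scaling_c \eqn{^{13}}C scaling factor (default 0.251).
#' @return CCSD in ppb (1 ppm = 1000 ppb).
#' @examples
#' ccsd(0.010, 0)          # 7.0711 ppb
#' ccsd(0, 0.100)          # 17.7484 ppb
#' @export
ccsd <- function(ddh, ddc, scaling_c = 0.251) {
  if (any(!is.finite(ddh)) || any(!is.finite(ddc)))
    stop("ccsd: shift differences must be finite")
  1000 * sqrt(0.5 * (ddh^2 + (scaling_c * ddc)^2))
}

#' Match cross-peaks between two peak lists
#'
#' When `by_label = TRUE` (the default) and the label sets overlap, peaks
#' are paired by identical label — the workflow where one manually
#' defined peak list is reused for all spectra — and the tolerances are
#' applied afterwards only to flag out-of-tolerance pairs (they are kept,
#' not dropped). Otherwise pairing is greedy one-to-one nearest-neighbor
#' in the scaled metric \eqn{d = \sqrt{\Delta\delta_H^2 +
#' (0.251\,\Delta\delta_C)^2}}, accepting only candidate pairs with
#' \eqn{|\Delta\delta_H| \le} `tol_h` and \eqn{|\Delta\delta_C| \le}
#' `tol_c`; ties are broken by smaller distance, then lexicographically
#' smaller reference label.
#'
#' Reference peaks left unmatched are candidates for "disappeared" spin
#' systems.
#'
#' @param ref reference [peaklist()].
#' @param query query [peaklist()].
#' @param tol_h,tol_c matching tolerances in ppm (> 0); the defaults
#'   (0.02 / 0.2) are roughly two bin widths of the standard bucketing
#'   grid.
#' @param by_label pair by identical label when possible.
#' @param scaling_c \eqn{^{13}}C scaling in the matching metric.
#' @return A list of class `match_result`: `pairs` (data.frame with
#'   `ref_label`, `query_label`, `ddh`, `ddc`, `in_tolerance`),
#'   `unmatched_ref`, `unmatched_query` (character vectors), and the
#'   matching parameters.
#' @export
match_peaks <- function(ref, query, tol_h = 0.02, tol_c = 0.2,
                        by_label = TRUE, scaling_c = 0.251) {
  stopifnot(is_peaklist(ref), is_peaklist(query))
  if (nrow(ref) == 0L) stop("match_peaks: empty reference list")
  if (tol_h <= 0 || tol_c <= 0) stop("match_peaks: tolerances must be > 0")
  use_labels <- by_label && any(query$label %in% ref$label)
  if (use_labels) {
    common <- intersect(ref$label, query$label)
    ri <- match(common, ref$label)
    qi <- match(common, query$label)
    ddh <- query$delta_h[qi] - ref$delta_h[ri]
    ddc <- query$delta_c[qi] - ref$delta_c[ri]
    pairs <- data.frame(ref_label = common, query_label = common,
                        ddh = ddh, ddc = ddc,
                        in_tolerance = abs(ddh) <= tol_h & abs(ddc) <= tol_c,
                        stringsAsFactors = FALSE)
    unmatched_ref <- setdiff(ref$label, common)
    unmatched_query <- setdiff(query$label, common)
  } else {
    # all in-tolerance candidate pairs, sorted by scaled distance then
    # reference label; greedy one-to-one acceptance
    cand_r <- integer(0); cand_q <- integer(0); cand_d <- numeric(0)
    for (i in seq_len(nrow(ref))) {
      ok <- abs(query$delta_h - ref$delta_h[i]) <= tol_h &
            abs(query$delta_c - ref$delta_c[i]) <= tol_c
      if (any(ok)) {
        j <- which(ok)
        d <- sqrt((query$delta_h[j] - ref$delta_h[i])^2 +
                  (scaling_c * (query$delta_c[j] - ref$delta_c[i]))^2)
        cand_r <- c(cand_r, rep(i, length(j)))
        cand_q <- c(cand_q, j)
        cand_d <- c(cand_d, d)
      }
    }
    ord <- order(cand_d, ref$label[cand_r], query$label[cand_q])
    used_r <- rep(FALSE, nrow(ref)); used_q <- rep(FALSE, nrow(query))
    sel <- integer(0)
    for (k in ord) {
      if (!used_r[cand_r[k]] && !used_q[cand_q[k]]) {
        used_r[cand_r[k]] <- TRUE; used_q[cand_q[k]] <- TRUE
        sel <- c(sel, k)
      }
    }
    ri <- cand_r[sel]; qi <- cand_q[sel]
    o <- order(ref$label[ri])
    ri <- ri[o]; qi <- qi[o]
    pairs <- data.frame(ref_label = ref$label[ri],
                        query_label = query$label[qi],
                        ddh = query$delta_h[qi] - ref$delta_h[ri],
                        ddc = query$delta_c[qi] - ref$delta_c[ri],
                        in_tolerance = rep(TRUE, length(ri)),
                        stringsAsFactors = FALSE)
    unmatched_ref <- ref$label[!used_r]
    unmatched_query <- query$label[!used_q]
  }
  structure(list(pairs = pairs,
                 unmatched_ref = unmatched_ref,
                 unmatched_query = unmatched_query,
                 ref_id = spectrum_id(ref), query_id = spectrum_id(query),
                 tol_h = tol_h, tol_c = tol_c,
                 by_label = use_labels, scaling_c = scaling_c),
            class = "match_result")
}

#' CCSD profile of a matched spectrum pair
#'
#' Per-spin-system CCSDs for every matched pair, their average, and a
#' normal-approximation confidence halfwidth
#' \eqn{z \cdot s / \sqrt{n}} with \eqn{s} the sample standard deviation
#' (denominator \eqn{n - 1}) of the per-peak CCSD values. By default
#' \eqn{n} is the number of per-peak CCSD values entering the mean
#' (`ci_n = "peaks"`); `ci_n = "spectra"` instead uses the number of
#' compared spectra (2) for the literal reading of the error formula.
#' Reference peaks without a counterpart are reported as disappeared.
#'
#' @param match a [match_peaks()] result.
#' @param scaling_c \eqn{^{13}}C scaling factor.
#' @param confidence_z normal quantile of the confidence level
#'   (default 1.96, i.e. 95\%).
#' @param ci_n `"peaks"` or `"spectra"`.
#' @return A list of class `ccsd_profile`: `per_peak` (named numeric,
#'   ppb), `average_ccsd`, `ci_halfwidth` (ppb; `NA` with a warning when
#'   only one pair), `n_values`, `disappeared` (character), `scaling_c`,
#'   plus the ids of the compared spectra.
#' @export
ccsd_profile <- function(match, scaling_c = 0.251, confidence_z = 1.96,
                         ci_n = c("peaks", "spectra")) {
  ci_n <- match.arg(ci_n)
  stopifnot(inherits(match, "match_result"))
  if (nrow(match$pairs) == 0L)
    stop("ccsd_profile: no matched peaks between '", match$ref_id,
         "' and '", match$query_id, "'")
  values <- ccsd(match$pairs$ddh, match$pairs$ddc, scaling_c)
  names(values) <- match$pairs$ref_label
  n <- length(values)
  avg <- mean(values)
  if (n < 2L) {
    warning("ccsd_profile: only one matched pair; CI undefined")
    hw <- NA_real_
  } else {
    denom <- if (ci_n == "peaks") n else 2L
    hw <- confidence_z * stats::sd(values) / sqrt(denom)
  }
  structure(list(per_peak = values, average_ccsd = avg,
                 ci_halfwidth = hw, n_values = n,
                 disappeared = match$unmatched_ref,
                 scaling_c = scaling_c, confidence_z = confidence_z,
                 ref_id = match$ref_id, query_id = match$query_id),
            class = "ccsd_profile")
}

#' @export
print.ccsd_profile <- function(x, ...) {
  cat(sprintf("CCSD profile: '%s' vs reference '%s'\n",
              x$query_id, x$ref_id))
  cat(sprintf("  average CCSD = %.2f +/- %.2f ppb (n = %d)\n",
              x$average_ccsd, x$ci_halfwidth, x$n_values))
  if (length(x$disappeared))
    cat(sprintf("  disappeared spin systems: %d (%s)\n",
                length(x$disappeared),
                paste(utils::head(x$disappeared, 5), collapse = ", ")))
  invisible(x)
}

#' Pairwise average-CCSD matrix
#'
#' Builds the square table of average CCSD values between every pair of
#' peak lists (e.g. time points of a batch), with a zero diagonal. With
#' label-based matching the matrix is exactly symmetric; both triangles
#' are computed and the maximal asymmetry is checked against 1e-9 ppb in
#' that mode. A pair with no matched peaks yields `NA` with a warning,
#' never a silent 0.
#'
#' @param lists list of two or more [peaklist()] objects; names (or the
#'   lists' `spectrum_id`s) become the row/column ids.
#' @param tol_h,tol_c matching tolerances in ppm.
#' @param scaling_c \eqn{^{13}}C scaling factor.
#' @param by_label use label-based matching (default).
#' @return A list of class `ccsd_matrix`: `ids` and `values` (symmetric
#'   numeric matrix, ppb, zero diagonal).
#' @export
ccsd_matrix <- function(lists, tol_h = 0.02, tol_c = 0.2,
                        scaling_c = 0.251, by_label = TRUE) {
  if (length(lists) < 2L) stop("ccsd_matrix: need at least 2 peak lists")
  stopifnot(all(vapply(lists, is_peaklist, logical(1))))
  ids <- names(lists)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(lists, spectrum_id, character(1))
  if (anyDuplicated(ids))
    ids <- make.unique(ids)
  m <- length(lists)
  values <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      mr <- match_peaks(lists[[i]], lists[[j]], tol_h, tol_c,
                        by_label = by_label, scaling_c = scaling_c)
      if (nrow(mr$pairs) == 0L) {
        warning(sprintf("ccsd_matrix: no matched peaks for (%s, %s); entry set to NA",
                        ids[i], ids[j]))
        values[i, j] <- NA_real_
      } else {
        values[i, j] <- mean(ccsd(mr$pairs$ddh, mr$pairs$ddc, scaling_c))
      }
    }
  }
  if (by_label) {
    asym <- max(abs(values - t(values)), na.rm = TRUE)
    if (is.finite(asym) && asym > 1e-9)
      warning(sprintf("ccsd_matrix: label-based matrix asymmetry %.3g ppb exceeds 1e-9",
                      asym))
  }
  structure(list(ids = ids, values = values,
                 tol_h = tol_h, tol_c = tol_c, scaling_c = scaling_c,
                 by_label = by_label),
            class = "ccsd_matrix")
}

#' @export
print.ccsd_matrix <- function(x, ...) {
  cat("Average CCSD matrix (ppb):\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Tabulate disappeared spin systems across comparisons
#'
#' Collates the disappeared-peak sets of several [ccsd_profile()]s
#' sharing a reference into one long table (one row per disappeared
#' label per comparison) plus per-comparison counts. An empty table
#' means no spin system disappeared anywhere.
#'
#' @param profiles list of `ccsd_profile` objects; names (or query ids)
#'   identify the comparisons.
#' @return A list with `by_label` (data.frame `comparison`, `label`) and
#'   `counts` (data.frame `comparison`, `n_disappeared`).
#' @export
disappeared_report <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "ccsd_profile")))
  ids <- names(profiles)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(profiles, `[[`, character(1), "query_id")
  rows <- lapply(seq_along(profiles), function(k) {
    d <- profiles[[k]]$disappeared
    if (!length(d)) return(NULL)
    data.frame(comparison = ids[k], label = sort(d),
               stringsAsFactors = FALSE)
  })
  by_label <- do.call(rbind, rows)
  if (is.null(by_label))
    by_label <- data.frame(comparison = character(), label = character(),
                           stringsAsFactors = FALSE)
  counts <- data.frame(
    comparison = ids,
    n_disappeared = vapply(profiles, function(p) length(p$disappeared),
                           integer(1)),
    stringsAsFactors = FALSE)
  list(by_label = by_label, counts = counts)
}
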