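#' Bar plot of a CCSD profile
#'
#' One bar per spin system along the reference peak list, in ppb, with a
#' horizontal line at the average CCSD. Disappeared spin systems are
#' drawn as full-height red bars, mirroring the convention of marking
#' lost cross-peaks after oxidative stress.
#'
#' @param profile a [ccsd_profile()].
#' @return A ggplot object.
#' @export
plot_ccsd_profile <- function(profile) {
  stopifnot(inherits(profile, "ccsd_profile"))
  df <- data.frame(label = names(profile$per_peak),
                   ccsd_ppb = unname(profile$per_peak),
                   disappeared = FALSE, stringsAsFactors = FALSE)
  if (length(profile$disappeared)) {
    df <- rbind(df, data.frame(label = profile$disappeared,
                               ccsd_ppb = max(df$ccsd_ppb),
                               disappeared = TRUE,
                               stringsAsFactors = FALSE))
  }
  df <- df[order(df$label), ]
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$ccsd_ppb,
                                   fill = .data$disappeared)) +
    ggplot2::geom_col(show.legend = any(df$disappeared)) +
    ggplot2::geom_hline(yintercept = profile$average_ccsd,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30",
                                          `TRUE` = "red")) +
    ggplot2::labs(x = "spin system", y = "CCSD (ppb)",
                  title = sprintf("%s vs %s (average %.1f ppb)",
                                  profile$query_id, profile$ref_id,
                                  profile$average_ccsd)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' PCA score plot of binned spectra
#'
#' @param pca a [spectra_pca()] result.
#' @param groups optional factor/character vector (one per spectrum) to
#'   colour the scores, e.g. the arm labels.
#' @param components which two components to plot.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca, groups = NULL, components = c(1L, 2L)) {
  stopifnot(inherits(pca, "pca_result"))
  k <- ncol(pca$scores)
  components <- components[components <= k]
  if (length(components) < 2L) components <- c(1L, min(2L, k))
  df <- data.frame(id = pca$ids,
                   x = pca$scores[, components[1L]],
                   y = pca$scores[, components[2L]],
                   group = if (is.null(groups)) "all" else as.character(groups),
                   stringsAsFactors = FALSE)
  evr <- pca$explained_variance_ratio
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * evr[i])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab(components[1L]), y = lab(components[2L]),
                  colour = NULL, title = "PCA score plot") +
    ggplot2::theme_minimal()
}

#' Bar plot of Euclidean distances to a reference spectrum
#'
#' @param dm a [distance_matrix()].
#' @param reference_id id of the reference spectrum.
#' @param groups optional fill grouping (one per non-reference id).
#' @return A ggplot object.
#' @export
plot_distance_bars <- function(dm, reference_id, groups = NULL) {
  df <- distances_to_reference(dm, reference_id)
  df$group <- if (is.null(groups)) df$id else as.character(groups)
  df$id <- factor(df$id, levels = df$id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id,
                                   y = .data$distance_to_reference,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Euclidean distance",
                  title = sprintf("Distances to %s", reference_id),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
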