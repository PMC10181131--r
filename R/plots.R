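#' Plot dosage calls over the signal-ratio axis
#'
#' One panel per marker: transformed signal ratios coloured by assigned
#' dosage, with unassigned records in grey.
#'
#' @param object A `dosage_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dosage_calls <- function(object, ...) {
  df <- object$calls %>%
    mutate(y = ratio_transform(.data$ratio),
           dosage = factor(.data$dosage, levels = 0:4))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$marker,
                                   colour = .data$dosage)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8, na.rm = TRUE) +
    ggplot2::scale_colour_viridis_d(na.value = "grey70", drop = FALSE) +
    ggplot2::labs(x = "asin(sqrt(HEX / (FAM + HEX)))", y = NULL,
                  colour = "dosage") +
    ggplot2::theme_minimal()
}

#' Fingerprint heatmap
#'
#' Samples by loci tile plot of dosage scores, the standard rendering of an
#' SNP fingerprint table.
#'
#' @param object A `fingerprint_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fingerprint_table <- function(object, ...) {
  loci <- fingerprint_loci(object)
  df <- tibble(sample = rep(object$sample, each = length(loci)),
               locus = factor(rep(loci, nrow(object)), levels = loci),
               dosage = factor(unlist(strsplit(object$code, "")),
                               levels = c(as.character(0:4), "N")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$sample,
                                   fill = .data$dosage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c("0" = "#f8b5c1", "1" = "#f5e05c",
                                          "2" = "#f5a623", "3" = "#d0021b",
                                          "4" = "#2e8b57", "N" = "grey85")) +
    ggplot2::labs(x = "SNP locus", y = NULL, fill = "dosage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' PCA score plot
#'
#' @param object A `dosage_pca` from [pca_scores()].
#' @param ... Unused.
#' @return A ggplot of the first two components with explained-variance
#'   percentages in the axis labels.
#' @export
autoplot.dosage_pca <- function(object, ...) {
  sc <- object$scores
  ev <- round(100 * object$explained_variance, 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ev[1]),
                  y = sprintf("PC2 (%.1f%%)", ev[2])) +
    ggplot2::theme_minimal()
}

#' SNP density track
#'
#' @param windows Window tibble from [snp_density()] or
#'   [snp_rich_regions()].
#' @return A ggplot of per-bin SNP counts along each contig; SNP-rich
#'   windows, when flagged, are highlighted.
#' @export
plot_snp_density <- function(windows) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$snp_count)) +
    ggplot2::geom_col(width = windows$end[1] - windows$start[1]) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "SNPs per bin") +
    ggplot2::theme_minimal()
  if ("rich" %in% names(windows)) {
    p <- p + ggplot2::geom_col(
      data = windows[windows$rich, , drop = FALSE], fill = "firebrick",
      width = windows$end[1] - windows$start[1])
  }
  p
}
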