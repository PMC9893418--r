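# ggplot2 views of the result types. Each plot_* function takes the tidy
# result tibble; autoplot() methods dispatch on the result classes.

#' Plot a per-column entropy profile
#'
#' @param profile Output of [column_entropy()].
#' @param highlight Optional entropy level to draw as a reference line.
#' @return A ggplot.
#' @export
plot_entropy_profile <- function(profile, highlight = 1) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$entropy)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_hline(yintercept = highlight, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Alignment position", y = "Shannon entropy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.entropy_profile <- function(object, ...) {
  plot_entropy_profile(object, ...)
}

#' Plot a Kyte-Doolittle hydropathy profile
#'
#' @param profile Output of [kd_profile()].
#' @param threshold Threshold line (default 1.6).
#' @return A ggplot.
#' @export
plot_hydropathy <- function(profile, threshold = 1.6) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Residue (window center)",
                  y = "Mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kd_profile <- function(object, ...) plot_hydropathy(object, ...)

#' Plot RSCU values per codon
#'
#' Bar chart of RSCU grouped by amino acid, one facet per sequence; the
#' dashed line at 1 separates preferred from avoided codons.
#'
#' @param rscu_tbl Output of [rscu()].
#' @return A ggplot.
#' @export
plot_rscu <- function(rscu_tbl) {
  d <- dplyr::filter(rscu_tbl, .data$aa != "*")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$codon, y = .data$rscu,
                                  fill = .data$aa)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~id) +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5,
                                                       vjust = 0.5))
}

#' Plot a sequence-logo matrix
#'
#' Stacked letter heights (frequency x column information, bits) per
#' position, the standard information-content logo view.
#'
#' @param logo Output of [logo_matrix()].
#' @param positions Optional position subset.
#' @return A ggplot.
#' @export
plot_logo_matrix <- function(logo, positions = NULL) {
  if (!is.null(positions)) {
    logo <- dplyr::filter(logo, .data$position %in% positions)
  }
  ggplot2::ggplot(logo, ggplot2::aes(x = .data$position, y = .data$height,
                                     fill = .data$letter)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.1) +
    ggplot2::labs(x = "Alignment position",
                  y = "Information (bits)", fill = "Residue") +
    ggplot2::theme_minimal()
}

#' Plot a membrane topology model
#'
#' @param topology Output of [assemble_topology()] / [membrane_topology()].
#' @return A ggplot showing the segment tiling along the sequence.
#' @export
plot_topology <- function(topology) {
  ggplot2::ggplot(topology,
                  ggplot2::aes(xmin = .data$start - 0.5,
                               xmax = .data$end + 0.5,
                               ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_manual(values = c(
      transmembrane = "grey20", extracellular = "steelblue",
      cytoplasmic = "darkorange")) +
    ggplot2::labs(x = "Residue", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.topology_model <- function(object, ...) plot_topology(object, ...)

#' Plot a bootstrap NJ tree
#'
#' Base-graphics tree plot with bootstrap supports on the internal nodes
#' (ape's plotting; trees are not a ggplot-native type).
#'
#' @param x A [bootstrap_support()] result or `phylo`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_nj_tree <- function(x, ...) {
  tree <- if (inherits(x, "boot_tree")) x$tree else x
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", adj = c(1.2, -0.5),
                    cex = 0.8)
  }
  invisible(tree)
}
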