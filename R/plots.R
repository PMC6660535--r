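#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for ricepanel results
#'
#' `autoplot()` produces a ggplot for the main result types: PCA score
#' scatter colored by subpopulation, predictive-ability boxplots per model,
#' per-marker QC histograms, and the pairwise polymorphic-count
#' distribution per group pair.
#'
#' @param object a ricepanel result object
#' @param colour column of the score tibble used for colour (PCA)
#' @param ... unused
#' @return a ggplot object.
#' @name ricepanel-autoplot
NULL

#' @rdname ricepanel-autoplot
#' @export
autoplot.geno_pca <- function(object, colour = "subpop", ...) {
  ve <- round(100 * object$var_explained[1:2], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' @rdname ricepanel-autoplot
#' @export
autoplot.gs_cv <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$model, .data$r, fill = .data$model)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "predictive ability (r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname ricepanel-autoplot
#' @param qc a [marker_qc()] tibble
#' @export
plot_marker_qc <- function(qc) {
  long <- tidyr::pivot_longer(qc, c("call_rate", "het", "maf"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}

#' @rdname ricepanel-autoplot
#' @export
autoplot.pairwise_poly <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$n_polymorphic)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~group_pair, scales = "free_y") +
    ggplot2::labs(x = "polymorphic SNPs per pair", y = "pairs") +
    ggplot2::theme_minimal()
}
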