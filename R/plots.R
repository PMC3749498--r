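#' Strip plot of per-marker densities by bin
#'
#' One dot per marker gene, grouped by taxonomic bin — the pooled
#' overview that shows how NCLDV marker density compares with the
#' cellular domains.
#'
#' @param densities Output of [marker_density()].
#' @param normalised Plot the alignment-length-normalised densities.
#' @return A ggplot object.
#' @export
plot_marker_density <- function(densities, normalised = FALSE) {
  d <- densities |>
    filter(!is.na(.data$bin)) |>
    mutate(value = if (normalised) .data$norm_density else .data$density)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL,
                  y = if (normalised) "marker density / L (per Mbp)"
                  else "marker density (hits per Mbp)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.ncldv_abundance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$genomes_per_ml,
                               shape = .data$count_source)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "NCLDV genomes per ml",
                  shape = "cell count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method
autoplot.cooccurrence_network <- function(object, ...) {
  e <- object$edges
  if (!"p_value" %in% names(e)) {
    abort("autoplot needs method-1 edge statistics")
  }
  sig <- if ("method1_pass" %in% names(e)) e$method1_pass else FALSE
  ggplot2::ggplot(e, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(boundary = 0, bins = 40, fill = "grey70") +
    ggplot2::geom_histogram(data = e[which(sig), , drop = FALSE],
                            boundary = 0, bins = 40, fill = "red3") +
    ggplot2::labs(x = "Spearman p-value", y = "taxon pairs") +
    ggplot2::theme_minimal()
}
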