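#' Plot per-exon PSI across samples
#'
#' Bar chart of percent-spliced-in for every internal exon of the model, one
#' panel per sample - the at-a-glance view of exon skipping.
#'
#' @param junctions Junction tibble.
#' @param model A [gene_model()].
#' @param samples Sample ids (default: all in the table).
#' @return A ggplot.
#' @export
plot_exon_psi <- function(junctions, model, samples = NULL) {
  if (is.null(samples)) samples <- unique(junctions$sample)
  internal <- seq(2L, length.out = max(0L, n_exons(model) - 2L))
  d <- purrr::map_dfr(samples, function(s)
    purrr::map_dfr(internal, function(k) exon_psi(junctions, model, k, s)))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$exon), y = .data$psi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "exon", y = "PSI",
                  title = sprintf("Exon inclusion, %s", model$gene_id)) +
    ggplot2::theme_minimal()
}

#' Plot junction support at a locus
#'
#' Draws each splice junction as an arc spanning its genomic gap, with line
#' width proportional to read support, over the exon boxes of the model.
#'
#' @param junctions Junction tibble.
#' @param model A [gene_model()].
#' @param sample Sample id.
#' @return A ggplot.
#' @export
plot_junctions <- function(junctions, model, sample) {
  j <- junctions[junctions$sample == sample &
                   junctions$chrom == model$chrom, ]
  ex <- model$exons
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = .data$gstart, xmax = .data$gend),
                       ymin = -0.08, ymax = 0.08, fill = "grey30") +
    ggplot2::geom_curve(data = j,
                        ggplot2::aes(x = .data$donor_end,
                                     xend = .data$acceptor_start,
                                     linewidth = .data$count),
                        y = 0.08, yend = 0.08, curvature = -0.35,
                        colour = "steelblue", alpha = 0.8) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::labs(x = sprintf("position on %s", model$chrom), y = NULL,
                  title = sprintf("Junction support in %s", sample)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.ranked_candidates <- function(object, top_n = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), top_n)
  d$label <- factor(d$id, levels = rev(d$id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label,
                                  y = pmin(.data$dist_to_splice_site,
                                           1e6),
                                  fill = .data$linked)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "distance to nearest event splice site (bp)",
                  title = "Ranked candidates") +
    ggplot2::theme_minimal()
}
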