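# cumulative genome coordinate for Manhattan-style layouts
genome_coords <- function(df) {
  df <- dplyr::arrange(df, .data$chrom, .data$bp)
  offsets <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$bp), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  dplyr::left_join(df, offsets[c("chrom", "offset")], by = "chrom") |>
    dplyr::mutate(pos = .data$bp + .data$offset)
}

#' Manhattan plot of a GRAMMAR-GC scan
#'
#' @param object A [grammar_gc_scan()] result.
#' @param threshold Optional horizontal significance line (p-value scale).
#' @param ... Unused.
#' @return A ggplot: -log10 genomic-control p-values along the genome,
#'   coloured by chromosome.
#' @export
autoplot.grammar_scan <- function(object, threshold = NULL, ...) {
  df <- genome_coords(tibble::as_tibble(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos,
                                        y = -log10(.data$p_gc),
                                        colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position (bp)",
                  y = expression(-log[10](italic(P)[GC])),
                  title = sprintf("GRAMMAR-GC scan (lambda = %.3f)",
                                  attr(object, "lambda"))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  p
}

#' Window genetic-variance shares along the genome
#'
#' @param object A [window_variance_proportions()] result.
#' @param threshold Candidate-region line (share scale, default 0.01).
#' @param ... Unused.
#' @return A ggplot of posterior-mean variance shares per 100 kb window.
#' @export
autoplot.window_result <- function(object, threshold = 0.01, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start_bp + df$end_bp) / 2
  df <- genome_coords(dplyr::rename(df, bp = "mid"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$var_proportion)) +
    ggplot2::geom_col(width = max(df$end_bp - df$start_bp) * 0.8,
                      fill = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)",
                  y = "posterior mean share of genetic variance") +
    ggplot2::theme_minimal()
}

#' Posterior SNP effects along the genome
#'
#' @param object A [run_bayesb()] fit.
#' @param ... Unused.
#' @return A ggplot of absolute posterior-mean allele-substitution
#'   effects per marker.
#' @export
autoplot.bayesb_fit <- function(object, ...) {
  df <- genome_coords(tidy(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = abs(.data$alpha_hat),
                                   colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position (bp)",
                  y = "|posterior mean SNP effect|") +
    ggplot2::theme_minimal()
}

#' Fold-level accuracy and bias of a cross-validation run
#'
#' @param object A [crossvalidate()] result.
#' @param ... Unused.
#' @return A ggplot with one point per fold for accuracy (`r`) and bias
#'   (`b`).
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("r", "b"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = paste0(attr(object, "method"),
                                 " cross-validation")) +
    ggplot2::theme_minimal()
}
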