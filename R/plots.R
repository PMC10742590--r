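#' Plot relative expression from a ddCt table
#'
#' Bars of 2^-ddCt per condition, faceted by gene, with the propagated
#' replicate error bars.
#'
#' @param object A `ugt_ddct` tibble from [ddct()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ugt_ddct <- function(object, ...) {
  object$condition <- factor(object$condition,
                             levels = unique(object$condition))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition, y = .data$rel_expr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rel_lo,
                                        ymax = .data$rel_hi), width = 0.25) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * Delta * "Ct"})) +
    ggplot2::theme_minimal()
}

#' Plot a PSPG scoring model as a weight heatmap
#'
#' @param object A `pspg_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pspg_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$aa,
                               fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "motif column", y = NULL, fill = "log2 odds") +
    ggplot2::theme_minimal()
}

#' Plot intron-class conservation
#'
#' Stacked bars of per-class intron counts split by phase, ordered I-1
#' onward along the alignment.
#'
#' @param class_summary Output of [intron_class_summary()] or
#'   [conservation_table()].
#' @return A ggplot object.
#' @export
plot_intron_classes <- function(class_summary) {
  long <- class_summary %>%
    dplyr::select("class_label", "phase0", "phase1", "phase2") %>%
    tidyr::pivot_longer(-"class_label", names_to = "phase",
                        values_to = "n") %>%
    dplyr::mutate(phase = sub("phase", "", .data$phase))
  ord <- class_summary$class_label[order(
    as.integer(sub("^I-", "", class_summary$class_label)))]
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$class_label, levels = ord),
    y = .data$n, fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "intron class", y = "introns", fill = "phase") +
    ggplot2::theme_minimal()
}

#' Plot binned promoter element counts per category
#'
#' @param counts A `promoter_counts` from [categorize_counts()].
#' @return A ggplot object.
#' @export
plot_promoter_bins <- function(counts) {
  ggplot2::ggplot(counts$bins,
                  ggplot2::aes(x = .data$bin, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::facet_wrap(~category, scales = "free_x") +
    ggplot2::labs(x = "elements per promoter", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot log2 fold changes with up/down flags
#'
#' @param fc Output of [fold_changes()].
#' @param threshold The flag threshold, drawn as guides.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(fc, threshold = 1) {
  fc <- fc %>%
    dplyr::arrange(.data$log2fc) %>%
    dplyr::mutate(rank = dplyr::row_number(),
                  flag = dplyr::case_when(.data$upregulated ~ "up",
                                          .data$downregulated ~ "down",
                                          TRUE ~ "ns"))
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$rank, y = .data$log2fc,
                                   colour = .data$flag)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", ns = "grey60")) +
    ggplot2::labs(x = "genes (ranked)", y = "log2 fold change",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
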