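#' Plot the chromosome distribution of P450 genes
#'
#' @param distribution Output of [chromosome_distribution()].
#' @return A ggplot object (bars of gene counts per chromosome).
#' @export
plot_chromosome_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$chromosome, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "P450 genes") +
    ggplot2::theme_minimal()
}

#' Plot duplication-mode counts
#'
#' @param calls Output of [classify_modes()].
#' @return A ggplot object (bars per duplication mode, fixed mode order).
#' @export
plot_duplication_modes <- function(calls) {
  calls$mode <- factor(calls$mode, levels = c("WGD", "TD", "PD", "TRD", "DSD"))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_bar(fill = "darkorange") +
    ggplot2::labs(x = "duplication mode", y = "gene pairs") +
    ggplot2::theme_minimal()
}

#' Plot Ka/Ks statistics by duplication mode
#'
#' @param calls [classify_modes()] output joined with [kaks_table()]
#'   estimates (needs `mode` and the requested statistic).
#' @param stat Which statistic to draw: `"Ks"`, `"Ka"` or `"ratio"`.
#' @return A ggplot object (boxplots per mode).
#' @export
plot_kaks_by_mode <- function(calls, stat = c("Ks", "Ka", "ratio")) {
  stat <- match.arg(stat)
  calls$mode <- factor(calls$mode, levels = c("WGD", "TD", "PD", "TRD", "DSD"))
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$mode, y = .data[[stat]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "duplication mode", y = stat) +
    ggplot2::theme_minimal()
}

#' Autoplot a flavonoid screen
#'
#' Volcano-style view of the stage-2 (component-sum) correlations: Pearson
#' r against -log10 p, candidates highlighted.
#'
#' @param object A `flavonoid_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot flavonoid_screen
#' @export
autoplot.flavonoid_screen <- function(object, ...) {
  d <- object$per_gene[object$per_gene$expressed, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_components,
                                  y = -log10(.data$p_components),
                                  colour = .data$candidate)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Pearson r (component sum)", y = "-log10 p",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
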