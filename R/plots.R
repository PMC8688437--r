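#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression fit
#'
#' @param object A `mirwin_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirwin_de <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$logFC,
                                    y = -log10(pmax(.data$PValue, 1e-300)),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value",
                  colour = sprintf("FDR < %g", object$fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' Cumulative-distribution plot of target versus background LFCs
#'
#' Reproduces the CDF-shift comparison for one tested miRNA: the empirical
#' CDF of its expressed target genes' log fold changes against the CDF of
#' all other expressed genes.
#'
#' @param shift_result A `mirwin_shift` tibble from [shift_analysis()].
#' @param mirna Which miRNA to draw (default: the smallest p-value).
#' @return A ggplot.
#' @export
plot_cdf_shift <- function(shift_result, mirna = NULL) {
  lfc_table <- attr(shift_result, "lfc_table")
  target_map <- attr(shift_result, "target_map")
  if (is.null(lfc_table) || is.null(target_map)) {
    abort("shift_result must come from shift_analysis()")
  }
  if (is.null(mirna)) {
    mirna <- shift_result$mirna_id[which.min(shift_result$p_value)]
  }
  names(lfc_table)[names(lfc_table) == "feature_id"] <- "gene_id"
  targets <- target_map$gene_id[target_map$mirna_id == mirna]
  df <- lfc_table %>%
    dplyr::mutate(set = ifelse(.data$gene_id %in% targets,
                               "targets", "background"))
  row <- shift_result[shift_result$mirna_id == mirna, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC, colour = .data$set)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(x = "log2 fold change", y = "cumulative fraction",
                  colour = NULL,
                  title = sprintf("%s: D = %.3f, p = %.2g", mirna,
                                  row$statistic, row$p_value)) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#' @param object A `mirwin_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirwin_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a median-split analysis
#' @param object A `mirwin_km` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirwin_km <- function(object, ...) {
  steps <- tidy.mirwin_km(object)
  start <- steps %>%
    dplyr::distinct(.data$group) %>%
    dplyr::mutate(time = 0, n_risk = NA_integer_, n_event = NA_integer_,
                  survival = 1)
  df <- dplyr::bind_rows(start, steps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = "expression",
                  title = sprintf("log-rank p = %.3g, HR = %.2f",
                                  object$p_value, object$hr)) +
    ggplot2::theme_minimal()
}
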