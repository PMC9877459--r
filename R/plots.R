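#' Volcano plot of a differential-expression result
#'
#' @param de A [moderated_de()] result.
#' @param p_cut,lfc_cut Threshold guides drawn on the plot.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_cut = 0.05, lfc_cut = 1) {
  ggplot2::ggplot(de, ggplot2::aes(.data$log2FC, -log10(.data$adj_p),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hub_ranking <- function(object, n = 15, ...) {
  top <- object[seq_len(min(n, nrow(object))), ]
  ggplot2::ggplot(top, ggplot2::aes(.data$mcc_score,
                                    stats::reorder(.data$node, .data$mcc_score))) +
    ggplot2::geom_col(fill = "#8e44ad") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "MCC score (log scale)", y = NULL,
                  title = "Maximal clique centrality hub ranking") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Immune quantity by signature high/low group
#'
#' Boxplot of a per-sample quantity split by a signature's mean-split
#' groups, annotated with the rank-sum significance tier.
#'
#' @param scores A [signature_scores()] table.
#' @param values Per-sample numeric quantity aligned with the table.
#' @param signature One of `"hub"`, `"tf"`, `"mirna"`.
#' @param label Axis label for the quantity.
#' @return A ggplot object.
#' @export
plot_score_groups <- function(scores, values, signature = "hub",
                              label = "value") {
  assoc <- immune_associations(scores, values, signature, "wilcoxon")
  df <- tibble::tibble(group = scores[[paste0(signature, "_group")]],
                       value = values)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("%s score group", signature), y = label,
                  subtitle = sprintf("Wilcoxon p = %.3g (%s)",
                                     assoc$p_value, assoc$tier)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a binary grouping
#'
#' @param time,event Survival outcome.
#' @param group Binary group labels.
#' @return A ggplot object with the log-rank p in the subtitle.
#' @export
plot_km <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  lr <- logrank_test(time, event, group)
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(time = fit$time, surv = fit$surv, strata = strata)
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, strata = unique(strata)), df)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$strata)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  subtitle = sprintf("log-rank p = %.3g", lr$p_value)) +
    ggplot2::theme_minimal()
}
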