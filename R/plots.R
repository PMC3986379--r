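#' Plot predicted cell-type composition by group
#'
#' Boxplots of per-sample proportions per cell type, split by group when a
#' design is supplied.
#'
#' @param W a [composition_matrix()] or [deconvolve()] result.
#' @param design optional [group_design()].
#' @return A ggplot object.
#' @export
plot_composition <- function(W, design = NULL) {
  if (inherits(W, "deconv_result")) W <- W$composition
  df <- as_tibble(W)
  p <- if (is.null(design)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$proportion))
  } else {
    design <- group_design(design)
    df <- dplyr::left_join(df, design, by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type,
                                     y = .data$proportion,
                                     fill = .data$group))
  }
  p +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn plot_composition autoplot method for `deconv_result`.
#' @param object a `deconv_result`.
#' @param ... passed on (a `design` is recognized).
#' @method autoplot deconv_result
#' @export
autoplot.deconv_result <- function(object, ...) {
  plot_composition(object, ...)
}

#' Number of calls against FDR, per cell type and direction
#'
#' The canonical read-out of a permutation FDR analysis: for each cell type,
#' the number of genes exceeding each cutoff plotted against the monotonized
#' FDR at that cutoff, one curve per tail, with the target FDR marked.
#'
#' @param object a [permutation_fdr()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cs_fdr
#' @export
autoplot.cs_fdr <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fdr, y = .data$n_obs,
                               colour = .data$direction)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$fdr_target, linetype = "dashed") +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = "false discovery rate", y = "probes called") +
    ggplot2::theme_minimal()
}

#' Group composition means with bootstrap confidence intervals
#'
#' @param summary_tbl output of [group_composition_summary()].
#' @return A ggplot object.
#' @export
plot_group_composition <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$cell_type, y = .data$mean,
                               colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(x = NULL, y = "mean proportion (95% bootstrap CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ratio scores by group
#'
#' @param scores tibble from [ratio_score()].
#' @param design a [group_design()].
#' @return A ggplot object.
#' @export
plot_ratio_scores <- function(scores, design) {
  design <- group_design(design)
  df <- dplyr::left_join(scores, design, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "up/down ratio score") +
    ggplot2::theme_minimal()
}

#' Median enrichment heat strip for candidate lists
#'
#' @param profiles tibble binding one or more [median_enrichment_profile()]
#'   outputs with an added `list` column naming each candidate list.
#' @return A ggplot object.
#' @export
plot_enrichment_profile <- function(profiles) {
  stopifnot(all(c("list", "tissue", "median_score") %in% names(profiles)))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$tissue, y = .data$list,
                               fill = .data$median_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "median\nenrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
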