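#' Plot per-sample on/off-target enrichment
#'
#' Bar chart of average fold coverage per sample, split by scope -- the
#' visual check that adaptive sampling actually enriched the targets.
#'
#' @param qc Per-sample statistics from [sample_stats()] (or
#'   [nanopore_run_qc()]).
#' @param metric Column to plot (default `"avg_cov"`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(qc, metric = "avg_cov") {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$sample, y = .data[[metric]],
                                   fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric, fill = NULL,
                  title = "On/off-target enrichment per sample") +
    ggplot2::theme_minimal()
}

#' Funnel plot of the prioritisation cascade
#'
#' Survivor counts after each stage of the filter cascade.
#'
#' @param object An `sv_cascade` from [run_cascade()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot sv_cascade
#' @export
autoplot.sv_cascade <- function(object, ...) {
  audit <- dplyr::mutate(object$audit,
                         stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(audit, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.3) +
    ggplot2::labs(x = "cascade stage", y = "records surviving",
                  title = "Prioritisation cascade audit") +
    ggplot2::theme_minimal()
}

#' Plot the LD profile of a region against its anchor SNP
#'
#' r-squared of every site versus the anchor, with the block threshold.
#'
#' @param haps A [hap_matrix()].
#' @param anchor_pos Anchor (lead SNP) position.
#' @param r2_threshold Threshold line (default 0.8).
#' @return A ggplot object.
#' @export
plot_ld_profile <- function(haps, anchor_pos, r2_threshold = 0.8) {
  prof <- r2_profile(haps, anchor_pos)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$pos, y = .data$r2)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = r2_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = anchor_pos, colour = "firebrick",
                        alpha = 0.5) +
    ggplot2::labs(x = "position (bp)", y = expression(r^2),
                  title = "LD with the anchor site") +
    ggplot2::theme_minimal()
}

#' Plot annotation-class frequencies across variant windows
#'
#' @param summary A [summarise_annotations()] result.
#' @return A ggplot object.
#' @export
plot_annotation_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$feature_class,
                                                  .data$frac),
                               y = .data$frac)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of variant windows",
                  title = "Functional annotations within ±2.5 kb") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
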