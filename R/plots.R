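#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point
#'   geom_hline geom_vline geom_abline labs theme_minimal annotate
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the single-strandedness profile of an ensemble
#'
#' Per-position probability of being unpaired, with the 0.5 accessibility
#' threshold marked; high plateaus are candidate seed regions.
#'
#' @param object A `structure_ensemble`.
#' @param threshold Threshold line to draw (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot structure_ensemble
#' @export
autoplot.structure_ensemble <- function(object, threshold = 0.5, ...) {
  df <- tidy.structure_ensemble(object)
  ggplot(df, aes(x = .data$position, y = .data$ss_prob)) +
    geom_line() +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = "position (nt)", y = "P(single-stranded)",
         title = object$seq$id) +
    theme_minimal()
}

#' Plot the energy decomposition of predicted sites
#'
#' One column block per candidate site showing the duplex energy, the two
#' disruption terms, the initiation constant and the resulting total; sites
#' with a negative total are the predicted functional ones.
#'
#' @param object A `site_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_prediction
#' @export
autoplot.site_prediction <- function(object, ...) {
  sites <- object$sites
  if (nrow(sites) == 0) stop("no candidate sites to plot")
  sites$site <- sprintf("%d-%d", sites$mrna_start, sites$mrna_end)
  long <- tidyr::pivot_longer(
    sites[, c("site", "dG_hybrid", "dG_T_disruption", "dG_S_disruption",
              "dG_total")],
    cols = -"site", names_to = "term", values_to = "kcal")
  ggplot(long, aes(x = .data$site, y = .data$kcal, fill = .data$term)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 0) +
    labs(x = "mRNA site", y = "free energy (kcal/mol)",
         title = sprintf("%s vs %s", object$srna$id, object$mrna$id)) +
    theme_minimal()
}

#' Scatter plot of RNA-seq versus Ribo-seq fold changes
#'
#' The classic two-assay view: genes off the diagonal respond more in one
#' assay than the other; points are colored by regulatory mode when
#' [classify_mode()] has been applied.
#'
#' @param calls Tibble from [call_targets()] (optionally with a `mode`
#'   column).
#' @param log2_threshold Threshold lines to draw (default 1).
#' @return A ggplot object.
#' @export
plot_target_calls <- function(calls, log2_threshold = 1.0) {
  p <- ggplot(calls, aes(x = .data$rna_log2fc, y = .data$ribo_log2fc)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_hline(yintercept = c(-log2_threshold, log2_threshold),
               linetype = "dashed") +
    geom_vline(xintercept = c(-log2_threshold, log2_threshold),
               linetype = "dashed") +
    labs(x = "RNA-seq log2 fold change (sRNA- / sRNA+)",
         y = "Ribo-seq log2 fold change (sRNA- / sRNA+)") +
    theme_minimal()
  if ("mode" %in% names(calls)) {
    p + geom_point(aes(color = .data$mode), alpha = 0.8)
  } else {
    p + geom_point(alpha = 0.8)
  }
}
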