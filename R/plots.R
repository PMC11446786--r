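# ggplot2 autoplot methods for the main result types.

#' @describeIn ordinate Scatter plot of the first two ordination components,
#'   colored by group.
#' @param object An `ir_ordination` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.ir_ordination <- function(object, ...) {
  axes <- setdiff(names(object), c("sample_id", "group"))[1:2]
  ve <- attr(object, "var_explained")
  labs <- if (!is.null(ve)) {
    sprintf("%s (%.1f%%)", axes, 100 * ve[1:2])
  } else axes
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[axes[1]]], y = .data[[axes[2]]], colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = sprintf("Sample ordination (%s) on intron ratios",
                                  toupper(attr(object, "method")))) +
    ggplot2::theme_minimal()
}

#' @describeIn diff_ir Volcano plot of `delta_psi` against `-log10(p)`,
#'   colored by call.
#' @param object A `diff_ir` object (for `autoplot`).
#' @export
autoplot.diff_ir <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$delta_psi,
                                   y = -log10(.data$p_value),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(IncIR = "#c0392b", DecIR = "#2471a3", NS = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$min_delta,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression(Delta ~ psi), y = expression(-log[10] ~ p),
                  title = sprintf("Differential intron retention: %s vs %s",
                                  object$groups["b"], object$groups["a"])) +
    ggplot2::theme_minimal()
}

#' @describeIn deg_test Volcano plot of the differential-expression table
#'   under the calling rule.
#' @param object A `deg_fit` (for `autoplot`).
#' @param p_max,fdr_max,fc_min Calling thresholds used for coloring.
#' @export
autoplot.deg_fit <- function(object, p_max = 0.05, fdr_max = 0.1,
                             fc_min = 1.2, ...) {
  rec <- call_degs(object, p_max = p_max, fdr_max = fdr_max,
                   fc_min = fc_min)$records
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$p_value),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2471a3", NS = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_min),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ p),
                  title = sprintf("Differential expression: %s vs %s",
                                  object$groups["b"], object$groups["a"])) +
    ggplot2::theme_minimal()
}

#' @describeIn link_enrichment Histogram of the random-set null totals with
#'   the observed total marked.
#' @param object A `link_enrichment` (for `autoplot`).
#' @export
autoplot.link_enrichment <- function(object, ...) {
  nulls <- tibble::tibble(total = object$null_totals)
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$total)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_total,
                        colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(x = "target-set link total of a random gene set",
                  y = "random sets",
                  title = sprintf("Observed %d links, empirical p = %.4g (K = %d)",
                                  object$observed_total, object$empirical_p,
                                  object$K)) +
    ggplot2::theme_minimal()
}

#' @describeIn recover_ir Mean intron-ratio trajectories of recovered loci
#'   across the three groups.
#' @param object An `ir_recovery` (for `autoplot`).
#' @param counts The junction-count table the recovery was computed from.
#' @export
autoplot.ir_recovery <- function(object, counts, ...) {
  sm <- recovery_summary(object, counts = counts)
  if (is.null(sm$psi_means) || nrow(sm$psi_means) == 0) {
    stop_domain("autoplot.ir_recovery: no recovered loci to plot")
  }
  dat <- sm$psi_means |>
    dplyr::mutate(group = factor(.data$group, levels = object$group_labels))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean_psi,
                                    group = .data$event_id)) +
    ggplot2::geom_line(alpha = 0.3, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = NULL, y = "mean intron ratio",
                  title = "Recovered intron-retention trajectories") +
    ggplot2::theme_minimal()
}
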