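#' Volcano-style plot of differential-splicing results
#'
#' PSI change against -log10 p, with the three-criterion filter verdict
#' mapped to color and the effect-size/p thresholds drawn as reference
#' lines.
#'
#' @param object An `nmd_diff` tibble from [test_differential()].
#' @param dpsi_min,p_max Thresholds to draw (match the values used in the
#'   test).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmd_diff <- function(object, dpsi_min = 0.10, p_max = 0.05, ...) {
  dat <- as_tibble(object) |> filter(!is.na(.data$p_value))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$delta_psi, y = -log10(.data$p_value),
    color = .data$passes_filter)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-dpsi_min, dpsi_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_max),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#7b3294",
                                           `FALSE` = "grey40"),
                                name = "passes filter") +
    ggplot2::labs(x = expression(Delta * Psi ~ "(test - control)"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Bar chart of NMD-substrate burden by event type
#'
#' @param burden `nmd_burden` tibble from [summarize_nmd_burden()].
#' @return A ggplot object.
#' @export
plot_nmd_burden <- function(burden) {
  long <- as_tibble(burden) |>
    tidyr::pivot_longer(c("nmd_up", "nmd_down"), names_to = "direction",
                        values_to = "n_events") |>
    mutate(direction = if_else(.data$direction == "nmd_up",
                               "NMD substrate up", "NMD substrate down"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$event_type,
                                     y = .data$n_events,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("NMD substrate up" = "#7b3294",
                                          "NMD substrate down" = "#008837"),
                               name = NULL) +
    ggplot2::labs(x = "event type", y = "significant events") +
    ggplot2::theme_minimal()
}

#' Variant allele frequency distributions by gene
#'
#' Box plot of somatic-call VAFs per gene, the comparison used to contrast
#' passenger-like and driver-like allelic fractions (e.g. UPF1 vs KRAS).
#'
#' @param calls Somatic call tibble with `vaf` and a gene/locus column.
#' @param gene_col Grouping column (default `"locus"`).
#' @return A ggplot object.
#' @export
plot_vaf_by_gene <- function(calls, gene_col = "locus") {
  if ("is_somatic" %in% names(calls)) calls <- calls |>
      filter(.data$is_somatic)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data[[gene_col]],
                                      y = .data$vaf)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = "variant allele frequency") +
    ggplot2::theme_minimal()
}

#' Overlap of reported mutations with standing variation
#'
#' Stacked per-context counts of match statuses from an overlap report.
#'
#' @param report `overlap_report` from [match_mutations()].
#' @return A ggplot object.
#' @export
plot_overlap_by_context <- function(report) {
  dat <- as_tibble(report) |>
    mutate(status = factor(.data$status,
                           levels = c("exact_allele", "in_reference",
                                      "position_only", "none")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$context, fill = .data$status)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "PuOr", name = "catalog match") +
    ggplot2::labs(x = NULL, y = "reported mutations") +
    ggplot2::theme_minimal()
}
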