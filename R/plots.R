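#' Plot a TSS-anchored metagene profile
#'
#' @param profile A `metagene_profile` from [metagene_profile()].
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset, y = .data$signal,
                               colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean normalized signal per gene",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metagene_profile <- function(object, ...) plot_metagene(object)

#' Plot compartment totals per sample
#'
#' Stacked normalized mark totals split into rDNA and euchromatic
#' compartments.
#'
#' @param comp A `compartment_summary` from [compartment_totals()].
#' @return A ggplot.
#' @export
plot_compartments <- function(comp) {
  tidy(comp) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$total,
                                 fill = .data$compartment)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "summed normalized signal", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.compartment_summary <- function(object, ...) plot_compartments(object)

#' Violin plot of promoter signal distributions
#'
#' @param signal A `promoter_signal` from [promoter_signal()].
#' @return A ggplot.
#' @export
plot_promoter_signal <- function(signal) {
  val <- if ("norm_count" %in% names(signal)) "norm_count" else "count"
  ggplot2::ggplot(signal,
                  ggplot2::aes(x = .data$sample_id, y = .data[[val]] + 0.5)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "promoter signal (TSS to TSS+500)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.promoter_signal <- function(object, ...) plot_promoter_signal(object)

#' Plot a copy-number track
#'
#' @param cn A `copy_number_track` from [copy_number_profile()].
#' @param chrom Optional chromosome to restrict to.
#' @return A ggplot.
#' @export
plot_copy_number <- function(cn, chrom = NULL) {
  x <- as_tibble(cn)
  if (!is.null(chrom)) x <- x[x$chrom %in% chrom, ]
  ggplot2::ggplot(x, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$cn, colour = .data$compartment)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_grid(.data$sample_id ~ .data$chrom, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position (bp)", y = "copy number (input / median)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.copy_number_track <- function(object, ...) plot_copy_number(object)
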