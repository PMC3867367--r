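#' Plot per-site Shenkin variability along an amplicon
#'
#' The variability profile makes sequencing noise visible as a low,
#' flat baseline out of which true variant sites rise; it is the visual
#' justification for a frequency threshold well above the noise floor.
#'
#' @param stats [site_stats()] output (optionally several pools).
#' @return A ggplot object.
#' @export
plot_site_variability <- function(stats) {
  if (!"shenkin_s" %in% names(stats))
    abort("Run site_stats() first.", class = "tillpool_input_error")
  p <- ggplot2::ggplot(stats,
                       ggplot2::aes(x = .data$pos, y = .data$shenkin_s)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~amplicon, scales = "free_x") +
    ggplot2::labs(x = "amplicon position (bp)",
                  y = "Shenkin variability S") +
    ggplot2::theme_minimal()
  if ("pool" %in% names(stats))
    p <- p + ggplot2::aes(colour = .data$pool)
  p
}

#' Plot pooled allele frequencies against the calling threshold
#'
#' Scatter of called alternate-allele frequencies along each amplicon
#' (log scale), with the calling threshold and, optionally, a pool's
#' predicted EMS frequency window.
#'
#' @param calls [call_snps()] output.
#' @param min_frequency Calling threshold line (default 0.005).
#' @param window Optional one-row [ems_frequency_window()] tibble drawn
#'   as a shaded band.
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(calls, min_frequency = 0.005,
                                    window = NULL) {
  p <- ggplot2::ggplot(calls,
                       ggplot2::aes(x = .data$pos, y = .data$frequency))
  if (!is.null(window))
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = window$lo, ymax = window$hi,
                               alpha = 0.15, fill = "steelblue")
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pool), size = 0.8) +
    ggplot2::geom_hline(yintercept = min_frequency, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~amplicon, scales = "free_x") +
    ggplot2::labs(x = "amplicon position (bp)",
                  y = "alternate allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot a study summary
#'
#' Bar panels of the Venn region sizes and the effect categories.
#'
#' @param object A `study_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_summary <- function(object, ...) {
  td <- tidy(object) %>%
    filter(.data$section %in% c("venn", "effects"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$item, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~section, scales = "free") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
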