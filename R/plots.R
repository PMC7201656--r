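# ggplot2 displays for the main result types.

#' @rdname saturation
#' @param object An `ltr_saturation` table.
#' @param ... Unused.
#' @method autoplot ltr_saturation
#' @export
autoplot.ltr_saturation <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("detected", "detected_filtered"),
                            names_to = "filter", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$n,
                                   colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = scales_comma) +
    ggplot2::labs(x = "subsampled read pairs", y = "detected loci",
                  colour = NULL,
                  title = "Saturation of locus detection with depth") +
    ggplot2::theme_minimal()
}

scales_comma <- function(x) format(x, big.mark = ",", scientific = FALSE)

#' @rdname pairwise_scan
#' @param object An `ltr_polymorphic_scan`.
#' @method autoplot ltr_polymorphic_scan
#' @export
autoplot.ltr_polymorphic_scan <- function(object, ...) {
  df <- tidy(object) |>
    mutate(pair = paste(.data$individual_a, .data$individual_b, sep = " vs "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = .data$neg_log10_p,
                                   colour = .data$call == "polymorphic")) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$p_max),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(object$thresholds$fc_min),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log2 CPM fold change", y = "-log10 p",
                  colour = "polymorphic",
                  title = "Polymorphic loci between individuals") +
    ggplot2::theme_minimal()
}

#' @rdname cpm_correlation
#' @param object An `ltr_cor` matrix.
#' @param ... Unused.
#' @method autoplot ltr_cor
#' @export
autoplot.ltr_cor <- function(object, ...) {
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("sample_a", "sample_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pearson correlation of locus CPMs") +
    ggplot2::theme_minimal()
}
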