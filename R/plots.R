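#' Plot methods
#'
#' `autoplot()` methods for the package's result types: the allele
#' frequency spectrum of a variant table, per-pool coverage from a QC
#' report, and the permutation null of a burden test.
#'
#' @param object A `variant_table`, `coverage_report` or `burden_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name poolscreen-autoplot
NULL

#' @rdname poolscreen-autoplot
#' @export
autoplot.variant_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$af)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cohort allele frequency (log scale)",
                  y = "variants",
                  title = "Rare-variant site frequency spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname poolscreen-autoplot
#' @export
autoplot.coverage_report <- function(object, ...) {
  ggplot2::ggplot(object$pools,
                  ggplot2::aes(x = stats::reorder(.data$pool_id,
                                                  .data$fraction_covered),
                               y = .data$fraction_covered)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("fraction of bases at >= %dx per individual",
                              object$per_individual_threshold),
                  title = "Per-pool target coverage") +
    ggplot2::theme_minimal()
}

#' @rdname poolscreen-autoplot
#' @export
autoplot.burden_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick") +
    ggplot2::labs(x = "permutation rate difference (case - control)",
                  y = "permutations",
                  title = sprintf("Gene burden permutation null (P = %.3g)",
                                  object$p)) +
    ggplot2::theme_minimal()
}
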