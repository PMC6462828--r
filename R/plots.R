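#' Plot the allele frequency distribution per gene
#'
#' Stacked bars of allele frequencies within each gene; novel alleles (8-
#' digit) are highlighted when panel entries are supplied.
#'
#' @param distribution Result of [allele_distribution()].
#' @param entries Optional panel entries (for novelty colouring; allele
#'   ids must match).
#' @return A ggplot object.
#' @export
plot_allele_distribution <- function(distribution, entries = NULL) {
  df <- distribution$frequencies
  if (!is.null(entries)) {
    df <- df |>
      left_join(entries |> select("allele_id", "novel_8digit"),
                by = c(allele = "allele_id")) |>
      mutate(novel = tidyr::replace_na(.data$novel_8digit, FALSE))
  } else {
    df$novel <- FALSE
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$frequency,
                                   fill = .data$novel,
                                   group = .data$allele)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85",
                                          `TRUE` = "#d95f02"),
                               name = "novel (8-digit)") +
    ggplot2::labs(x = NULL, y = "allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot population coverage by resolution
#'
#' @param coverage Tibble from [population_coverage()] (possibly several
#'   resolutions bound together).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = factor(.data$resolution),
                               y = .data$coverage, fill = .data$gene)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "name resolution (digits)", y = "population coverage",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot variant accuracy by pipeline stage
#'
#' @param accuracy Accuracy tibble of a `panel_run` (stage, gene,
#'   accuracy).
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  df <- accuracy |> filter(.data$gene != ".mean")
  df$stage <- factor(df$stage, levels = c("draft", "refined", "panel"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$accuracy,
                                   group = .data$gene,
                                   colour = .data$gene)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "variant accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a pipeline run (variant accuracy by stage)
#'
#' @param object A `panel_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panel_run <- function(object, ...) {
  plot_accuracy(object$accuracy)
}
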