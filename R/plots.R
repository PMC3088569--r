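#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the read-accounting distributions of a run
#'
#' Stacked single-bar charts of the adaptor-class and size-class read
#' fractions plus the annotation-category read distribution, the run's
#' at-a-glance composition.
#'
#' @param object an `srna_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.srna_run <- function(object, ...) {
  cats <- object$screen$categories |>
    dplyr::transmute(block = "adaptor class", level = as.character(.data$category),
                     n_reads = .data$n_reads)
  sizes <- object$screen$size_classes |>
    dplyr::transmute(block = "insert size (legitimate)",
                     level = as.character(.data$size_class),
                     n_reads = .data$n_reads)
  ann <- object$report$annotation |>
    dplyr::filter(.data$category != "total") |>
    dplyr::transmute(block = "annotation (matched)",
                     level = .data$category, n_reads = .data$n_reads)
  df <- dplyr::bind_rows(cats, sizes, ann)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$n_reads,
                                   fill = .data$level)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "fraction of reads", fill = NULL,
                  title = "Read accounting") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Arc diagram of a folded RNA structure
#'
#' Base pairs are drawn as arcs over the sequence axis; the mature region
#' of a hairpin candidate is highlighted.
#'
#' @param object an `rna_fold` or `hairpin_candidate`.
#' @param mature optional integer range to highlight (positions).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rna_fold <- function(object, mature = NULL, ...) {
  n <- nchar(object$sequence)
  base_df <- tidy(object)
  p <- ggplot2::ggplot(base_df, ggplot2::aes(x = .data$position, y = 0))
  if (nrow(object$pairs) > 0) {
    arcs <- purrr::map_dfr(seq_len(nrow(object$pairs)), function(r) {
      i <- object$pairs[r, 1]; j <- object$pairs[r, 2]
      t <- seq(0, pi, length.out = 24)
      tibble::tibble(arc = r,
                     x = (i + j) / 2 + (j - i) / 2 * cos(t),
                     y = (j - i) / 2 * sin(t))
    })
    p <- p + ggplot2::geom_path(
      data = arcs, ggplot2::aes(x = .data$x, y = .data$y, group = .data$arc),
      linewidth = 0.3, colour = "steelblue")
  }
  if (!is.null(mature)) {
    p <- p + ggplot2::annotate("rect", xmin = min(mature) - 0.5,
                               xmax = max(mature) + 0.5, ymin = -n / 30,
                               ymax = 0, fill = "firebrick", alpha = 0.5)
  }
  p +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "position (nt)", y = NULL,
                  title = sprintf("MFE %.2f kcal/mol", object$energy)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @export
autoplot.hairpin_candidate <- function(object, ...) {
  autoplot(object$structure,
           mature = object$mature_offset:
             (object$mature_offset + object$mature_length - 1), ...)
}

#' Expression rank plot
#'
#' CPM versus abundance rank on a log scale, the standard look at a
#' heavy-tailed small RNA expression table.
#'
#' @param records expression tibble from [expression_table()].
#' @param top_n label the top n features.
#' @return a ggplot object.
#' @export
plot_expression_rank <- function(records, top_n = 5) {
  df <- dplyr::mutate(dplyr::arrange(records, dplyr::desc(.data$cpm)),
                      rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cpm)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(data = utils::head(df, top_n),
                       ggplot2::aes(label = .data$mirna_id),
                       hjust = -0.1, vjust = 0.5, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "CPM") +
    ggplot2::theme_minimal()
}
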