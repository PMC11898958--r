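# Graphical exports: endpoint heat map and Williams plot (vector graphics),
# each with a companion CSV of the plotted values.

utils::globalVariables(c("index", "compound", "value", "std_residual", "set"))

#' Export a clustered endpoint heat map
#'
#' Writes a vector-graphics (PDF) heat map of the auto-scaled endpoint
#' values with compounds ordered by the dendrogram leaf order, plus a
#' companion CSV of the plotted matrix in the same row order.
#'
#' @param table the `retention_table` that was clustered
#' @param clustering a `qsrr_hclust` computed on `table`
#' @param path output PDF path; the companion CSV replaces the extension
#' @return Invisibly, the paths written (`plot`, `csv`).
#' @export
heatmap_export <- function(table, clustering, path) {
  stopifnot(inherits(clustering, "qsrr_hclust"))
  S <- clustering$data[clustering$tree$order, , drop = FALSE]
  if (!setequal(rownames(S), table$name)) {
    stop("clustering was not computed on this table")
  }
  long <- data.frame(
    compound = factor(rep(rownames(S), ncol(S)),
                      levels = rev(rownames(S))),
    index = factor(rep(colnames(S), each = nrow(S)), levels = colnames(S)),
    value = as.vector(S))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = index, y = compound, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "auto-scaled\nvalue") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Biomimetic chromatography endpoints") +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(path, p, width = 5, height = 0.25 * nrow(S) + 1.5,
                  limitsize = FALSE)
  csv <- paste0(sub("\\.[A-Za-z]+$", "", path), ".csv")
  write.csv(data.frame(compound = rownames(S), S, check.names = FALSE),
            csv, row.names = FALSE)
  invisible(list(plot = path, csv = csv))
}

#' Export a Williams plot
#'
#' Leverage against standardized residual for training and validation
#' compounds, with the critical leverage `h*` and the +/- 3 residual band
#' marked. A companion CSV holds the plotted assessment table.
#'
#' @param assessment a `domain_assessment` from [williams_assessment()]
#' @param path output PDF path; the companion CSV replaces the extension
#' @return Invisibly, the paths written (`plot`, `csv`).
#' @export
williams_plot_export <- function(assessment, path) {
  stopifnot(inherits(assessment, "domain_assessment"))
  h_star <- attr(assessment, "h_star")
  df <- as.data.frame(assessment)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = leverage, y = std_residual,
                                        colour = set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(training = "#2e7d32",
                                            validation = "#6a1b9a")) +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)", h_star)) +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(path, p, width = 5, height = 4)
  csv <- paste0(sub("\\.[A-Za-z]+$", "", path), ".csv")
  write.csv(df, csv, row.names = FALSE)
  invisible(list(plot = path, csv = csv))
}
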