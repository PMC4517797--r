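#' Plot benchmark results
#'
#' Fraction of replicates ranked accurately (AUC above the threshold) against
#' seed-set size, one line per scoring method.
#'
#' @param object An `ebc_benchmark` from [benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebc_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$seed_size, y = .data$fraction_auc_above,
    colour = .data$method, group = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = unique(object$seed_size)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Seed set size |S|",
      y = sprintf("Fraction of test sets with AUC > %.2g",
                  attr(object, "threshold") %||% 0.7),
      colour = "Method"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmaps of a matrix and its ITCC smoothing
#'
#' Draws the binary matrix with rows and columns ordered by cluster, next to
#' the "smoothed" block approximation the biclustering implies; cells absent
#' from the data but consistent with the block structure light up in the
#' smoothed panel.
#'
#' @param matrix The matrix the biclustering was fitted to.
#' @param biclustering An `ebc_biclustering` from [itcc()].
#' @return A ggplot object (two facets: observed and smoothed).
#' @export
plot_smoothed <- function(matrix, biclustering) {
  M <- as_dense(matrix)
  q <- smoothed_matrix(matrix, biclustering)
  ro <- order(biclustering$row_assign)
  co <- order(biclustering$col_assign)
  long <- function(mat, panel) {
    tibble(
      row = rep(seq_len(nrow(mat)), ncol(mat)),
      col = rep(seq_len(ncol(mat)), each = nrow(mat)),
      value = as.vector(mat),
      panel = panel
    )
  }
  dat <- dplyr::bind_rows(long(M[ro, co], "observed"),
                          long(q[ro, co], "smoothed"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkorange") +
    ggplot2::labs(x = "Dependency paths (cluster order)",
                  y = "Entity pairs (cluster order)", fill = "Mass") +
    ggplot2::theme_minimal()
}

#' Plot the relationship landscape dendrogram
#'
#' Base-graphics dendrogram of a minimax-linkage tree, optionally coloured by
#' a tree cut.
#'
#' @param tree An `ebc_protoclust`.
#' @param cut_height Optional height at which to draw the cut line.
#' @param ... Passed to [plot()].
#' @return Invisibly, the tree.
#' @export
plot_landscape <- function(tree, cut_height = NULL, ...) {
  hc <- stats::as.hclust(tree)
  plot(hc, hang = -1, xlab = "", sub = "", ...)
  if (!is.null(cut_height)) {
    graphics::abline(h = cut_height, col = "red", lty = 2)
  }
  invisible(tree)
}
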