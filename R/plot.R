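# Plotting: annotated spectra (ggplot2) and fragmentation trees (igraph).

#' Plot an annotated spectrum
#'
#' Stick spectrum with annotated peaks highlighted and labelled by the
#' best-matching ion formula.
#'
#' @param object an `annotation_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.annotation_result <- function(object, ...) {
  d <- tidy.annotation_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0,
                                       colour = .data$annotated),
                          linewidth = 0.8) +
    ggplot2::geom_text(data = d[d$annotated, ],
                       ggplot2::aes(label = .data$best_formula),
                       vjust = -0.4, size = 2.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey55"),
                                 labels = c(`TRUE` = "annotated",
                                            `FALSE` = "unannotated"),
                                 name = NULL) +
    ggplot2::labs(x = "m/z", y = "relative intensity (%)",
                  title = object$label,
                  subtitle = paste("score", score_string(object))) +
    ggplot2::ylim(0, 112) +
    ggplot2::theme_minimal()
}

#' Plot a spectrum
#' @param object an `ms_spectrum`.
#' @param ... unused.
#' @export
autoplot.ms_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.8, colour = "grey30") +
    ggplot2::labs(x = "m/z", y = "relative intensity (%)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a fragmentation tree
#'
#' Layered (Sugiyama) layout of the ion DAG; nodes are labelled with formula
#' and 2-decimal m/z, edges with the applied rule.
#'
#' @param x a `frag_tree`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.frag_tree <- function(x, ...) {
  if (nrow(x$nodes) == 0) {
    graphics::plot.new(); graphics::title("empty fragmentation tree")
    return(invisible(x))
  }
  ig <- igraph::graph_from_data_frame(
    d = x$edges[, c("parent", "child", "rule")],
    directed = TRUE,
    vertices = data.frame(name = x$nodes$id,
                          label = sprintf("%s\n%.2f", x$nodes$formula,
                                          x$nodes$mz)))
  lay <- igraph::layout_with_sugiyama(ig,
                                      layers = x$nodes$stage + 1)$layout
  igraph::plot.igraph(ig, layout = lay,
                      vertex.label = igraph::V(ig)$label,
                      vertex.shape = "rectangle", vertex.size = 30,
                      vertex.size2 = 14, vertex.color = "white",
                      vertex.label.cex = 0.6,
                      edge.label = igraph::E(ig)$rule,
                      edge.label.cex = 0.5, edge.arrow.size = 0.3, ...)
  invisible(x)
}
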