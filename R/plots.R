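# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RMS network
#'
#' Nodes are transformation classes (sized by member count), directed
#' edges are drawn with width proportional to the transition
#' probability.  The layout is a seeded Fruchterman-Reingold embedding,
#' so the same network always draws the same picture.
#'
#' @param object an `rms_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rms_network
#' @export
autoplot.rms_network <- function(object, seed = 1L, ...) {
  g <- rms_igraph(object)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  nd <- tibble::tibble(class_id = igraph::V(g)$name,
                       n_members = igraph::V(g)$n_members,
                       x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    dplyr::left_join(nd[c("class_id", "x", "y")],
                     by = c(from = "class_id")) |>
    dplyr::left_join(nd[c("class_id", "x", "y")],
                     by = c(to = "class_id"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$prob),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_members),
      colour = "steelblue") +
    ggplot2::geom_text(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$class_id),
      vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "reactions", linewidth = "Pr(j|i)",
                  title = sprintf("RMS network (height %d)", object$height))
}

#' Plot conserved modules by length and PCI
#'
#' @param object an `rms_modules` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rms_modules
#' @export
autoplot.rms_modules <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$length), y = .data$pci)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, colour = "steelblue") +
    ggplot2::labs(x = "path length (edges)", y = "PCI",
                  title = "Conserved chemical transformation modules") +
    ggplot2::theme_minimal()
}

#' Score-separation boxplots
#'
#' Distribution of the conservation scores over all enumerated paths
#' versus paths that occur as windows of known metabolic pathways, the
#' package's analogue of the score-separation analysis.
#'
#' @param paths tibble from [score_all_paths()].
#' @param length restrict to one path length (default 2 edges).
#' @return A ggplot object.
#' @export
plot_score_separation <- function(paths, length = 2L) {
  df <- paths[paths$length == length, ]
  long <- tidyr::pivot_longer(
    df[c("known_window", "score_rea", "score_pagerank", "score_prot")],
    cols = -"known_window", names_to = "score", values_to = "value")
  long <- long[!is.na(long$value), ]
  long$set <- ifelse(long$known_window, "Known metabolic windows", "All paths")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "score (log scale)",
                  title = sprintf("Conservation scores, paths of length %d",
                                  length)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
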