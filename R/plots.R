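# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.redundancy_matrix <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(df,
                         dplyr::rename(df, site_i = "site_j",
                                       site_j = "site_i"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$site_i),
                                   y = factor(.data$site_j),
                                   fill = .data$R)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "R") +
    ggplot2::labs(x = "site", y = "site",
                  title = "Pairwise interdependency redundancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 6))
}

#' @exportS3Method ggplot2::autoplot
autoplot.kmodes_config <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = factor(.data$cluster),
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_tile(height = 0.8, width = 0.9, show.legend = FALSE) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$is_mode),
                        ggplot2::aes(x = .data$site,
                                     y = factor(.data$cluster)),
                        shape = 21, fill = "white", size = 2,
                        show.legend = FALSE) +
    ggplot2::labs(x = "site label", y = "cluster",
                  title = paste0("k-modes partition, k = ", object$k),
                  subtitle = "white dot = cluster mode") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.kmodes_sweep <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(best_sr_mode = max(.data$sr_mode),
                     mean_sr_mode = mean(.data$sr_mode[.data$order >= 2]),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"k", names_to = "summary", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$summary)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "k (sweep direction)", y = "SR(mode)",
                  title = "Cluster interdependency across the k-sweep") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_tree <- function(object, ...) {
  nd <- tidy(object)
  nd$x <- vapply(object$nodes$sites, function(s) mean(s), numeric(1))
  seg <- object$edges
  if (nrow(seg) > 0) {
    seg$x <- nd$x[match(seg$child, nd$node)]
    seg$y <- nd$order[match(seg$child, nd$node)]
    seg$xend <- nd$x[match(seg$parent, nd$node)]
    seg$yend <- nd$order[match(seg$parent, nd$node)]
  }
  p <- ggplot2::ggplot(nd, ggplot2::aes(x = .data$x, y = .data$order))
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend),
      colour = "grey60")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$branch),
                                     shape = .data$representative),
                        size = 2) +
    ggplot2::scale_y_reverse(breaks = unique(nd$order)) +
    ggplot2::labs(x = "mean site label", y = "cluster order",
                  colour = "branch", shape = "representative",
                  title = "Cluster tree across the k-sweep") +
    ggplot2::theme_minimal()
}
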