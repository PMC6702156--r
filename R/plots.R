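#' Hockey-stick plot of ranked enhancer signal
#'
#' The classic super-enhancer figure: regions ordered by increasing total
#' signal, with the cutoff and flagged super-enhancers highlighted.
#'
#' @param x An `se_table` (from [super_cutoff()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_table <- function(x, ...) {
  d <- tibble::as_tibble(x)
  d$order <- nrow(d) - d$rank + 1
  cutoff <- attr(x, "cutoff_signal")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$order, y = .data$signal,
                                       colour = .data$is_super)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "super-enhancer") +
    ggplot2::labs(x = "regions ranked by signal",
                  y = "total H3K27ac signal (rpm)") +
    ggplot2::theme_minimal()
  if (!is.na(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Bar plot of TFs ranked by total degree
#'
#' @param nodes A node tibble (from [rank_tfs()]) or a `crc_network`.
#' @return A ggplot object.
#' @export
plot_tf_degrees <- function(nodes) {
  if (inherits(nodes, "crc_network")) nodes <- nodes$nodes
  ggplot2::ggplot(nodes,
                  ggplot2::aes(x = stats::reorder(.data$tf, .data$rank),
                               y = .data$total_degree)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "total degree") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.crc_network <- function(x, ...) plot_tf_degrees(x)

#' Heatmap of summit-centered signal by chromatin state
#'
#' Rows (binding sites) are grouped by state cluster; columns are position
#' bins, faceted by mark. Bins are down-sampled for display.
#'
#' @param x A `state_clustering`.
#' @param mats The matrices used for clustering (named list per mark).
#' @param every Keep every `every`-th bin (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_clustering <- function(x, mats, every = 10, ...) {
  ord <- order(x$assignments$cluster)
  long <- dplyr::bind_rows(lapply(names(mats), function(mk) {
    m <- mats[[mk]][ord, seq(1, ncol(mats[[mk]]), by = every),
                    drop = FALSE]
    tibble::tibble(mark = mk,
                   site = rep(seq_len(nrow(m)), times = ncol(m)),
                   bin = rep(seq_len(ncol(m)), each = nrow(m)),
                   signal = as.numeric(m))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$site,
                                     fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~mark, nrow = 1) +
    ggplot2::scale_fill_viridis_c(name = "rpm/bp") +
    ggplot2::labs(x = "position bin", y = "binding site (by state)") +
    ggplot2::theme_minimal()
}
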