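# ggplot2 displays for the main result types.

#' Plot a crosslink track region
#'
#' @param track Crosslink track tibble (contig, strand, pos, count).
#' @param contig Contig to display (default: first in the track).
#' @param xlim Optional position range.
#' @return A ggplot object: per-nucleotide crosslink events, one facet
#'   per strand.
#' @export
plot_crosslink_track <- function(track, contig = NULL, xlim = NULL) {
  if (is.null(contig)) contig <- track$contig[1]
  d <- track[track$contig == contig, , drop = FALSE]
  if (!is.null(xlim)) d <- d[d$pos >= xlim[1] & d$pos <= xlim[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strand)) +
    ggplot2::labs(x = paste0("position on ", contig),
                  y = "crosslink events") +
    ggplot2::theme_minimal()
}

#' @rdname dimer_profile
#' @param object A `dimer_profile` or `moderated_fit`.
#' @param ... Unused.
#' @method autoplot dimer_profile
#' @export
autoplot.dimer_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset, y = .data$occurrence,
                               colour = .data$dimer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from site midpoint (nt)",
                  y = "mean 2-mer occurrence", colour = "2-mer") +
    ggplot2::theme_minimal()
}

#' @rdname moderated_test
#' @param object A `moderated_fit`.
#' @param ... Unused.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, ...) {
  d <- object$results
  if (!"significant" %in% names(d)) d$significant <- FALSE
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
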