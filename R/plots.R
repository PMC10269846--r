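#' Plot methods
#'
#' Thin ggplot2 views of the package's result objects.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name coretier-plots
NULL

#' @rdname coretier-plots
#' @method autoplot core_sweep
#' @export
autoplot.core_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("jaccard", "abund_real", "abund_sim"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "prevalence threshold (%)", y = NULL,
                  title = "Core threshold sweep",
                  subtitle = "Jaccard agreement and core-set abundance, real vs simulated")
}

#' @rdname coretier-plots
#' @method autoplot ncm_fit
#' @export
autoplot.ncm_fit <- function(object, ...) {
  tx <- dplyr::filter(object$taxa, .data$fitted)
  tx <- dplyr::arrange(tx, .data$p)
  ggplot2::ggplot(tx, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f, colour = .data$label), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::scale_colour_manual(values = c(above = "turquoise3",
                                            below = "red3",
                                            neutral = "grey25")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  title = sprintf("Neutral model fit: Nm = %.1f, R² = %.3f",
                                  object$Nm, object$r_squared))
}

#' @rdname coretier-plots
#' @method autoplot doc_fit
#' @export
autoplot.doc_fit <- function(object, ...) {
  cp <- if (is.na(object$change_point)) max(object$curve$overlap) else object$change_point
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$overlap, y = .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_ribbon(data = object$curve,
                         ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi),
                         fill = "red", alpha = 0.15) +
    ggplot2::geom_line(data = object$curve, colour = "red") +
    ggplot2::geom_vline(xintercept = cp, linetype = 2) +
    ggplot2::labs(x = "overlap", y = "rJSD", title = "Dissimilarity-overlap curve")
}

#' @rdname coretier-plots
#' @method autoplot nmds_ordination
#' @export
autoplot.nmds_ordination <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("NMDS (stress = %.4f)", object$stress))
}

#' Edge-frequency histogram of a combined network
#'
#' @param net A `combined_network`.
#' @param min_freq Frequency cut to mark (default 20).
#' @return A ggplot.
#' @export
plot_edge_histogram <- function(net, min_freq = 20) {
  stopifnot(inherits(net, "combined_network"))
  ggplot2::ggplot(net$histogram,
                  ggplot2::aes(x = .data$frequency, y = .data$n_edges)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = min_freq + 0.5, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "edge frequency across simulated subcommunities",
                  y = "number of edges")
}
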