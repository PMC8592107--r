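#' Plot a stopping boundary
#'
#' Draws the lower and upper continuation limits against the number of
#' pairwise allocations (observed plus pipeline). The continuation
#' region is the band between the curves; it pinches shut at the
#' maximum sample size.
#'
#' @param object A `valseq_boundary`.
#' @param coordinate x-axis convention: `"allocations"` (observed +
#'   pipeline pairs) or `"effective"` (prior effective sample size n0 +
#'   allocations).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot valseq_boundary
#' @export
autoplot.valseq_boundary <- function(object, coordinate = c("allocations", "effective"),
                                     ...) {
  coordinate <- match.arg(coordinate)
  tb <- tidy(object)
  tb$x <- if (coordinate == "allocations") tb$allocations else tb$plot_coordinate
  tb <- tidyr::pivot_longer(tb, cols = c("lower_gbp", "upper_gbp"),
                            names_to = "side", values_to = "mu")
  ggplot2::ggplot(tb[!is.na(tb$mu), ],
                  ggplot2::aes(x = .data$x, y = .data$mu, group = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = if (coordinate == "allocations") "pairwise allocations (observed + pipeline)"
          else "effective sample size (n0 + allocations)",
      y = "posterior mean of incremental net monetary benefit (GBP)",
      title = "Optimal stopping boundary",
      subtitle = "continue recruiting while the posterior mean stays between the curves"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a replayed path over its stopping boundary
#'
#' @param object A `valseq_path`.
#' @param ... Passed to [autoplot.valseq_boundary()].
#' @return A ggplot object.
#' @method autoplot valseq_path
#' @export
autoplot.valseq_path <- function(object, ...) {
  p <- autoplot(object$boundary, ...)
  looks <- tidy(object)
  p +
    ggplot2::geom_line(data = looks,
                       ggplot2::aes(x = .data$allocations, y = .data$mu),
                       inherit.aes = FALSE, colour = "#2166AC") +
    ggplot2::geom_point(data = looks,
                        ggplot2::aes(x = .data$allocations, y = .data$mu),
                        inherit.aes = FALSE, colour = "#2166AC") +
    ggplot2::geom_point(data = looks[nrow(looks), ],
                        ggplot2::aes(x = .data$allocations, y = .data$mu),
                        inherit.aes = FALSE, shape = 4, size = 3, stroke = 1.5,
                        colour = "#B2182B") +
    ggplot2::labs(subtitle = "interim posterior means; X marks the stopping look")
}

#' Plot operating characteristics
#'
#' @param object A `valseq_oc`.
#' @param type `"sample_size"` (relative-frequency histogram of
#'   allocations at first crossing), `"ecdf"` (its empirical CDF) or
#'   `"posterior"` (histogram of the terminal posterior mean).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot valseq_oc
#' @export
autoplot.valseq_oc <- function(object, type = c("sample_size", "ecdf", "posterior"),
                               ...) {
  type <- match.arg(type)
  pp <- object$per_path
  base <- ggplot2::theme_minimal()
  if (type == "sample_size") {
    ggplot2::ggplot(pp, ggplot2::aes(x = .data$allocations_T,
                                     y = ggplot2::after_stat(.data$count) / nrow(pp))) +
      ggplot2::geom_histogram(binwidth = object$params$block_size,
                              boundary = 0, fill = "grey35") +
      ggplot2::labs(x = "pairwise allocations at first boundary crossing",
                    y = "relative frequency") + base
  } else if (type == "ecdf") {
    ggplot2::ggplot(pp, ggplot2::aes(x = .data$allocations_T)) +
      ggplot2::stat_ecdf() +
      ggplot2::labs(x = "pairwise allocations at first boundary crossing",
                    y = "empirical CDF") + base
  } else {
    ggplot2::ggplot(pp, ggplot2::aes(x = .data$mu_final,
                                     y = ggplot2::after_stat(.data$count) / nrow(pp))) +
      ggplot2::geom_histogram(bins = 40, fill = "grey35") +
      ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
      ggplot2::labs(x = "terminal posterior mean of incremental net monetary benefit (GBP)",
                    y = "relative frequency") + base
  }
}
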