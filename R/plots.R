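#' Plot a correlation matrix heat map
#'
#' @param object A `cn_correlation` object.
#' @param ... Unused.
#' @return A ggplot object: variables on both axes, tiles coloured by r
#'   on a blue-white-red scale.
#' @method autoplot cn_correlation
#' @export
autoplot.cn_correlation <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, source = "target", target = "source"),
    tibble::tibble(source = object$variable_ids,
                   target = object$variable_ids, r = 1)
  )
  lv <- object$variable_ids
  df2$source <- factor(df2$source, levels = lv)
  df2$target <- factor(df2$target, levels = rev(lv))
  ggplot2::ggplot(df2, ggplot2::aes(.data$source, .data$target,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = paste0("Pairwise ", object$method,
                                 " correlation")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the degree distribution of a topology report
#'
#' Log-log scatter of degree versus frequency with the fitted power-law
#' line overlaid when the fit is defined.
#'
#' @param object A `cn_topology` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cn_topology
#' @export
autoplot.cn_topology <- function(object, ...) {
  deg <- object$vertices$degree
  deg <- deg[deg > 0]
  tab <- table(deg)
  df <- tibble::tibble(degree = as.numeric(names(tab)),
                       count = as.numeric(tab))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$degree, .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of vertices",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
  pl <- object$power_law
  if (!is.na(pl$exponent)) {
    fit <- stats::lm(log(count) ~ log(degree), data = df)
    df$fitted <- exp(stats::fitted(fit))
    p <- p + ggplot2::geom_line(data = df,
                                ggplot2::aes(y = .data$fitted),
                                linetype = "dashed", colour = "grey40") +
      ggplot2::labs(subtitle = sprintf("power-law exponent %.2f (r² = %.2f)",
                                       pl$exponent, pl$r_squared))
  }
  p
}
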