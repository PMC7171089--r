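#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a regional comparison
#'
#' @param x a `region_comparison` from [compare_groups()].
#' @param ... unused.
#' @return tibble with one row per region: `region_id`, `estimate` (log fold
#'   change), `statistic`, `p.value`, `q.value`, `significant`.
#' @export
tidy.region_comparison <- function(x, ...) {
  tibble::tibble(region_id = x$region_id, estimate = x$log_fc,
                 statistic = x$statistic, p.value = x$p_value,
                 q.value = x$q_value, significant = x$significant)
}

#' @rdname tidy.region_comparison
#' @export
glance.region_comparison <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x),
                 n_tested = sum(!x$degenerate),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 min_q = suppressWarnings(min(x$q_value, na.rm = TRUE)))
}

#' @rdname tidy.region_comparison
#' @export
tidy.nb_test <- function(x, ...) {
  tibble::tibble(term = "group", estimate = x$log_fc,
                 statistic = x$statistic, p.value = x$p_value)
}

#' @rdname tidy.region_comparison
#' @export
glance.nb_test <- function(x, ...) {
  tibble::tibble(mean_a = x$mean_a, mean_b = x$mean_b,
                 dispersion = x$dispersion, test = x$test,
                 degenerate = x$degenerate)
}

#' Volcano-style plot of a regional comparison
#'
#' Log fold change against `-log10(q)`, significant regions highlighted.
#'
#' @param object a `region_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.region_comparison <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$q.value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(pmax(.data$q.value, 1e-300)),
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log fold change (density)",
                  y = expression(-log[10] ~ q),
                  color = "q < threshold") +
    ggplot2::theme_minimal()
}

#' Mid-volume section plot
#'
#' Quick look at a volume: a raster of one z section (default the middle
#' one).
#'
#' @param object a [volume()].
#' @param z section index (1-based), default middle.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.volume <- function(object, z = NULL, ...) {
  d <- dim(object$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[1]))
  df$value <- as.vector(object$data[, , z])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("section z = %d", z)) +
    ggplot2::theme_minimal()
}
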