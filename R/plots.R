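# Plot layers: confusion heatmap, prediction timelines, precision boxplots.
# These are thin, non-contractual views over the evaluation tibbles.

#' Plot a confusion chart as a heatmap
#'
#' @param object An `sladl_confusion`.
#' @param normalize `"none"` for raw counts, `"row"` (diagonal =
#'   sensitivity) or `"column"` (diagonal = precision) for percentages.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sladl_confusion <- function(object, normalize = "none", ...) {
  m <- if (normalize == "none") unclass(object) * 1.0 else {
    normalize_chart(object, normalize)
  }
  d <- tibble::as_tibble(as.data.frame.table(m, responseName = "value"))
  names(d)[1:2] <- c("true", "predicted")
  lab <- if (normalize == "none") "count" else "%"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$value), "",
                     format(round(.data$value, 1), trim = TRUE))),
      size = 3) +
    ggplot2::scale_y_discrete(limits = rev(SLADL_CLASSES)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey90", name = lab) +
    ggplot2::labs(x = "predicted class", y = "true class")
}

#' Plot true-versus-predicted timelines for one fold
#'
#' Solid line: annotated class; dashed line: predicted class, both at 10 Hz.
#'
#' @param fold_result One row of an `sladl_loso`.
#' @return A ggplot object.
#' @export
plot_timeline <- function(fold_result) {
  tl <- export_timeline(fold_result)
  d <- tidyr::pivot_longer(tl, c("true", "pred"), names_to = "series",
                           values_to = "class")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s,
                                  y = as.integer(.data$class),
                                  linetype = .data$series)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::scale_y_continuous(breaks = seq_along(SLADL_CLASSES),
                                labels = SLADL_CLASSES) +
    ggplot2::scale_linetype_manual(values = c(true = "solid",
                                              pred = "dashed")) +
    ggplot2::labs(x = "time (s)", y = NULL, linetype = NULL)
}

#' Precision boxplots per class and sensor combination
#'
#' @param records Tidy metrics records ([tidy.sladl_loso()] output, possibly
#'   several combinations bound together).
#' @param measure Measure column to plot.
#' @return A ggplot object.
#' @export
plot_precision <- function(records, measure = "precision") {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$class, y = .data[[measure]],
                               fill = .data$combination)) +
    ggplot2::geom_boxplot(outlier.shape = 1, na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = measure, fill = "combination")
}
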