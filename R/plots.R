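#' Plot a weighted kNN model
#'
#' Observed versus leave-one-out-predicted responses for a continuous
#' model, or a per-class bar chart of leave-one-out accuracy for a
#' classifier.
#'
#' @param object A [wknn_fit()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wknn <- function(object, ...) {
  loo <- loo_predict(object)
  if (object$task == "continuous") {
    ggplot2::ggplot(loo, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "Observed response",
                    y = "Leave-one-out predicted response",
                    title = sprintf("Weighted kNN (k = %d, %d descriptors)",
                                    object$k, length(object$descriptors)))
  } else {
    df <- dplyr::summarise(
      dplyr::group_by(loo, class = .data$observed),
      accuracy = mean(.data$observed == .data$predicted), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$accuracy)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = NULL, y = "Leave-one-out recall",
                    title = sprintf("Weighted kNN classifier (k = %d)",
                                    object$k))
  }
}

#' Plot a descriptor-selection result
#'
#' `type = "frequency"` shows per-descriptor GA selection frequencies (final
#' round); `type = "forward"` shows the forward-selection fitness curve with
#' the chosen subset size marked.
#'
#' @param object A [select_descriptors()] result.
#' @param type Which panel to draw.
#' @param top_n How many descriptors to show in the frequency panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qspr_selection <- function(object, type = c("frequency", "forward"),
                                    top_n = 20, ...) {
  type <- match.arg(type)
  if (type == "frequency") {
    freq <- object$trace$frequency
    fcol <- intersect(c("frequency_r2", "frequency"), names(freq))[1]
    df <- head(freq[!is.na(freq[[fcol]]), ], top_n)
    df$descriptor <- factor(df$descriptor, levels = rev(df$descriptor))
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[fcol]], y = .data$descriptor)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "GA selection frequency", y = NULL,
                    title = "Descriptor selection frequencies")
  } else {
    df <- object$curve
    ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$cv_fitness, colour = "CV")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fit_fitness, colour = "fit")) +
      ggplot2::geom_vline(xintercept = length(object$selected),
                          linetype = "dashed") +
      ggplot2::labs(x = "Descriptors included", y = "Fitness",
                    colour = NULL, title = "Forward selection path")
  }
}

#' Plot an applicability-domain assessment
#'
#' Local 5-NN index against leverage for a batch of queries, coloured by the
#' interpretation category, with the global `3p/n` threshold and the 0.4 /
#' 0.6 local bands marked.
#'
#' @param assessment A tibble from [assess_ad()].
#' @param ad The [fit_ad()] object (for the leverage threshold line).
#' @return A ggplot object.
#' @export
plot_ad_assessment <- function(assessment, ad = NULL) {
  p <- ggplot2::ggplot(assessment,
                       ggplot2::aes(x = .data$leverage,
                                    y = .data$local_ad_index,
                                    colour = .data$interpretation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(0.4, 0.6), linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Leverage", y = "Local AD index",
                  title = "Two-tier applicability domain")
  if (!is.null(ad)) {
    p <- p + ggplot2::geom_vline(xintercept = ad$threshold,
                                 linetype = "dashed")
  }
  p
}
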