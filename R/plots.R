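# ggplot2 displays for the package's result objects

#' Radial emotion z-score display ("emotional flower" data)
#'
#' Plots a z-score profile as petal-shaped bars on a polar layout, with the
#' |z| = 1.96 rejection ring marked; emotions whose z is undefined are
#' dropped from the display.
#'
#' @param object A [`zscore_profile`][profile_zscores].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.zscore_profile <- function(object, ...) {
  df <- as_tibble(object) %>% filter(.data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emotion, y = .data$z,
                                   fill = .data$significant)) +
    ggplot2::geom_col(width = 0.9, alpha = 0.85) +
    ggplot2::geom_hline(yintercept = 1.96, linetype = "dashed") +
    ggplot2::coord_polar() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#7f8c8d"),
                               guide = "none") +
    ggplot2::labs(y = "z-score vs resampled baseline", x = NULL,
                  title = "Emotion profile against random word samples")
}

#' Null-ensemble distribution with the observed value
#'
#' Histogram of the ensemble's complexity values (network level) or
#' iteration-median entropies (list level), with the observed statistic as
#' a dashed vertical line.
#'
#' @param object A [`null_ensemble`][network_null].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.null_ensemble <- function(object, ...) {
  if (object$level == "network") {
    df <- tibble(value = object$samples$c_r)
    obs <- object$observed$c
    lab <- "emotional complexity c"
  } else {
    df <- tibble(value = object$iteration_summary$median_h)
    obs <- median(object$observed$h)
    lab <- "median entropy (bits)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2c3e50", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = obs, linetype = "dashed",
                        color = "#c0392b") +
    ggplot2::labs(
      x = lab, y = "iterations",
      title = sprintf("%s null model (%d iterations)",
                      object$model, object$n_iter)
    )
}

#' Triangle census by valence signature
#'
#' Bar chart of the 10 triad signatures, colored by coherence.
#'
#' @param object A [`triad_census_affect`][triad_census].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.triad_census_affect <- function(object, ...) {
  df <- as_tibble(object$counts)
  df$signature <- factor(df$signature, levels = all_triad_signatures())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$n,
                                   fill = .data$coherent)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#27ae60", `FALSE` = "#c0392b"),
      labels = c(`TRUE` = "coherent", `FALSE` = "incoherent"),
      name = NULL
    ) +
    ggplot2::labs(x = "triad valence signature", y = "triangles",
                  title = sprintf("Triad census (c = %s)",
                                  if (object$defined)
                                    sprintf("%.3f", object$c)
                                  else "undefined"))
}
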