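#' Plot a cohort's daily adherence raster
#'
#' One tile per participant-day, filled by adherence status, with the
#' train/test split marked.  Useful for eyeballing the weekly structure and
#' the late-phase drift toward non-adherence that the generator emulates.
#'
#' @param object An `adherence_cohort` tibble.
#' @param rule A [label_rule()] used to binarize play time.
#' @param train_days Day of the split line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adherence_cohort <- function(object, rule = label_rule(),
                                      train_days = 30, ...) {
  df <- mutate(object,
               adherent = factor(binarize_adherence(.data$play_seconds, rule),
                                 levels = c(0, 1),
                                 labels = c("non-adherent", "adherent")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$participant_id,
                                   fill = .data$adherent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = train_days + 0.5, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c("non-adherent" = "grey85",
                                          "adherent" = "steelblue4")) +
    ggplot2::labs(x = "day", y = NULL, fill = NULL,
                  title = "Daily adherence by participant",
                  subtitle = "dashed line: train/test split") +
    ggplot2::theme_minimal()
}

#' Plot the training-loss history of a fitted model
#'
#' @param object A trained `adherence_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adherence_model <- function(object, ...) {
  if (!object$trained) abort("model has no training history yet")
  df <- tibble(epoch = seq_along(object$history), loss = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = sprintf("%s training loss", object$spec$family)) +
    ggplot2::theme_minimal()
}

#' Plot the macro-metric comparison grid of an experiment
#'
#' One panel per metric, techniques on the x axis, one line per model
#' family — the comparison view of the augmentation-technique study.
#'
#' @param object An `experiment_result`.
#' @param metrics Which metrics to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object,
                                       metrics = c("precision", "recall",
                                                   "f1", "auc", "accuracy"),
                                       ...) {
  df <- object$grid |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    mutate(technique = factor(.data$technique,
                              levels = augmentation_techniques))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$technique, y = .data$value,
                                   colour = .data$family,
                                   group = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = NULL, y = "macro average", colour = "model",
                  title = "Augmentation technique comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Histogram of estimated per-participant window sizes
#'
#' @param windows Output of [estimate_window_sizes()].
#' @return A ggplot object.
#' @export
plot_window_sizes <- function(windows) {
  ggplot2::ggplot(windows, ggplot2::aes(x = factor(.data$window_size),
                                        fill = .data$is_fallback)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "window size (days)", y = "participants",
                  fill = "fallback",
                  title = "Estimated lookback windows") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
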