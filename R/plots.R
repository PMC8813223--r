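# ggplot2 views of the pipeline's result objects.

#' Plot training history of a fitted pipeline
#'
#' Training loss and train/validation accuracy per epoch.
#'
#' @param object An `ortho_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ortho_pipeline <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-patient integrity findings
#'
#' Duplicate and missing slot counts per patient; complete cases sit at zero.
#'
#' @param object An `integrity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.integrity_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_patient[, c("patient_id", "duplicates", "missing")],
                              -"patient_id", names_to = "finding", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient_id, y = .data$count,
                                     fill = .data$finding)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "patient", y = "slots", title = "Case integrity findings") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Plot per-class accuracy of a classification run
#'
#' @param object An `ortho_classification` with ground truth.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ortho_classification <- function(object, ...) {
  res <- object$results
  df <- res |>
    dplyr::count(.data$category, correct = .data$predicted_category == .data$category) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(accuracy = sum(.data$n[.data$correct]) / sum(.data$n))
  df$category <- factor(df$category, levels = ortho_categories())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy", title = "Per-category accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
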