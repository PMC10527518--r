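# ggplot2 views of the pipeline's result objects.

#' Bar chart of the most-scored features
#'
#' Cumulative Mann-Whitney selection counts over the feature-selection
#' MCCV rounds, highest first.
#'
#' @param board A `scoreboard` from [run_fs_mccv()].
#' @param top_n Number of features to show; default 20.
#' @return A ggplot object.
#' @export
plot_scoreboard <- function(board, top_n = 20) {
  b <- head(tidy(board), top_n)
  ggplot2::ggplot(b, ggplot2::aes(x = stats::reorder(.data$feature, .data$score),
                                  y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("cumulative score (rounds selected, of ",
                                       b$rounds[1], ")"),
                  title = "Most scored features across MCCV rounds") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scoreboard <- function(object, ...) plot_scoreboard(object, ...)

#' Tuning curve: mean validation F1 against k
#'
#' One line per reduction technique and component count, as produced by
#' the paired tuning MCCV.
#'
#' @param tuning A `tuning_result` from [tune_model()].
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(tuning) {
  curve <- tidy(tuning)
  curve$setting <- paste0(toupper(curve$reduction), " (d = ", curve$d, ")")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$mean_f1,
                                      colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of neighbours k",
                  y = "mean validation F1 (minority class)",
                  colour = NULL, title = "Model parameter optimization") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tuning_result <- function(object, ...) plot_tuning_curve(object, ...)

#' Component-space view of a trained kNN model
#'
#' Plots the model's reference points in the first two components,
#' coloured by class; optional query patients are overlaid as stars, which
#' makes the neighbour-vote classification directly inspectable.
#'
#' @param model A `knn_model` from [train_model()].
#' @param newdata Optional cohort rows to project and overlay.
#' @return A ggplot object.
#' @export
plot_component_space <- function(model, newdata = NULL) {
  refs <- tibble::tibble(
    C1 = model$ref[, 1],
    C2 = if (ncol(model$ref) >= 2) model$ref[, 2] else 0,
    class = ifelse(model$ref_labels == 1, "malignant", "benign")
  )
  g <- ggplot2::ggplot(refs, ggplot2::aes(x = .data$C1, y = .data$C2,
                                          colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(malignant = "firebrick",
                                            benign = "dodgerblue3")) +
    ggplot2::labs(x = "component 1", y = "component 2", colour = NULL,
                  title = "Patients in reduced component space") +
    ggplot2::theme_minimal()
  if (!is.null(newdata)) {
    z <- apply_standardizer(model$standardizer, newdata)
    q <- predict(model$reduction, z[model$signature])
    qd <- tibble::tibble(C1 = q[, 1],
                         C2 = if (ncol(q) >= 2) q[, 2] else 0)
    g <- g + ggplot2::geom_point(data = qd, colour = "black", shape = 8,
                                 size = 3)
  }
  g
}

#' @export
autoplot.knn_model <- function(object, ...) plot_component_space(object, ...)
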