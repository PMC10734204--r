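# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `cdn_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold and one column per metric.
#' @method tidy cdn_cv
#' @export
tidy.cdn_cv <- function(x, ...) x$metrics

#' One-row cross-validation summary (fold means)
#'
#' @param x A `cdn_cv`.
#' @param ... Unused.
#' @return One-row tibble of mean metrics plus the fold count.
#' @method glance cdn_cv
#' @export
glance.cdn_cv <- function(x, ...) {
  dplyr::mutate(x$summary, folds = x$split$fold_count)
}

#' Plot per-fold metrics of a cross-validation run
#'
#' Points are per-fold values; the crossbar is the fold mean.
#'
#' @param object A `cdn_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdn_cv
#' @export
autoplot.cdn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    c("auc", "aupr", "f1", "accuracy", "recall", "precision", "specificity"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3, color = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Cross-validation metrics by fold") +
    ggplot2::theme_minimal()
}

#' Tidy a trained model into a pair-score table
#'
#' @param x A `cdn_model`.
#' @param ... Unused.
#' @return Tibble with `circRNA`, `drug`, `score`.
#' @method tidy cdn_model
#' @export
tidy.cdn_model <- function(x, ...) {
  sc <- x$scores
  tibble::tibble(
    circRNA = rep(rownames(sc), times = ncol(sc)),
    drug = rep(colnames(sc), each = nrow(sc)),
    score = as.vector(sc))
}

#' One-row training summary
#'
#' @param x A `cdn_model`.
#' @param ... Unused.
#' @return One-row tibble with epochs, first/final objective and the
#'   alternation length of the final coefficient solve.
#' @method glance cdn_model
#' @export
glance.cdn_model <- function(x, ...) {
  tibble::tibble(epochs = length(x$loss), objective_first = x$loss[1L],
                 objective_final = x$loss[length(x$loss)],
                 alternation_steps = length(x$fit$J) - 1L)
}

#' Plot the training objective trace
#'
#' @param object A `cdn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdn_model
#' @export
autoplot.cdn_model <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss), J = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$J)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "objective J", title = "Training objective") +
    ggplot2::theme_minimal()
}
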