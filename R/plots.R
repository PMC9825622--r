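# ggplot2 visualizations for the main result types.

#' Plot generation quality
#'
#' Bar chart of validity, uniqueness and novelty percentages (and, when the
#' molecules carry an `epoch` column, their trajectory across transfer
#' epochs).
#'
#' @param object A `declm_generation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.declm_generation_report <- function(object, ...) {
  df <- tibble(metric = factor(c("valid", "unique", "novel"),
                               levels = c("valid", "unique", "novel")),
               pct = c(object$pct_valid, object$pct_unique, object$pct_novel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "% of sampled strings",
                  title = sprintf("Generation quality (n = %d)", object$n_sampled)) +
    ggplot2::theme_minimal()
}

#' Plot the training loss trajectory
#'
#' @param object A `declm_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.declm_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Points are the measured responses; the line is the fitted Hill model
#' (slope -1) on a log10 dose axis.
#'
#' @param object A `declm_hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.declm_hill_fit <- function(object, ...) {
  grid <- tibble(dose = exp(seq(log(min(object$data$dose)),
                                log(max(object$data$dose)), length.out = 100)))
  grid$response <- hill_response(grid$dose, object$kd, object$background,
                                 object$signal)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M)", y = "response",
                  title = sprintf("Kd = %.3g nM", object$kd * 1e9)) +
    ggplot2::theme_minimal()
}

#' Vote-confidence curve of a ranked library
#'
#' Number of molecules predicted highly active as a function of the
#' confidence level (minimum number of votes); non-increasing by
#' construction.
#'
#' @param votes Tibble from [ensemble_votes()].
#' @param members Ensemble size M (defaults to the maximum observed votes).
#' @return A ggplot.
#' @export
plot_vote_confidence <- function(votes, members = max(votes$votes)) {
  df <- tibble(confidence = 0:members)
  df$n_molecules <- vapply(df$confidence,
                           function(cf) sum(votes$votes >= cf), numeric(1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$n_molecules)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "confidence level (votes)",
                  y = "molecules predicted highly active") +
    ggplot2::theme_minimal()
}
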