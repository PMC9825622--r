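# broom-style tidiers for fitted objects.

#' Tidy a trained language model's loss history
#'
#' @param x A `declm_model`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @export
tidy.declm_model <- function(x, ...) {
  x$history
}

#' One-row summary of a trained model
#'
#' @param x A `declm_model`.
#' @param ... Unused.
#' @return A tibble with architecture and final-loss columns.
#' @export
glance.declm_model <- function(x, ...) {
  tibble(head = x$head, vocab_size = vocab_size(x$vocab),
         units1 = x$units[1], units2 = x$units[2],
         n_parameters = model_parameter_count(x),
         epochs = nrow(x$history),
         final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_)
}

#' Tidy per-molecule generation results
#'
#' @param x A `declm_generation_report`.
#' @param ... Unused.
#' @return The per-molecule tibble (`smiles`, `valid`, `unique`, `novel`).
#' @export
tidy.declm_generation_report <- function(x, ...) {
  x$molecules
}

#' One-row generation quality summary
#'
#' @param x A `declm_generation_report`.
#' @param ... Unused.
#' @return A tibble `n_sampled, pct_valid, pct_unique, pct_novel`.
#' @export
glance.declm_generation_report <- function(x, ...) {
  tibble(n_sampled = x$n_sampled, pct_valid = x$pct_valid,
         pct_unique = x$pct_unique, pct_novel = x$pct_novel,
         denominator = x$denominator)
}

#' Tidy a Hill dose-response fit
#'
#' @param x A `declm_hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.declm_hill_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' One-row summary of a Hill fit
#'
#' @param x A `declm_hill_fit`.
#' @param ... Unused.
#' @return A tibble `kd, kd_nM, background, signal, rss, n`.
#' @export
glance.declm_hill_fit <- function(x, ...) {
  tibble(kd = x$kd, kd_nM = x$kd * 1e9, background = x$background,
         signal = x$signal, hill_slope = x$hill_slope, rss = x$rss,
         n = nrow(x$data))
}
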