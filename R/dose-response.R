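# Hill-model dose-response fitting for equilibrium binding (Kd estimation).

#' Hill binding response with slope -1
#'
#' `response = background + (signal - background) / (1 + dose / Kd)`; with
#' the Hill slope fixed at -1, `Kd^slope / dose^slope` equals `dose / Kd`.
#' At `dose = Kd` the response is halfway between signal and background; as
#' dose approaches 0 the response approaches `signal`.
#'
#' @param dose Positive dose(s), molar.
#' @param kd Positive dissociation constant, molar.
#' @param background Plateau at saturating dose.
#' @param signal Plateau at zero dose.
#' @return Numeric response(s).
#' @export
hill_response <- function(dose, kd, background = 0, signal = 100) {
  if (any(dose <= 0)) declm_abort("Doses must be positive.", "declm_non_positive_dose")
  stopifnot(kd > 0)
  background + (signal - background) / (1 + dose / kd)
}

#' Simulate an n-point serial-dilution binding curve
#'
#' Mirrors the assay design of an 11-point three-fold serial dilution:
#' doses `top_dose / dilution^(0:(n_points-1))`, responses from
#' [hill_response()] plus optional Gaussian noise scaled to the dynamic
#' range.
#'
#' @param kd True dissociation constant (molar).
#' @param top_dose Highest dose (molar).
#' @param n_points Number of dilution points (default 11).
#' @param dilution Serial dilution factor (default 3).
#' @param background,signal Curve plateaus.
#' @param noise Multiplicative Gaussian noise: each response is scaled by
#'   `1 + N(0, noise)` (e.g. 0.05 for 5% proportional noise, the usual
#'   heteroscedastic model for assay signals).
#' @param seed Seed for the noise draw.
#' @return A tibble `dose, response`.
#' @export
simulate_dose_response <- function(kd, top_dose = 1e-4, n_points = 11L,
                                   dilution = 3, background = 0, signal = 100,
                                   noise = 0, seed = 1L) {
  dose <- top_dose / dilution^(seq_len(n_points) - 1L)
  mu <- hill_response(dose, kd, background, signal)
  resp <- if (noise > 0) {
    withr::with_seed(seed, mu * (1 + rnorm(n_points, 0, noise)))
  } else mu
  tibble(dose = dose, response = resp)
}

#' Fit Kd from dose-response data
#'
#' Unweighted nonlinear least squares with the Levenberg-Marquardt
#' algorithm (`minpack.lm::nlsLM`), Hill slope fixed at -1, estimating
#' `kd`, `background` and `signal`. Starting values follow the standard
#' robust choice: background = min(response), signal = max(response), Kd =
#' the dose nearest the half-range crossing.
#'
#' @param data Data frame with `dose` (molar, positive) and `response`.
#' @param init Optional named list overriding the starting values
#'   (`kd`, `background`, `signal`).
#' @return A `declm_hill_fit` with elements `kd`, `background`, `signal`,
#'   `rss`, `fitted`, `data`.
#' @export
fit_kd <- function(data, init = NULL) {
  stopifnot(is.data.frame(data), all(c("dose", "response") %in% names(data)))
  dose <- data$dose; response <- data$response
  if (length(dose) < 4L) {
    declm_abort("Need at least 4 dose points spanning the transition.",
                "declm_insufficient_data")
  }
  if (any(dose <= 0)) declm_abort("Doses must be positive.", "declm_non_positive_dose")
  if (sd(response) == 0) {
    declm_abort("Constant responses: Kd is unidentifiable.", "declm_fit_diverged")
  }
  half <- (min(response) + max(response)) / 2
  start <- list(kd = dose[which.min(abs(response - half))],
                background = min(response),
                signal = max(response))
  if (!is.null(init)) start[names(init)] <- init
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ background + (signal - background) / (1 + dose / kd),
      data = data.frame(dose = dose, response = response),
      start = start,
      lower = c(kd = .Machine$double.xmin, background = -Inf, signal = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) declm_abort(paste("Hill fit failed:", conditionMessage(e)),
                                    "declm_fit_diverged"))
  cf <- coef(fit)
  structure(list(kd = unname(cf["kd"]),
                 background = unname(cf["background"]),
                 signal = unname(cf["signal"]),
                 hill_slope = -1,
                 rss = sum(resid(fit)^2),
                 fitted = stats::fitted(fit),
                 data = tibble(dose = dose, response = response),
                 fit = fit),
            class = "declm_hill_fit")
}

#' @export
print.declm_hill_fit <- function(x, ...) {
  cat(sprintf("<Hill fit (slope -1)> Kd = %.4g M (%.3g nM), background = %.3g, signal = %.3g, RSS = %.3g\n",
              x$kd, x$kd * 1e9, x$background, x$signal, x$rss))
  invisible(x)
}
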