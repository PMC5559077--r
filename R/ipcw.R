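# Inverse-probability-of-censoring weighting for age-at-onset outcomes.
#
# The censoring survival function is estimated by Kaplan-Meier with the
# roles of event and censoring reversed, via survival::survfit. Weights are
# W_i = delta_i / Sc(Y_i-): evaluation uses the left limit so an event does
# not use censoring information occurring at its own time (ties resolved
# event-first, the standard IPCW convention).

#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimator treating censorings (`event == 0`) as the events
#' and true events as censored observations.
#'
#' @param y Observed (log-scale) times.
#' @param event 0/1 event indicators (`1` = true event, `0` = censored).
#' @return A `censoring_survfit`: step-function knots `time` (censoring
#'   event times) and `surv` values, evaluated with
#'   [eval_censoring_survival()].
#' @export
km_censoring_survival <- function(y, event) {
  stopifnot(length(y) > 0, length(y) == length(event))
  if (any(!is.finite(y))) stop("times must be finite", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(y, 1 - event) ~ 1)
  drop <- fit$n.event > 0
  structure(list(time = fit$time[drop], surv = fit$surv[drop]),
            class = "censoring_survfit")
}

#' Evaluate a censoring survival step function
#'
#' @param sc A `censoring_survfit`.
#' @param t Times at which to evaluate.
#' @param left Use the left limit `Sc(t-)` (the IPCW convention); with
#'   `left = FALSE` the right-continuous value `Sc(t)` is returned.
#' @return Numeric vector of survival probabilities.
#' @export
eval_censoring_survival <- function(sc, t, left = TRUE) {
  if (!length(sc$time)) return(rep(1, length(t)))
  # index of the last knot < t (left) or <= t (right-continuous)
  idx <- findInterval(t, sc$time, left.open = left)
  c(1, sc$surv)[idx + 1L]
}

#' IPCW weights and their summary statistics
#'
#' Computes `W_i = delta_i / Sc(Y_i-)`, so censored observations get weight
#' zero and events are up-weighted by the inverse probability of remaining
#' uncensored just before their event time.
#'
#' @param y Observed (log-scale) times.
#' @param event 0/1 event indicators.
#' @return An `ipcw_weights` object: `weights`, the `censoring_survival`
#'   step function, `v1` (sum of weights), `v2` (sum of squared weights)
#'   and the weighted mean outcome `y_bar_w`.
#' @export
ipcw_weights <- function(y, event) {
  if (sum(event) < 1) stop("all observations censored", call. = FALSE)
  sc <- km_censoring_survival(y, event)
  s_at <- eval_censoring_survival(sc, y, left = TRUE)
  if (any(event == 1 & s_at <= 0)) {
    stop("infinite IPCW weight: censoring survival reaches 0 before an event",
         call. = FALSE)
  }
  w <- ifelse(event == 1, 1 / s_at, 0)
  v1 <- sum(w)
  if (v1 <= 0) stop("all observations censored (zero total weight)",
                    call. = FALSE)
  structure(list(weights = w, censoring_survival = sc,
                 v1 = v1, v2 = sum(w^2), y_bar_w = sum(w * y) / v1),
            class = "ipcw_weights")
}

#' IPCW-weighted outcome variance
#'
#' Estimates the variance of the uncensored (log-scale) outcome as
#' `V1 * sum_i W_i (Y_i - Ybar_w)^2 / (V1^2 - V2)`, which reduces to the
#' usual `n - 1` sample variance when all weights equal one.
#'
#' @param w An [ipcw_weights()] object (or any list with `weights`, `v1`,
#'   `v2`, `y_bar_w`).
#' @param y Observed (log-scale) times used to build `w`.
#' @return The weighted variance estimate.
#' @export
weighted_outcome_variance <- function(w, y) {
  stopifnot(length(y) == length(w$weights))
  if (!(w$v1 > 0) || !(w$v1^2 > w$v2)) {
    stop("degenerate IPCW weights: need V1 > 0 and V1^2 > V2", call. = FALSE)
  }
  w$v1 * sum(w$weights * (y - w$y_bar_w)^2) / (w$v1^2 - w$v2)
}
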