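#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] exposing the survival step
#' function at event times. Censorings tied with an event time are handled
#' with the standard events-before-censorings convention.
#'
#' @param times Observed times in months (non-negative).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `km_curve`: list with `times` (strictly increasing event times),
#'   `survival` (right-continuous S at those times), `at_risk`, `n_event`,
#'   `n`, `obs_max` (largest observed time) and `tail` (S at `obs_max`).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0,
            all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none", se.fit = FALSE)
  ev <- fit$n.event > 0
  curve <- list(times = fit$time[ev],
                survival = fit$surv[ev],
                at_risk = fit$n.risk[ev],
                n_event = fit$n.event[ev],
                n = length(times),
                obs_max = max(times))
  curve$tail <- if (length(curve$times)) curve$survival[length(curve$survival)] else 1
  # S at obs_max: last event <= obs_max always, so tail is S(obs_max)
  class(curve) <- "km_curve"
  curve
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; times beyond the last event
#' take the last step value, S(0) = 1.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Numeric vector of times (months, >= 0).
#' @return Survival proportions at `t`.
#' @export
survival_rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  if (length(curve$times) == 0L) return(rep(1, length(t)))
  sf <- stats::stepfun(curve$times, c(1, curve$survival), right = FALSE)
  sf(t)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Applies the product-limit estimator with the censoring indicator treated
#' as the event, and returns the smallest time at which the resulting curve
#' drops to 0.5 or below. Returns `NA` when the curve never reaches 0.5
#' (e.g. no censored observations).
#'
#' @inheritParams km_estimate
#' @return Median follow-up in months, or `NA_real_`.
#' @export
reverse_km_median_followup <- function(times, events) {
  rk <- km_estimate(times, 1 - events)
  hit <- which(rk$survival <= 0.5)
  if (length(hit) == 0L) return(NA_real_)
  rk$times[hit[1]]
}

# Raw (unsymmetrized) KM plug-in estimate of P(X_i < X_j):
# sum over event times t of i up to tau of dF_i(t) * [S_j(t) + dF_j(t)/2],
# plus a half split of the joint residual KM mass beyond
# tau = min(largest observed time in i, in j).
.mw_raw <- function(km_i, km_j) {
  tau <- min(km_i$obs_max, km_j$obs_max)
  tail_i <- survival_rate_at(km_i, tau)
  tail_j <- survival_rate_at(km_j, tau)
  keep <- km_i$times <= tau
  acc <- 0
  if (any(keep)) {
    t_i <- km_i$times[keep]
    s_i <- km_i$survival[keep]
    s_i_prev <- c(1, km_i$survival)[which(keep)]
    dF_i <- s_i_prev - s_i
    s_j <- survival_rate_at(km_j, t_i)
    dF_j <- numeric(length(t_i))
    hit <- match(t_i, km_j$times)
    has <- !is.na(hit)
    if (any(has)) {
      s_j_prev <- c(1, km_j$survival)[hit[has]]
      dF_j[has] <- s_j_prev - km_j$survival[hit[has]]
    }
    acc <- sum(dF_i * (s_j + dF_j / 2))
  }
  list(theta = acc + 0.5 * tail_i * tail_j, tau = tau,
       tail_i = tail_i, tail_j = tail_j)
}

#' Mann-Whitney parameter between two censored cohorts
#'
#' Estimates theta = P(a survival time drawn from cohort i is shorter than
#' one drawn from cohort j) by Kaplan-Meier plug-in: the integral of S_j
#' against dF_i over the event grid up to the shorter cohort's follow-up
#' limit, with half weight on ties and on the joint residual mass beyond the
#' limit. The estimate is symmetrized by averaging `theta_hat(i,j)` with
#' `1 - theta_hat(j,i)`, so that `theta(i,j) + theta(j,i) = 1` exactly. On
#' fully uncensored data it equals the classical Mann-Whitney count
#' `U/(n m)` with half weight for ties.
#'
#' @param times_i,events_i Observed months and event indicators, cohort i.
#' @param times_j,events_j Observed months and event indicators, cohort j.
#' @return An `mw_estimate`: list with `theta` (symmetrized, in `[0,1]`),
#'   `tau` (truncation time), `tail_i`, `tail_j` (KM mass beyond `tau`) and
#'   the raw directed estimates.
#' @export
mann_whitney_parameter <- function(times_i, events_i, times_j, events_j) {
  km_i <- km_estimate(times_i, events_i)
  km_j <- km_estimate(times_j, events_j)
  if (sum(events_i) == 0 || sum(events_j) == 0) {
    warning("a cohort has no events; Mann-Whitney estimate rests on the censoring tail only",
            call. = FALSE)
  }
  .mw_from_curves(km_i, km_j)
}

.mw_from_curves <- function(km_i, km_j) {
  raw_ij <- .mw_raw(km_i, km_j)
  raw_ji <- .mw_raw(km_j, km_i)
  structure(list(theta = (raw_ij$theta + 1 - raw_ji$theta) / 2,
                 tau = raw_ij$tau,
                 tail_i = raw_ij$tail_i,
                 tail_j = raw_ij$tail_j,
                 theta_raw_ij = raw_ij$theta,
                 theta_raw_ji = raw_ji$theta),
            class = "mw_estimate")
}

#' Initial dissimilarity from a Mann-Whitney parameter
#'
#' `d = 2 |theta - 0.5|`: zero iff the two cohorts' survival distributions
#' are indistinguishable under theta, one at complete separation; symmetric
#' in the cohort pair because theta is symmetrized.
#'
#' @param theta Mann-Whitney parameter(s) in `[0, 1]`.
#' @return Dissimilarities in `[0, 1]`.
#' @export
initial_dissimilarity <- function(theta) {
  stopifnot(all(theta >= 0 & theta <= 1))
  2 * abs(theta - 0.5)
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable patients, the one with the higher
#' risk score dies earlier. Comparable (permissible) pairs anchor on a
#' death at time t with the other patient either surviving past t or
#' censored at t; tied risk scores count one half. Computed by
#' [survival::concordance()] with `reverse = TRUE` (higher score = higher
#' risk), which implements exactly these conventions.
#'
#' @param risk_scores Numeric risk scores, higher = worse prognosis.
#' @param times Observed months.
#' @param events Event indicators (1 = death).
#' @return The concordance index in `[0, 1]`.
#' @export
harrell_c_index <- function(risk_scores, times, events) {
  stopifnot(length(risk_scores) == length(times), length(times) == length(events))
  fit <- survival::concordance(survival::Surv(times, events) ~ risk_scores,
                               reverse = TRUE)
  cnt <- fit$count
  if (sum(cnt[c("concordant", "discordant", "tied.x")]) == 0) {
    stop("no permissible pairs for the concordance index", call. = FALSE)
  }
  as.numeric(fit$concordance)
}

#' Export a Kaplan-Meier curve as a data frame
#'
#' @param curve A `km_curve`.
#' @return Data frame with columns `time`, `survival`, `at_risk`, `n_events`.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$times, survival = x$survival,
             at_risk = x$at_risk, n_events = x$n_event)
}
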