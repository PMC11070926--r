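## Actuarial (product-limit) response rates with effective sample sizes.
## Incomplete follow-up is handled by treating excluded animals as censored
## at their last observation day; the effective sample size
## n_eff = p(1-p)/Var(p) then carries the same binomial information as the
## censoring-adjusted estimate, so the logistic regression can consume
## fractional "responders out of animals" counts.

#' Actuarial response probability for one dose group
#'
#' Product-limit estimate of the cumulative endpoint incidence by the
#' horizon. Responders contribute events at their latency day, excluded
#' animals are censored at their follow-up day, non-responders are at risk
#' through the horizon. Variance by Greenwood's formula; ties between an
#' event and a censoring day put the event first (standard convention).
#' Animals excluded on day 0 are dropped. When the estimate is 0 or 1 the
#' Greenwood variance vanishes and `n_eff` falls back to the crude count.
#'
#' @param records `animal_cohort` rows sharing one dose/schedule/quality
#' @param horizon follow-up horizon in days (default 300)
#' @return one-row data.frame (`dose_group_summary`): `n_crude`,
#'   `p_actuarial`, `var_p`, `n_eff`, `r_eff` plus the group keys
#' @export
#' @examples
#' d <- cohort_design("O16", 98, 120, 1L, 13.5)
#' tr <- response_params(13.5, 1.5)
#' actuarial_rate(simulate_cohort(d, tr, seed = 2))
actuarial_rate <- function(records, horizon = 300) {
  check_number(horizon, "horizon", 0, strict = TRUE)
  if (nrow(records) == 0L)
    stop_ionrbe("empty dose group", "ionrbe_empty_group")
  for (key in c("radiation_label", "let_value", "n_fractions", "total_dose"))
    if (length(unique(records[[key]])) != 1L)
      stop_ionrbe(sprintf("records mix values of `%s`", key),
                  "ionrbe_mixed_group")
  if (any(records$followup_day > horizon + 1e-9))
    stop_ionrbe("followup_day beyond horizon", "ionrbe_bad_argument")

  records <- records[!(records$excluded & records$followup_day <= 0), ,
                     drop = FALSE]
  n <- nrow(records)
  if (n == 0L) stop_ionrbe("no animals at risk", "ionrbe_empty_group")

  time <- ifelse(records$responder, records$event_day,
                 ifelse(records$excluded, records$followup_day, horizon))
  status <- as.integer(records$responder)

  if (all(status == 0L) || !any(records$excluded)) {
    # no events, or no censoring: crude binomial summary (exact reduction)
    p <- mean(status)
    v <- p * (1 - p) / n
  } else {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                             conf.type = "none")
    s <- summary(fit, times = horizon, extend = TRUE)
    p <- 1 - s$surv
    v <- if (is.na(s$std.err)) 0 else s$std.err^2   # Greenwood, SE of S
  }
  n_eff <- if (p > 0 && p < 1 && v > 0) p * (1 - p) / v else n
  data.frame(radiation_label = records$radiation_label[1L],
             let_value = records$let_value[1L],
             n_fractions = records$n_fractions[1L],
             total_dose = records$total_dose[1L],
             n_crude = n, p_actuarial = p, var_p = v,
             n_eff = n_eff, r_eff = n_eff * p,
             stringsAsFactors = FALSE)
}

#' Actuarial summaries for every dose group in a cohort table
#'
#' Splits records by (radiation quality, LET, schedule, total dose) and
#' applies [actuarial_rate()] to each group.
#'
#' @inheritParams actuarial_rate
#' @return data.frame of `dose_group_summary` rows, ordered by group keys
#' @export
summarize_dose_groups <- function(records, horizon = 300) {
  key <- interaction(records$radiation_label, records$let_value,
                     records$n_fractions, records$total_dose, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), actuarial_rate,
                               horizon = horizon))
  out <- out[order(out$radiation_label, out$let_value, out$n_fractions,
                   out$total_dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}
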