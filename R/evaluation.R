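#' Harrell's concordance for censored survival data
#'
#' A pair of patients is usable when the ordering of their event times is
#' determinable under censoring: the patient with the strictly shorter
#' follow-up time had an event. A usable pair is concordant when that patient
#' also has the strictly higher risk score; score ties contribute 1/2.
#' Tied follow-up times are not usable.
#'
#' @param score Risk scores, oriented so larger means higher event risk.
#' @param time Follow-up times (> 0).
#' @param event Event indicators (0/1).
#' @return List of class `concordance_result`: `c` (the statistic),
#'   `concordant`, `discordant`, `tied_score`, `usable` pair counts.
#' @export
#' @examples
#' harrell_c(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1))$c   # 1
harrell_c <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event),
            all(time > 0))
  n <- length(score)
  dt <- outer(time, time, `<`)                     # i strictly earlier than j
  usable <- dt & matrix(event == 1, n, n)          # ... and i had an event
  ds <- outer(score, score, `-`)
  concordant <- sum(usable & ds > 0)
  discordant <- sum(usable & ds < 0)
  tied <- sum(usable & ds == 0)
  total <- concordant + discordant + tied
  if (total == 0) stop("no usable pairs")
  structure(
    list(c = (concordant + 0.5 * tied) / total,
         concordant = concordant, discordant = discordant,
         tied_score = tied, usable = total),
    class = "concordance_result"
  )
}

#' Kaplan-Meier estimator as a step function
#'
#' Thin wrapper over [survival::survfit()] returning the product-limit
#' estimate with an evaluator for arbitrary times.
#'
#' @param time,event Follow-up times and event indicators.
#' @return List of class `km_fit`: `time`, `surv` (step function points) and
#'   `fit` (the survfit object). Use [km_surv_at()] to evaluate.
#' @export
km_estimator <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, fit = fit),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km A [km_estimator()] result.
#' @param t Evaluation time(s).
#' @return Survival probability at `t` (1 before the first observed time;
#'   carried forward beyond the last).
#' @export
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
}

#' Log-rank test across groups
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Group labels (>= 2 groups required).
#' @return List: `statistic` (chi-squared), `df` (groups - 1), `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("log-rank test undefined for a single group")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Tertile risk groups from predicted survival probabilities
#'
#' Splits patients into high / middle / low risk at the empirical tertiles of
#' their predicted recurrence-free survival probability: "high" risk means
#' the lowest predicted RFS. Cut points are reported to 3 decimals on the
#' RFS-probability scale.
#'
#' @param rfs_prob Predicted event-free probabilities in [0, 1].
#' @return List of class `risk_groups`: `group` (factor high/middle/low),
#'   `cutpoints` (the two tertile bounds, rounded to 3 decimals).
#' @export
risk_tertile_groups <- function(rfs_prob) {
  stopifnot(all(rfs_prob >= 0 & rfs_prob <= 1))
  degenerate <- length(unique(rfs_prob)) < 3
  if (degenerate) {
    warning("fewer than 3 distinct predicted probabilities; grouping is degenerate")
  }
  q <- stats::quantile(rfs_prob, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (q[1] == q[2]) {
    grp <- factor(rep("middle", length(rfs_prob)),
                  levels = c("high", "middle", "low"))
  } else {
    grp <- cut(rfs_prob, breaks = c(-Inf, q, Inf),
               labels = c("high", "middle", "low"), right = FALSE)
  }
  structure(list(group = grp, cutpoints = round(q, 3)), class = "risk_groups")
}

#' Calibration table of predicted against observed event risk
#'
#' Partitions patients into quantile groups of predicted risk and compares
#' the mean predicted risk with the Kaplan-Meier complement at the horizon
#' within each group (the KM complement, not the raw event fraction, is the
#' estimable observed risk under censoring).
#'
#' @param risk Predicted event probabilities at `horizon`.
#' @param time,event Follow-up times and event indicators.
#' @param horizon Evaluation time.
#' @param n_groups 5 (quintiles) or 10 (deciles).
#' @return Data frame: `group`, `n`, `mean_predicted`, `observed` (1 - KM at
#'   horizon), `max_followup`, `short_followup` (TRUE when no one in the
#'   group was followed to the horizon — flagged, never dropped).
#' @export
calibration_table <- function(risk, time, event, horizon, n_groups = 5) {
  if (!n_groups %in% c(5, 10)) stop("n_groups must be 5 or 10")
  ranks <- rank(risk, ties.method = "first")
  grp <- ceiling(ranks * n_groups / length(risk))
  rows <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    km <- km_estimator(time[sel], event[sel])
    maxf <- max(time[sel])
    data.frame(group = g, n = sum(sel),
               mean_predicted = mean(risk[sel]),
               observed = 1 - km_surv_at(km, horizon),
               max_followup = maxf,
               short_followup = maxf < horizon)
  })
  do.call(rbind, rows)
}
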