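#' Build the landmark analysis cohort
#'
#' Restricts to patients still event-free and under follow-up at the landmark
#' time s (observed RFS strictly greater than s), restarts the outcome clock
#' at s, and applies administrative censoring at the horizon: events after the
#' horizon are recoded as censored at `horizon - s`.
#'
#' @param outcomes Data frame `patient_id`, `rfs_months`, `event`.
#' @param landmark_month Landmark time s (months).
#' @param horizon_months Prediction horizon (months since surgery), > s.
#' @return Data frame `patient_id`, `residual_time` (months since s, > 0),
#'   `event` (1 if an event occurred in (s, horizon]).
#' @export
#' @examples
#' o <- data.frame(patient_id = 1:3, rfs_months = c(8, 40, 20),
#'                 event = c(1, 0, 1))
#' build_landmark_cohort(o, 12, 36)   # patient 1 excluded
build_landmark_cohort <- function(outcomes, landmark_month = 12,
                                  horizon_months = 36) {
  stopifnot(landmark_month > 0, landmark_month < horizon_months)
  keep <- outcomes$rfs_months > landmark_month
  if (!any(keep)) {
    stop("empty landmark cohort: 0 of ", nrow(outcomes),
         " patients at risk at month ", landmark_month)
  }
  d <- outcomes[keep, ]
  res_time <- pmin(d$rfs_months, horizon_months) - landmark_month
  ev <- as.integer(d$event == 1 & d$rfs_months <= horizon_months)
  data.frame(patient_id = d$patient_id, residual_time = res_time, event = ev)
}

#' Observed biomarker change up to the landmark (landmarking 1.0 predictor)
#'
#' Change in the biomarker from baseline to the last measurement at or before
#' the landmark. With LOCF-imputed series this is always defined; a series
#' holding only the baseline value yields 0 (flagged).
#'
#' @param series Data frame `visit_month`, `value` for one patient and one
#'   biomarker (LOCF-imputed), or a long table with `patient_id` for many.
#' @param landmark_month Landmark time s.
#' @return For a single series, the numeric change (attribute
#'   `baseline_only` flags the degenerate case); for a long table, a data
#'   frame `patient_id`, `change`, `baseline_value`.
#' @export
#' @examples
#' s <- data.frame(visit_month = c(0, 3, 6, 9, 12),
#'                 value = c(50, 49, 47, 46, 44))
#' lm10_change(s, 12)   # -6
lm10_change <- function(series, landmark_month = 12) {
  if ("patient_id" %in% names(series) &&
      length(unique(series$patient_id)) > 1) {
    parts <- split(series, series$patient_id)
    out <- do.call(rbind, lapply(parts, function(d) {
      data.frame(patient_id = d$patient_id[1],
                 change = as.numeric(lm10_change(d, landmark_month)),
                 baseline_value = d$value[d$visit_month == 0][1])
    }))
    rownames(out) <- NULL
    return(out)
  }
  d <- series[order(series$visit_month), ]
  base <- d$value[d$visit_month == 0]
  if (length(base) != 1 || is.na(base)) stop("baseline (month 0) value required")
  upto <- d[d$visit_month <= landmark_month & !is.na(d$value), ]
  if (nrow(upto) == 1) {
    return(structure(0, baseline_only = TRUE))
  }
  utils::tail(upto$value, 1) - base
}

# Closed-form BLUPs b_i = G Z_i' V_i^-1 (y_i - X_i alpha) with
# V_i = Z_i G Z_i' + sigma2 I, for the random-intercept + random-slope model
# with X_i = Z_i = [1, t].
blup_random_effects <- function(data, alpha, G, sigma2) {
  grp <- factor(data$patient_id, levels = unique(data$patient_id))
  idx <- split(seq_len(nrow(data)), grp)
  b <- matrix(0, length(idx), 2)
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    Z <- cbind(1, data$visit_month[i])
    V <- Z %*% G %*% t(Z) + diag(sigma2, length(i))
    b[k, ] <- G %*% crossprod(Z, solve(V, data$value[i] - Z %*% alpha))
  }
  out <- data.frame(patient_id = data$patient_id[vapply(idx, `[`, 0L, 1)],
                    b0 = b[, 1], b1 = b[, 2])
  rownames(out) <- NULL
  out
}

#' Fit the shared linear mixed model for one biomarker up to the landmark
#'
#' Maximum-likelihood fit of a random-intercept + random-slope linear mixed
#' model `value ~ month + (month | patient)` on the observed (non-imputed)
#' measurements at or before the landmark. Variance components come from
#' [lme4::lmer()]; per-patient random effects are then computed by the
#' package's own closed form `b_i = G Z_i' V_i^-1 (y_i - X_i a)` with
#' `V_i = Z_i G Z_i' + s2 I`, so predictions shrink individual trajectories
#' toward the population line in proportion to the residual noise.
#'
#' @param data Long data frame `patient_id`, `visit_month`, `value` (one
#'   biomarker). Rows after the landmark are dropped.
#' @param landmark_month Landmark time s.
#' @return A list of class `trajectory_fit`: `alpha` (fixed intercept and
#'   slope), `G` (2x2 random-effects covariance), `sigma2` (residual
#'   variance), `blups` (per-patient b0, b1), `baseline` (per-patient month-0
#'   value), `singular` (TRUE when a variance component was pinned at the
#'   boundary, in which case BLUPs degrade gracefully toward the population
#'   line), `n_patients`, `landmark_month`.
#' @export
fit_trajectory_model <- function(data, landmark_month = 12) {
  d <- data[data$visit_month <= landmark_month & !is.na(data$value),
            c("patient_id", "visit_month", "value")]
  if (!nrow(d)) stop("no observations at or before the landmark")
  if (max(table(d$patient_id)) < 2) {
    stop("need at least one patient with >= 2 observations")
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ visit_month + (visit_month | patient_id),
               data = d, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  ))
  alpha <- unname(lme4::fixef(fit))
  vc <- lme4::VarCorr(fit)
  G <- unname(as.matrix(vc$patient_id)[1:2, 1:2])
  sigma2 <- attr(vc, "sc")^2
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("variance component at boundary; BLUPs shrink toward the population line")
  }
  base <- d[d$visit_month == 0, c("patient_id", "value")]
  names(base)[2] <- "baseline_value"
  structure(
    list(alpha = alpha, G = G, sigma2 = sigma2,
         blups = blup_random_effects(d, alpha, G, sigma2),
         baseline = base, singular = singular,
         n_patients = length(unique(d$patient_id)),
         landmark_month = landmark_month),
    class = "trajectory_fit"
  )
}

#' BLUP-predicted biomarker at the landmark (landmarking 1.5 predictor)
#'
#' Predicts each patient's biomarker value at the landmark from the mixed
#' model, `yhat_i(s) = (a0 + b0_i) + (a1 + b1_i) s`. By default the value
#' returned is the predicted change `yhat_i(s) - y_i(0)` so that the
#' landmarking 1.0 and 1.5 predictors differ only in how the landmark value
#' is obtained; `type = "level"` returns the predicted level itself.
#'
#' @param fit A [fit_trajectory_model()] result.
#' @param patient_ids Patients to predict for (must appear in the fit).
#' @param type `"change"` (default) or `"level"`.
#' @return Data frame `patient_id`, `predicted` (level at s), and for
#'   `type = "change"` a `change` column (predicted minus observed baseline).
#' @export
lm15_predicted <- function(fit, patient_ids = fit$blups$patient_id,
                           type = c("change", "level")) {
  type <- match.arg(type)
  idx <- match(patient_ids, fit$blups$patient_id)
  if (anyNA(idx)) {
    stop("patient(s) absent from trajectory fit: ",
         paste(patient_ids[is.na(idx)], collapse = ", "))
  }
  s <- fit$landmark_month
  b <- fit$blups[idx, ]
  pred <- (fit$alpha[1] + b$b0) + (fit$alpha[2] + b$b1) * s
  out <- data.frame(patient_id = patient_ids, predicted = pred)
  if (type == "change") {
    bidx <- match(patient_ids, fit$baseline$patient_id)
    if (anyNA(bidx)) {
      stop("no observed baseline value for patient(s): ",
           paste(patient_ids[is.na(bidx)], collapse = ", "))
    }
    out$change <- pred - fit$baseline$baseline_value[bidx]
  }
  out
}
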