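#' Collapse sparse clinical covariate levels
#'
#' Deterministic relabeling used before model fitting: pathological N stages
#' N3a and N3b merge into N3, pT stages T1 and T2 merge into "T1&2", and
#' tumours at the esophagogastric junction are categorized with the upper
#' stomach. All other levels pass through unchanged; unknown levels raise an
#' error naming them. Idempotent.
#'
#' @param baseline Data frame with (any of) `pn_stage`, `pt_stage`,
#'   `location` columns using the standard level vocabulary.
#' @return The data frame with collapsed levels (plain character columns).
#' @export
#' @examples
#' collapse_levels(data.frame(pn_stage = "N3b"))$pn_stage   # "N3"
collapse_levels <- function(baseline) {
  maps <- list(
    pn_stage = list(known = c("N0", "N1", "N2", "N3a", "N3b", "N3"),
                    map = c(N3a = "N3", N3b = "N3")),
    pt_stage = list(known = c("T1", "T2", "T3", "T4a", "T4b", "T1&2"),
                    map = c(T1 = "T1&2", T2 = "T1&2")),
    location = list(known = c("Upper", "Middle", "Lower", "Whole",
                              "Esophagogastric junction"),
                    map = c(`Esophagogastric junction` = "Upper"))
  )
  for (col in intersect(names(maps), names(baseline))) {
    x <- as.character(baseline[[col]])
    unknown <- setdiff(unique(x), maps[[col]]$known)
    if (length(unknown)) {
      stop("unknown ", col, " level(s): ", paste(unknown, collapse = ", "))
    }
    m <- maps[[col]]$map
    hit <- x %in% names(m)
    x[hit] <- m[x[hit]]
    baseline[[col]] <- x
  }
  baseline
}

#' Fit a Cox proportional hazards model with its Breslow baseline hazard
#'
#' Wraps [survival::coxph()] (Efron tie handling by default) and attaches the
#' Breslow estimate of the baseline cumulative hazard on the uncentered
#' covariate scale, so absolute risks at any time are available downstream.
#' With no terms the model is the null model and the baseline cumulative
#' hazard is the Nelson-Aalen estimator of the sample.
#'
#' @param data Data frame holding the outcome and predictor columns.
#' @param terms Character vector of model terms (may include interactions,
#'   e.g. `"age:s1_duration"`); empty for the null model.
#' @param time,event Names of the follow-up time and event indicator columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param on_separation What to do when a monotone partial likelihood
#'   (quasi-complete separation) is suspected, i.e. some `|coef| >
#'   coef_limit`: `"warn"` (default — the coefficient is effectively
#'   infinite, risks for the degenerate level saturate at 0/1, AIC remains
#'   comparable) or `"error"`. Separation arises routinely in resamples when
#'   a rare covariate level carries no events.
#' @param coef_limit Magnitude threshold for the separation guard.
#' @return A list of class `gclm_cox`: `fit` (the coxph object), `coef`,
#'   `terms`, `loglik`, `aic` (`-2 loglik + 2 k`, k = estimated
#'   coefficients), `basehaz` (`time`, `hazard` step function, uncentered),
#'   `n`, `nevent`, `ties`.
#' @export
fit_cox <- function(data, terms = character(0),
                    time = "residual_time", event = "event",
                    ties = c("efron", "breslow"),
                    on_separation = c("warn", "error"), coef_limit = 15) {
  ties <- match.arg(ties)
  on_separation <- match.arg(on_separation)
  if (sum(data[[event]]) < 1) stop("no events in dataset")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(
    paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs)
  )
  for (tm in setdiff(unlist(strsplit(terms, ":", fixed = TRUE)), names(data))) {
    stop("term not found in data: ", tm)
  }
  fit <- suppressWarnings(
    survival::coxph(fml, data = data, ties = ties, x = TRUE, model = TRUE)
  )
  cf <- stats::coef(fit)
  if (length(cf) && anyNA(cf)) {
    stop("rank-deficient design; aliased: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (length(cf) && any(abs(cf) > coef_limit)) {
    msg <- paste0("monotone likelihood suspected (|coef| > ", coef_limit,
                  "): ", paste(names(cf)[abs(cf) > coef_limit], collapse = ", "))
    if (on_separation == "error") stop(msg) else warning(msg)
  }
  ll <- if (length(cf)) fit$loglik[2] else fit$loglik[1]
  k <- length(cf)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(
    list(fit = fit, coef = cf, terms = terms, loglik = ll,
         aic = -2 * ll + 2 * k,
         basehaz = data.frame(time = bh$time, hazard = bh$hazard),
         n = fit$n, nevent = fit$nevent, ties = ties,
         time_col = time, event_col = event),
    class = "gclm_cox"
  )
}

#' @export
print.gclm_cox <- function(x, ...) {
  cat("Cox model (", x$ties, " ties): n = ", x$n, ", events = ", x$nevent,
      ", AIC = ", round(x$aic, 2), "\n", sep = "")
  if (length(x$coef)) print(round(x$coef, 4)) else cat("(null model)\n")
  invisible(x)
}

# Step-function lookup of the cumulative baseline hazard at time t.
basehaz_at <- function(model, t) {
  idx <- findInterval(t, model$basehaz$time)
  ifelse(idx == 0, 0, model$basehaz$hazard[pmax(idx, 1)])
}

#' Absolute event risk from a fitted Cox model
#'
#' Computes `1 - exp(-H0(t) * exp(x'beta))` with H0 the Breslow baseline
#' cumulative hazard (uncentered). Covariates must use the level vocabulary
#' seen at fit time; unseen levels raise an error.
#'
#' @param model A [fit_cox()] result.
#' @param newdata Data frame of covariate profiles.
#' @param t Prediction time (same scale as the fitting time column).
#' @return Numeric vector of event probabilities in [0, 1].
#' @export
predict_risk <- function(model, newdata, t) {
  lp <- if (length(model$coef)) {
    nd <- newdata
    nd[[model$time_col]] <- 1
    nd[[model$event_col]] <- 1
    as.numeric(stats::predict(model$fit, newdata = nd, type = "lp",
                              reference = "zero"))
  } else {
    rep(0, nrow(newdata))
  }
  h0 <- basehaz_at(model, t)
  1 - exp(-h0 * exp(lp))
}

#' Linear risk score from a fitted Cox model
#'
#' The linear predictor `x'beta` (uncentered); monotone in 3-year risk and
#' used for concordance.
#'
#' @inheritParams predict_risk
#' @return Numeric vector.
#' @export
risk_score <- function(model, newdata) {
  if (!length(model$coef)) return(rep(0, nrow(newdata)))
  nd <- newdata
  nd[[model$time_col]] <- 1
  nd[[model$event_col]] <- 1
  as.numeric(stats::predict(model$fit, newdata = nd, type = "lp",
                            reference = "zero"))
}
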