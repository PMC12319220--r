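mandatory_terms <- function() c("lvi", "pt_stage", "pn_stage", "s1_duration")
optional_terms <- function() {
  c("age", "sex", "histology", "surgery", "complications", "age:s1_duration")
}
baseline_excluded_terms <- function() {
  c("s1_duration", "age:s1_duration", "bm_change")
}

# Per-patient, per-biomarker landmark predictors from a LOCF-imputed long
# biomarker table: baseline value and observed change up to the landmark.
biomarker_predictor_table <- function(bm_locf, landmark_month) {
  d <- bm_locf[bm_locf$visit_month <= landmark_month, ]
  d <- d[order(d$biomarker, d$patient_id, d$visit_month), ]
  g <- paste(d$biomarker, d$patient_id, sep = "\r")
  first <- !duplicated(g)
  last <- !duplicated(g, fromLast = TRUE)
  stopifnot(all(d$visit_month[first] == 0))
  data.frame(patient_id = d$patient_id[first], biomarker = d$biomarker[first],
             baseline_value = d$value[first],
             change = d$value[last] - d$value[first],
             stringsAsFactors = FALSE)
}

attach_biomarker <- function(data, biomarker_values, bm,
                             lm15_change = NULL) {
  bv <- biomarker_values[biomarker_values$biomarker == bm, ]
  idx <- match(data$patient_id, bv$patient_id)
  data$bm_baseline <- bv$baseline_value[idx]
  data$bm_change <- bv$change[idx]
  if (!is.null(lm15_change)) {
    j <- match(data$patient_id, lm15_change$patient_id)
    data$bm_change <- lm15_change$change[j]
  }
  data
}

# Fit the three comparison models from one selected term set.
fit_three_models <- function(lm_data, sel_terms, biomarker_values, winner,
                             lm15_change, ties = "efron") {
  d10 <- attach_biomarker(lm_data, biomarker_values, winner)
  d15 <- attach_biomarker(lm_data, biomarker_values, winner, lm15_change)
  base_terms <- setdiff(sel_terms, baseline_excluded_terms())
  list(
    baseline = fit_cox(d10, base_terms, ties = ties),
    lm10 = fit_cox(d10, sel_terms, ties = ties),
    lm15 = fit_cox(d15, sel_terms, ties = ties),
    data10 = d10, data15 = d15, base_terms = base_terms
  )
}

# One full development pass on a landmark dataset: biomarker scan, then the
# trajectory model for the winner, then the three fitted models.
develop_models <- function(lm_data, biomarker_values, bm_series_obs,
                           landmark_month, ties = "efron") {
  scan <- biomarker_scan(lm_data, biomarker_values,
                         mandatory = mandatory_terms(),
                         optional = optional_terms(), ties = ties)
  winner <- scan$winner
  series <- bm_series_obs[bm_series_obs$biomarker == winner, ]
  # group by the dataset's row identity so resampled duplicates stay distinct
  rows <- split(seq_len(nrow(series)), factor(series$patient_id))
  picked <- rows[as.character(lm_data$patient_id)]
  len <- lengths(picked)
  flat <- unlist(picked, use.names = FALSE)
  traj_data <- data.frame(patient_id = rep(seq_along(picked), len),
                          orig_id = rep(lm_data$patient_id, len),
                          visit_month = series$visit_month[flat],
                          value = series$value[flat])
  traj <- suppressWarnings(fit_trajectory_model(traj_data, landmark_month))
  pred <- lm15_predicted(traj)
  lm15_change <- data.frame(
    patient_id = lm_data$patient_id[pred$patient_id],
    change = pred$change
  )
  # resampling can duplicate a patient; predictions per duplicate are equal,
  # so collapse to one row per original id
  lm15_change <- lm15_change[!duplicated(lm15_change$patient_id), ]
  models <- fit_three_models(lm_data, sel_terms = scan$winner_fit$terms,
                             biomarker_values, winner, lm15_change,
                             ties = ties)
  c(models, list(scan = scan, traj = traj, winner = winner,
                 sel_terms = scan$winner_fit$terms,
                 lm15_change = lm15_change))
}

# Covariate levels unseen at fit time (a sparse level missing from a
# bootstrap resample) are scored at the reference level; level definitions
# are taken as given rather than re-derived per resample.
clamp_to_xlevels <- function(model, newdata) {
  xlev <- model$fit$xlevels
  for (col in names(xlev)) {
    if (is.null(newdata[[col]])) next
    v <- as.character(newdata[[col]])
    bad <- !(v %in% xlev[[col]])
    if (any(bad)) {
      v[bad] <- xlev[[col]][1]
      newdata[[col]] <- v
    }
  }
  newdata
}

# Score any dataset with a developed model set (lp scale, higher = riskier).
score_with <- function(dev, which, data, biomarker_values, bm_series_obs,
                       landmark_month) {
  lm15c <- NULL
  if (which == "lm15") {
    series <- bm_series_obs[bm_series_obs$biomarker == dev$winner, ]
    series <- series[series$patient_id %in% data$patient_id, ]
    blups <- blup_random_effects(
      data.frame(patient_id = series$patient_id,
                 visit_month = series$visit_month, value = series$value),
      dev$traj$alpha, dev$traj$G, dev$traj$sigma2)
    s <- landmark_month
    pred_level <- (dev$traj$alpha[1] + blups$b0) +
      (dev$traj$alpha[2] + blups$b1) * s
    bv <- biomarker_values[biomarker_values$biomarker == dev$winner, ]
    base <- bv$baseline_value[match(blups$patient_id, bv$patient_id)]
    lm15c <- data.frame(patient_id = blups$patient_id,
                        change = pred_level - base)
  }
  d <- attach_biomarker(data, biomarker_values, dev$winner, lm15c)
  model <- dev[[which]]
  risk_score(model, clamp_to_xlevels(model, d))
}

#' Run the full dynamic-prediction study pipeline
#'
#' Orchestrates the analysis end to end: load (or simulate) the cohort,
#' derive the fifteen inflammatory biomarkers with LOCF imputation, build the
#' 1-year landmark cohort, scan the biomarker catalog with AIC backward
#' selection, fit the baseline / landmarking 1.0 / landmarking 1.5 Cox
#' models, and compare them (concordance, risk-tertile Kaplan-Meier with
#' log-rank, calibration, NRI), optionally with bootstrap internal validation
#' that replicates the entire development process per resample.
#'
#' @param labs,baseline,outcomes Data frames or CSV paths (long lab table;
#'   baseline covariates; outcomes). Supply either these or `scenario`.
#' @param scenario `"paper-like"` (187 patients, ~25% 3-year event rate) or a
#'   list with elements `config`, `traj`, `hazard` for [generate_cohort()].
#' @param landmark_month,horizon_months Landmark and horizon (months).
#' @param visit_months Scheduled lab visits.
#' @param pni_convention Passed to [biomarker_catalog()].
#' @param nri_cuts Risk-category cut points for the NRI.
#' @param n_calib_groups 5 or 10 calibration groups.
#' @param B Bootstrap replicates for internal validation; 0 skips it.
#' @param seed Integer seed for simulation and resampling.
#' @param ties Cox tie handling.
#' @param out_dir If non-NULL, write biomarkers.csv, landmark.csv,
#'   models.json, report.json and run_manifest.json there.
#' @return A list of class `gclm_report` (see Details in the vignette):
#'   counts, selection table, fitted models, apparent and (if `B > 0`)
#'   optimism-corrected concordances, tertile stratification, calibration,
#'   NRI, and the reproducibility manifest.
#' @export
run_study <- function(labs = NULL, baseline = NULL, outcomes = NULL,
                      scenario = NULL,
                      landmark_month = 12, horizon_months = 36,
                      visit_months = c(0, 3, 6, 9, 12),
                      pni_convention = c("paper", "standard"),
                      nri_cuts = c(0.116, 0.167, 0.36),
                      n_calib_groups = 5,
                      B = 0, seed = 1L, ties = "efron",
                      out_dir = NULL) {
  pni_convention <- match.arg(pni_convention)
  have_data <- !is.null(labs) && !is.null(baseline) && !is.null(outcomes)
  if (have_data == !is.null(scenario)) {
    stop("supply exactly one of {labs+baseline+outcomes} or scenario")
  }
  if (have_data) {
    read_maybe <- function(x) if (is.character(x)) utils::read.csv(x) else x
    labs <- read_maybe(labs); baseline <- read_maybe(baseline)
    outcomes <- read_maybe(outcomes)
  } else {
    if (identical(scenario, "paper-like")) {
      scenario <- list(config = cohort_config(n_patients = 187, seed = seed),
                       traj = default_trajectory_params(),
                       hazard = default_hazard_params())
    }
    scenario$config$seed <- as.integer(seed)
    cohort <- generate_cohort(scenario$config, scenario$traj, scenario$hazard)
    labs <- cohort$labs; baseline <- cohort$baseline
    outcomes <- cohort$outcomes
  }
  baseline <- collapse_levels(baseline)

  counts <- list(n_total = nrow(baseline))
  catalog <- biomarker_catalog(pni_convention)
  bm_obs <- compute_biomarkers(labs, catalog, pni_convention)
  lm_outcomes <- build_landmark_cohort(outcomes, landmark_month, horizon_months)
  counts$n_landmark <- nrow(lm_outcomes)
  counts$n_events_landmark <- sum(lm_outcomes$event)
  counts$n_events_horizon <- sum(outcomes$event == 1 &
                                   outcomes$rfs_months <= horizon_months)

  schedule <- visit_months[visit_months <= landmark_month]
  bm_lm <- bm_obs[bm_obs$patient_id %in% lm_outcomes$patient_id &
                    bm_obs$visit_month <= landmark_month, ]
  bm_locf <- locf_impute(bm_lm, schedule)
  biomarker_values <- biomarker_predictor_table(bm_locf, landmark_month)
  bm_series_obs <- bm_lm  # observed (non-imputed) values feed the mixed model

  lm_data <- merge(lm_outcomes, baseline, by = "patient_id")
  dev <- develop_models(lm_data, biomarker_values, bm_series_obs,
                        landmark_month, ties = ties)

  # time-0 fit of the baseline model on the full cohort (pre-landmark view)
  full <- collapse_levels(baseline)
  full$residual_time <- pmin(outcomes$rfs_months[match(full$patient_id,
                                                       outcomes$patient_id)],
                             horizon_months)
  full$event <- as.integer(outcomes$event[match(full$patient_id,
                                                outcomes$patient_id)] == 1 &
                             outcomes$rfs_months[match(full$patient_id,
                                                       outcomes$patient_id)] <=
                             horizon_months)
  bm_base_all <- compute_biomarkers(labs[labs$visit_month == 0, ],
                                    catalog[catalog$name == dev$winner, ],
                                    pni_convention)
  full$bm_baseline <- bm_base_all$value[match(full$patient_id,
                                              bm_base_all$patient_id)]
  baseline_full <- fit_cox(full, dev$base_terms, ties = ties)

  # ---- model comparison on the landmark cohort ----
  res_hor <- horizon_months - landmark_month
  model_names <- c("baseline", "lm10", "lm15")
  eval_data <- list(baseline = dev$data10, lm10 = dev$data10,
                    lm15 = dev$data15)
  risks <- lapply(model_names, function(m) {
    predict_risk(dev[[m]], eval_data[[m]], res_hor)
  })
  names(risks) <- model_names
  apparent_c <- vapply(model_names, function(m) {
    harrell_c(risks[[m]], lm_data$residual_time, lm_data$event)$c
  }, numeric(1))

  tertiles <- lapply(model_names, function(m) {
    rg <- risk_tertile_groups(1 - risks[[m]])
    lr <- tryCatch(
      logrank_test(lm_data$residual_time, lm_data$event, rg$group),
      error = function(e) list(statistic = NA_real_, df = NA, p = NA_real_))
    list(cutpoints = rg$cutpoints, group = rg$group, logrank_p = lr$p)
  })
  names(tertiles) <- model_names

  calibration <- lapply(model_names, function(m) {
    calibration_table(risks[[m]], lm_data$residual_time, lm_data$event,
                      res_hor, n_calib_groups)
  })
  names(calibration) <- model_names

  rec <- reclassification_table(risks$baseline, risks$lm15, lm_data$event,
                                cuts = nri_cuts)
  nri <- nri_categorical(rec)

  boot <- NULL
  if (B > 0) {
    boot <- internal_validation(lm_data, biomarker_values, bm_series_obs,
                                landmark_month, res_hor, B = B,
                                seed = seed + 7L, ties = ties,
                                apparent_c = apparent_c)
  }

  report <- structure(list(
    counts = counts,
    selection = list(table = dev$scan$table, winner = dev$winner,
                     terms = dev$sel_terms),
    models = list(
      baseline_full = summarize_model(baseline_full),
      baseline = summarize_model(dev$baseline),
      lm10 = summarize_model(dev$lm10),
      lm15 = summarize_model(dev$lm15)
    ),
    fits = list(baseline_full = baseline_full, baseline = dev$baseline,
                lm10 = dev$lm10, lm15 = dev$lm15, traj = dev$traj),
    evaluation = list(
      apparent_c = apparent_c,
      tertiles = lapply(tertiles, function(x) x[c("cutpoints", "logrank_p")]),
      calibration = calibration,
      nri = list(nri = nri$nri, se = nri$se, ci = nri$ci, cuts = nri_cuts,
                 n_events = nri$n_events, n_nonevents = nri$n_nonevents),
      bootstrap = boot
    ),
    manifest = list(
      seed = seed, landmark_month = landmark_month,
      horizon_months = horizon_months, pni_convention = pni_convention,
      ties = ties, B = B, nri_cuts = nri_cuts,
      n_calib_groups = n_calib_groups,
      package_version = as.character(utils::packageVersion("gclandmark")),
      decisions = c(
        "ties: Efron partial-likelihood approximation unless overridden",
        "backward selection: exact AIC-based elimination with refits, marginality honored",
        "selection criterion: AIC within models and across the biomarker scan",
        "landmarking 1.5 predictor: BLUP-predicted change from baseline",
        "mixed model: ML (not REML), linear time, random intercept+slope, observed values only",
        "LOCF only at scheduled visits within follow-up; baseline must be observed",
        "calibration observed risk: Kaplan-Meier complement at the horizon",
        "bootstrap CI: percentile; optimism replicates the full build incl. selection"
      )
    )
  ), class = "gclm_report")

  if (!is.null(out_dir)) {
    write_report_bundle(report, bm_locf, lm_data, out_dir)
  }
  report
}

summarize_model <- function(m) {
  list(terms = m$terms, coef = as.list(m$coef), aic = m$aic,
       loglik = m$loglik, n = m$n, nevent = m$nevent,
       basehaz = list(time = m$basehaz$time, hazard = m$basehaz$hazard))
}

# Single-loop bootstrap internal validation: every replicate reruns the whole
# development (scan, selection, trajectory model, fits); optimism per model
# and a percentile CI for C(lm15) - C(baseline) share the resamples.
internal_validation <- function(lm_data, biomarker_values, bm_series_obs,
                                landmark_month, res_hor, B, seed, ties,
                                apparent_c) {
  set.seed(seed)
  n <- nrow(lm_data)
  idx <- replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  model_names <- c("baseline", "lm10", "lm15")
  c_boot <- c_orig <- matrix(NA_real_, B, 3,
                             dimnames = list(NULL, model_names))
  delta <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    ok <- tryCatch(suppressWarnings({
      d_b <- lm_data[idx[[b]], ]
      rownames(d_b) <- NULL
      dev_b <- develop_models(d_b, biomarker_values, bm_series_obs,
                              landmark_month, ties = ties)
      for (m in model_names) {
        sc_b <- score_with(dev_b, m, d_b, biomarker_values, bm_series_obs,
                           landmark_month)
        sc_o <- score_with(dev_b, m, lm_data, biomarker_values,
                           bm_series_obs, landmark_month)
        c_boot[b, m] <- harrell_c(sc_b, d_b$residual_time, d_b$event)$c
        c_orig[b, m] <- harrell_c(sc_o, lm_data$residual_time,
                                  lm_data$event)$c
      }
      delta[b] <- c_boot[b, "lm15"] - c_boot[b, "baseline"]
      TRUE
    }), error = function(e) FALSE)
  }
  failed <- sum(is.na(delta))
  if (failed > 0.1 * B) {
    stop(failed, " of ", B, " bootstrap replicates failed (> 10%)")
  }
  optimism <- colMeans(c_boot - c_orig, na.rm = TRUE)
  list(B = B, n_failed = failed,
       optimism = optimism,
       corrected_c = apparent_c - optimism,
       delta_c_lm15_baseline_ci = stats::quantile(delta, c(0.025, 0.975),
                                                  na.rm = TRUE, names = FALSE))
}

write_report_bundle <- function(report, bm_locf, lm_data, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(bm_locf, file.path(out_dir, "biomarkers.csv"),
                   row.names = FALSE)
  utils::write.csv(lm_data, file.path(out_dir, "landmark.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  rep_out <- report[c("counts", "selection", "evaluation", "manifest")]
  rep_out$selection$table <- as.list(report$selection$table)
  jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.gclm_report <- function(x, ...) {
  cat("Dynamic recurrence-prediction study\n")
  cat(sprintf("  patients: %d total, %d in landmark cohort (%d events in window)\n",
              x$counts$n_total, x$counts$n_landmark, x$counts$n_events_landmark))
  cat(sprintf("  3-year events (full cohort): %d (%.1f%%)\n",
              x$counts$n_events_horizon,
              100 * x$counts$n_events_horizon / x$counts$n_total))
  cat("  selected biomarker:", x$selection$winner, "\n")
  cat("  retained terms:", paste(x$selection$terms, collapse = ", "), "\n")
  ac <- x$evaluation$apparent_c
  cat(sprintf("  apparent C: baseline %.3f, lm1.0 %.3f, lm1.5 %.3f\n",
              ac["baseline"], ac["lm10"], ac["lm15"]))
  if (!is.null(x$evaluation$bootstrap)) {
    cc <- x$evaluation$bootstrap$corrected_c
    ci <- x$evaluation$bootstrap$delta_c_lm15_baseline_ci
    cat(sprintf("  corrected C (B = %d): baseline %.3f, lm1.0 %.3f, lm1.5 %.3f\n",
                x$evaluation$bootstrap$B, cc["baseline"], cc["lm10"], cc["lm15"]))
    cat(sprintf("  bootstrap 95%% CI for C(lm1.5) - C(baseline): %.3f to %.3f\n",
                ci[1], ci[2]))
  }
  cat(sprintf("  NRI (lm1.5 vs baseline) = %.3f (95%% CI %.3f to %.3f)\n",
              x$evaluation$nri$nri, x$evaluation$nri$ci[1],
              x$evaluation$nri$ci[2]))
  invisible(x)
}
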