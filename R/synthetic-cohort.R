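#' Configuration for a synthetic post-gastrectomy cohort
#'
#' Assembles and validates the design of a simulated cohort: size, visit
#' schedule, follow-up horizon, landmark time, baseline covariate
#' frequencies, exponential loss-to-follow-up rate and the probability that a
#' post-baseline lab visit goes unmeasured. Defaults emulate a stage II-III
#' gastric cancer derivation cohort: labs at surgery and 3, 6, 9, 12 months,
#' administrative censoring at 36 months, landmark at 1 year, and marginal
#' covariate frequencies matching a published derivation set of 187 patients.
#'
#' @param n_patients Number of patients (positive integer).
#' @param visit_months Ordered lab-visit schedule in months; must start at 0.
#' @param horizon_months Administrative censoring time (months).
#' @param landmark_month Landmark time (months); must precede the horizon.
#' @param seed Integer seed controlling all randomness in generation.
#' @param covariate_freqs Named list: per categorical covariate, a named
#'   probability vector over its levels (each summing to 1).
#' @param censor_rate Exponential rate (per month) of random loss to
#'   follow-up, independent of everything else; 0 disables it.
#' @param missing_prob Probability that each post-baseline visit is
#'   unmeasured, in [0, 1).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 187,
                          visit_months = c(0, 3, 6, 9, 12),
                          horizon_months = 36,
                          landmark_month = 12,
                          seed = 1L,
                          covariate_freqs = default_covariate_freqs(),
                          censor_rate = 0.005,
                          missing_prob = 0.1) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1 ||
      n_patients != round(n_patients)) {
    stop("n_patients must be a positive integer")
  }
  stopifnot(
    is.numeric(visit_months), length(visit_months) >= 1,
    !is.unsorted(visit_months, strictly = TRUE),
    visit_months[1] == 0,
    horizon_months > 0,
    landmark_month > 0, landmark_month < horizon_months,
    censor_rate >= 0,
    missing_prob >= 0, missing_prob < 1
  )
  for (nm in names(covariate_freqs)) {
    p <- covariate_freqs[[nm]]
    if (abs(sum(p) - 1) > 1e-9) {
      stop("covariate_freqs[['", nm, "']] must sum to 1")
    }
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop("covariate_freqs[['", nm, "']] must be a named probability vector")
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), visit_months = visit_months,
         horizon_months = horizon_months, landmark_month = landmark_month,
         seed = as.integer(seed), covariate_freqs = covariate_freqs,
         censor_rate = censor_rate, missing_prob = missing_prob),
    class = "cohort_config"
  )
}

#' Default baseline covariate frequencies
#'
#' Marginal frequencies of the categorical baseline covariates in a 187-patient
#' stage II-III gastric cancer derivation cohort (counts over 187).
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_freqs <- function() {
  f <- function(counts) counts / sum(counts)
  list(
    sex = f(c(Male = 129, Female = 58)),
    histology = f(c(Diffuse = 91, Intestinal = 78, Mixed = 18)),
    location = f(c(Upper = 39, Middle = 72, Lower = 64, Whole = 7,
                   `Esophagogastric junction` = 5)),
    surgery = f(c(Distal = 106, Total = 81)),
    pt_stage = f(c(T1 = 6, T2 = 23, T3 = 84, T4a = 69, T4b = 5)),
    pn_stage = f(c(N0 = 41, N1 = 54, N2 = 47, N3a = 33, N3b = 12)),
    lvi = f(c(Absent = 9, Present = 178)),
    complications = f(c(Absent = 120, Present = 67)),
    s1_duration = f(c(`<6 months` = 56, `>=6 months` = 131))
  )
}

#' Linear mixed-effects trajectory parameters for one raw marker
#'
#' Describes the latent trajectory y_ij = (a0 + b0_i) + (a1 + b1_i) t_j + e_ij
#' with subject random intercept/slope (b0_i, b1_i) ~ N(0, G) and residual
#' e_ij ~ N(0, residual_sd^2).
#'
#' @param fixed_intercept,fixed_slope Population intercept (marker units) and
#'   slope (units/month).
#' @param random_intercept_sd,random_slope_sd,random_corr Random-effect SDs
#'   and their correlation; the implied 2x2 covariance must be positive
#'   semidefinite (|random_corr| <= 1).
#' @param residual_sd Measurement-noise SD (>= 0).
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(fixed_intercept, fixed_slope = 0,
                              random_intercept_sd = 0, random_slope_sd = 0,
                              random_corr = 0, residual_sd = 0) {
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  stopifnot(random_intercept_sd >= 0, random_slope_sd >= 0)
  if (abs(random_corr) > 1) stop("random_corr must lie in [-1, 1] (non-PSD G otherwise)")
  structure(
    list(fixed_intercept = fixed_intercept, fixed_slope = fixed_slope,
         random_intercept_sd = random_intercept_sd,
         random_slope_sd = random_slope_sd,
         random_corr = random_corr, residual_sd = residual_sd),
    class = "trajectory_params"
  )
}

#' Default marker trajectory parameters
#'
#' Realistic adult post-gastrectomy values for the six raw markers: stable
#' myeloid counts, a mild population-level decline in albumin and lymphocytes
#' over the first postoperative year (so the derived nutritional indices can
#' carry prognostic signal), and measurement noise of the order of routine
#' laboratory variation.
#'
#' @return Named list of [trajectory_params()], one per raw marker.
#' @export
default_trajectory_params <- function() {
  list(
    monocytes = trajectory_params(400, 0, 90, 4, 0, 60),
    platelets = trajectory_params(250000, -800, 50000, 1500, 0, 20000),
    crp = trajectory_params(0.5, -0.005, 0.25, 0.015, 0, 0.15),
    albumin = trajectory_params(4.0, -0.02, 0.35, 0.025, 0, 0.2),
    neutrophils = trajectory_params(3500, 0, 800, 40, 0, 500),
    lymphocytes = trajectory_params(1500, -10, 320, 18, 0, 220)
  )
}

#' Proportional-hazards parameters of the simulated event process
#'
#' The hazard is piecewise exponential: at time t the rate is
#' `baseline_rate * exp(lp_i(t))` where `lp_i(t)` sums the patient's baseline
#' covariate effects and, per marker, `beta_marker_change[m]` times the true
#' (noise-free) change of marker m since baseline, updated at visit times and
#' held constant between visits and after the last visit.
#'
#' @param baseline_rate Events per month (> 0).
#' @param beta_covariates Named numeric vector; names are
#'   `"covariate:level"` pairs (e.g. `"lvi:Present"`). Unlisted levels have
#'   coefficient 0 (reference levels).
#' @param beta_marker_change Named numeric vector keyed by raw marker name;
#'   log-hazard per unit of true change since baseline. Unlisted markers do
#'   not affect the hazard.
#' @return A list of class `hazard_params`.
#' @export
hazard_params <- function(baseline_rate,
                          beta_covariates = numeric(0),
                          beta_marker_change = numeric(0)) {
  stopifnot(is.numeric(baseline_rate), length(baseline_rate) == 1)
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (!all(is.finite(c(beta_covariates, beta_marker_change)))) {
    stop("hazard coefficients must be finite")
  }
  structure(
    list(baseline_rate = baseline_rate,
         beta_covariates = beta_covariates,
         beta_marker_change = beta_marker_change),
    class = "hazard_params"
  )
}

#' Default hazard parameters of the paper-like scenario
#'
#' Nodal stage, tumour depth, lymphovascular invasion and shortened adjuvant
#' chemotherapy raise the hazard; declines in albumin and lymphocytes (the
#' components of the prognostic nutritional index) raise it further. The
#' baseline rate is calibrated so that, under [default_covariate_freqs()] and
#' [default_trajectory_params()], about 25% of patients have an event within
#' 36 months.
#'
#' @return A `hazard_params` object.
#' @export
default_hazard_params <- function() {
  hazard_params(
    baseline_rate = 0.001,
    beta_covariates = c(
      "lvi:Present" = 0.8,
      "pt_stage:T3" = 0.3, "pt_stage:T4a" = 0.7, "pt_stage:T4b" = 1.0,
      "pn_stage:N1" = 0.2, "pn_stage:N2" = 0.5,
      "pn_stage:N3a" = 0.9, "pn_stage:N3b" = 1.1,
      "s1_duration:<6 months" = 0.4
    ),
    beta_marker_change = c(albumin = -1.0, lymphocytes = -0.0012)
  )
}

# Draw (b0, b1) random effects: n x 2 matrix from N(0, G).
draw_random_effects <- function(n, traj) {
  sds <- c(traj$random_intercept_sd, traj$random_slope_sd)
  G <- diag(sds^2)
  G[1, 2] <- G[2, 1] <- traj$random_corr * sds[1] * sds[2]
  if (all(sds == 0)) return(matrix(0, n, 2))
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-12) stop("random-effects covariance G is not PSD")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  matrix(stats::rnorm(2 * n), n, 2) %*% t(L)
}

#' Simulate one marker's longitudinal series for a set of patients
#'
#' @param n Number of subjects (random effects drawn internally), or a matrix
#'   of pre-drawn random effects via `ranef`.
#' @param traj A [trajectory_params()] object.
#' @param visits Sorted, non-empty visit months.
#' @param ranef Optional n x 2 matrix of (b0, b1); drawn from N(0, G) if NULL.
#' @param floor Lower detection limit: simulated values below it are reported
#'   at the floor (0 lets values of 0 through, as assays do for CRP).
#' @return List with `values` (n x length(visits) matrix of observed values),
#'   `truth` (n x 2 random effects). Values are the linear trajectory plus
#'   residual noise, floored at the detection limit.
#' @export
simulate_marker_series <- function(n, traj, visits, ranef = NULL, floor = 0) {
  stopifnot(length(visits) >= 1, !is.unsorted(visits))
  if (is.null(ranef)) ranef <- draw_random_effects(n, traj)
  mean_mat <- outer(traj$fixed_intercept + ranef[, 1], rep(1, length(visits))) +
    outer(traj$fixed_slope + ranef[, 2], visits)
  noise <- if (traj$residual_sd > 0) {
    matrix(stats::rnorm(n * length(visits), sd = traj$residual_sd), n)
  } else {
    matrix(0, n, length(visits))
  }
  values <- pmax(mean_mat + noise, floor)
  colnames(values) <- as.character(visits)
  list(values = values, truth = ranef)
}

# Piecewise-exponential event times. lp is an n x k matrix of linear
# predictors on the pieces [t_k, t_{k+1}) with the last piece open-ended.
sample_piecewise_event_times <- function(baseline_rate, lp, breaks) {
  n <- nrow(lp)
  k <- ncol(lp)
  stopifnot(length(breaks) == k, breaks[1] == 0)
  rates <- baseline_rate * exp(lp)
  widths <- diff(breaks)
  target <- stats::rexp(n) # cumulative hazard to be reached
  times <- rep(Inf, n)
  cumh <- rep(0, n)
  for (j in seq_len(k)) {
    w <- if (j < k) widths[j] else Inf
    piece_h <- rates[, j] * w
    hit <- is.infinite(times) & (cumh + piece_h >= target)
    times[hit] <- breaks[j] + (target[hit] - cumh[hit]) / rates[hit, j]
    cumh <- cumh + piece_h
  }
  times
}

covariate_lp <- function(baseline, beta_covariates) {
  lp <- rep(0, nrow(baseline))
  for (nm in names(beta_covariates)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(baseline[[parts[1]]])) {
      stop("beta_covariates name not of the form 'covariate:level': ", nm)
    }
    lp <- lp + beta_covariates[[nm]] * (baseline[[parts[1]]] == parts[2])
  }
  lp
}

#' Generate a synthetic cohort with linked biomarker and event processes
#'
#' Draws baseline covariates from the configured marginal frequencies,
#' simulates the six raw-marker trajectories, and samples recurrence-free
#' survival times from a proportional-hazards process whose linear predictor
#' combines covariate effects with the true (noise-free) marker change since
#' baseline, updated at visit times. Censoring is exponential plus
#' administrative at the horizon, independent of everything else. Lab rows
#' after a patient's observed follow-up are dropped; post-baseline visits are
#' then removed completely at random with the configured probability.
#'
#' @param config A [cohort_config()].
#' @param traj Named list of [trajectory_params()], one per raw marker.
#' @param hazard A [hazard_params()].
#' @return A list of class `simulated_cohort`: `baseline` (one row per
#'   patient: id, age and the categorical covariates), `outcomes`
#'   (`patient_id`, `rfs_months`, `event`), `labs` (long format, one row per
#'   retained visit with the six markers), `truth` (per-patient event and
#'   censor times plus per-marker random effects), and `config`.
#' @export
generate_cohort <- function(config,
                            traj = default_trajectory_params(),
                            hazard = default_hazard_params()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(hazard, "hazard_params"))
  missing_traj <- setdiff(raw_marker_names(), names(traj))
  if (length(missing_traj)) {
    stop("trajectory parameters missing for: ", paste(missing_traj, collapse = ", "))
  }
  set.seed(config$seed)
  n <- config$n_patients
  visits <- config$visit_months

  baseline <- data.frame(patient_id = seq_len(n))
  baseline$age <- pmin(pmax(round(stats::rnorm(n, 69, 10)), 25), 86)
  for (nm in names(config$covariate_freqs)) {
    p <- config$covariate_freqs[[nm]]
    baseline[[nm]] <- sample(names(p), n, replace = TRUE, prob = p)
  }

  # counts and albumin have positive assay detection limits; CRP reports 0
  marker_sims <- list()
  for (m in raw_marker_names()) {
    fl <- if (m == "crp") 0 else 0.02 * traj[[m]]$fixed_intercept
    marker_sims[[m]] <- simulate_marker_series(n, traj[[m]], visits, floor = fl)
  }

  # true change since baseline per marker at each visit: (a1 + b1_i) * t
  lp <- matrix(covariate_lp(baseline, hazard$beta_covariates), n, length(visits))
  for (m in names(hazard$beta_marker_change)) {
    if (!m %in% raw_marker_names()) stop("unknown marker in beta_marker_change: ", m)
    slope_i <- traj[[m]]$fixed_slope + marker_sims[[m]]$truth[, 2]
    lp <- lp + hazard$beta_marker_change[[m]] * outer(slope_i, visits)
  }

  event_time <- sample_piecewise_event_times(hazard$baseline_rate, lp, visits)
  censor_time <- if (config$censor_rate > 0) {
    stats::rexp(n, config$censor_rate)
  } else {
    rep(Inf, n)
  }
  rfs <- pmin(event_time, censor_time, config$horizon_months)
  event <- as.integer(event_time <= pmin(censor_time, config$horizon_months))
  outcomes <- data.frame(patient_id = seq_len(n), rfs_months = rfs, event = event)

  labs <- data.frame(
    patient_id = rep(seq_len(n), each = length(visits)),
    visit_month = rep(visits, n)
  )
  for (m in raw_marker_names()) {
    labs[[m]] <- as.vector(t(marker_sims[[m]]$values))
  }
  labs <- labs[labs$visit_month <= rep(rfs, each = length(visits)), ]
  rownames(labs) <- NULL

  truth <- data.frame(patient_id = seq_len(n),
                      event_time = event_time, censor_time = censor_time)
  for (m in raw_marker_names()) {
    truth[[paste0(m, "_b0")]] <- marker_sims[[m]]$truth[, 1]
    truth[[paste0(m, "_b1")]] <- marker_sims[[m]]$truth[, 2]
  }

  cohort <- structure(
    list(baseline = baseline, outcomes = outcomes, labs = labs,
         truth = truth, config = config),
    class = "simulated_cohort"
  )
  apply_missingness(cohort, config$missing_prob,
                    seed = config$seed + 1000003L)
}

#' Remove post-baseline lab visits completely at random
#'
#' Month-0 rows are never removed. Removed visits are recorded in
#' `cohort$removed_visits`.
#'
#' @param cohort A `simulated_cohort`.
#' @param missing_prob Per-visit removal probability in [0, 1).
#' @param seed Integer seed.
#' @return The cohort with thinned `labs`.
#' @export
apply_missingness <- function(cohort, missing_prob, seed = 1L) {
  if (missing_prob >= 1) stop("missing_prob must be < 1")
  if (missing_prob < 0) stop("missing_prob must be >= 0")
  if (missing_prob == 0) {
    cohort$removed_visits <- cohort$labs[0, c("patient_id", "visit_month")]
    return(cohort)
  }
  set.seed(seed)
  eligible <- cohort$labs$visit_month > 0
  drop <- eligible & (stats::runif(nrow(cohort$labs)) < missing_prob)
  cohort$removed_visits <- cohort$labs[drop, c("patient_id", "visit_month")]
  rownames(cohort$removed_visits) <- NULL
  cohort$labs <- cohort$labs[!drop, ]
  rownames(cohort$labs) <- NULL
  cohort
}

#' Write a simulated cohort to CSV files
#'
#' Writes `labs.csv`, `baseline.csv`, `outcomes.csv` and (for tests)
#' `truth.csv` into `dir`.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("labs.csv", "baseline.csv", "outcomes.csv", "truth.csv"))
  utils::write.csv(cohort$labs, paths[1], row.names = FALSE)
  utils::write.csv(cohort$baseline, paths[2], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[3], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[4], row.names = FALSE)
  invisible(paths)
}
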