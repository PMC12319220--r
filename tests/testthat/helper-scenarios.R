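# Shared scenario builders for tests.

quick_config <- function(n = 187, seed = 1L, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

# Hazard driven purely through the prognostic nutritional index: the marker
# coefficients are proportional to PNI's weights (1 on albumin, 0.005 on
# lymphocytes), so the true log-hazard is a multiple of the PNI change.
pni_driven_hazard <- function(strength = 1.5, baseline_rate = 0.004) {
  hazard_params(
    baseline_rate = baseline_rate,
    beta_covariates = numeric(0),
    beta_marker_change = c(albumin = -strength,
                           lymphocytes = -strength * 0.005)
  )
}

# Trajectories with pronounced between-patient slope heterogeneity in the
# PNI components, so post-baseline visits are informative.
pni_driven_traj <- function() {
  tr <- default_trajectory_params()
  tr$albumin <- trajectory_params(4.0, -0.02, 0.35, 0.045, 0, 0.2)
  tr$lymphocytes <- trajectory_params(1500, -10, 320, 30, 0, 220)
  tr
}

# Small complete long series for mixed-model tests.
toy_series <- function(n = 12, seed = 42, alpha = c(10, -0.3),
                       sd_b0 = 1.5, sd_b1 = 0.15, sigma = 0.5,
                       visits = c(0, 3, 6, 9, 12)) {
  set.seed(seed)
  b0 <- rnorm(n, 0, sd_b0)
  b1 <- rnorm(n, 0, sd_b1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = i, visit_month = visits,
               value = alpha[1] + b0[i] + (alpha[2] + b1[i]) * visits +
                 rnorm(length(visits), 0, sigma),
               b0 = b0[i], b1 = b1[i])
  }))
}
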