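test_that("generation is deterministic under a fixed seed", {
  cfg <- quick_config(n = 100, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(a$labs, f1, row.names = FALSE)
  write.csv(b$labs, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$baseline, b$baseline)
})

test_that("config validation rejects impossible designs", {
  expect_error(cohort_config(n_patients = 0), "positive integer")
  expect_error(cohort_config(missing_prob = 1), "missing_prob")
  expect_error(cohort_config(landmark_month = 40), "landmark_month")
  expect_error(cohort_config(covariate_freqs = list(sex = c(Male = 0.6, Female = 0.3))),
               "sum to 1")
  expect_error(trajectory_params(1, residual_sd = -1), "residual_sd")
  expect_error(trajectory_params(1, random_corr = 1.5), "PSD")
  expect_error(hazard_params(0), "baseline_rate")
})

test_that("null-effect cohorts match the exponential closed form", {
  r <- 0.01
  cfg <- quick_config(n = 2000, seed = 5, censor_rate = 0, missing_prob = 0)
  hz <- hazard_params(baseline_rate = r)
  co <- generate_cohort(cfg, hazard = hz)
  p_expected <- 1 - exp(-36 * r)
  se <- sqrt(p_expected * (1 - p_expected) / 2000)
  expect_lt(abs(mean(co$outcomes$event) - p_expected), 3 * se)
})

test_that("default scenario yields roughly a quarter of patients with events by 3 years", {
  co <- generate_cohort(quick_config(n = 4000, seed = 11))
  expect_gt(mean(co$outcomes$event), 0.20)
  expect_lt(mean(co$outcomes$event), 0.30)
})

test_that("covariate marginals track the configured frequencies", {
  cfg <- quick_config(n = 3000, seed = 2)
  co <- generate_cohort(cfg)
  for (nm in names(cfg$covariate_freqs)) {
    p <- cfg$covariate_freqs[[nm]]
    obs <- table(factor(co$baseline[[nm]], levels = names(p))) / 3000
    se <- sqrt(p * (1 - p) / 3000)
    expect_true(all(abs(obs - p) <= 3 * pmax(se, 1e-6)), info = nm)
  }
})

test_that("marker series obey the linear mixed structure", {
  # no randomness: exactly linear
  tr <- trajectory_params(100, -2)
  s <- simulate_marker_series(5, tr, c(0, 3, 6, 9, 12))
  expect_equal(unname(s$values[3, ]), 100 - 2 * c(0, 3, 6, 9, 12))

  # variance at t = 0 over many subjects matches ri_sd^2 + resid_sd^2
  set.seed(31)
  tr2 <- trajectory_params(100, 0, random_intercept_sd = 4,
                           random_slope_sd = 0.5, residual_sd = 3)
  s2 <- simulate_marker_series(10000, tr2, c(0, 6, 12))
  expect_lt(abs(var(s2$values[, 1]) / (16 + 9) - 1), 0.05)

  # negative population slope moves the month-12 mean below month 0
  set.seed(32)
  tr3 <- trajectory_params(100, -1, 2, 0.1, 0, 1)
  s3 <- simulate_marker_series(2000, tr3, c(0, 12))
  expect_lt(mean(s3$values[, 2]), mean(s3$values[, 1]))
})

test_that("missingness is MCAR at the configured rate and spares baseline", {
  cfg <- quick_config(n = 500, seed = 9, missing_prob = 0, censor_rate = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$removed_visits), 0)

  eligible <- sum(co$labs$visit_month > 0)
  thinned <- apply_missingness(co, 0.3, seed = 4)
  frac <- nrow(thinned$removed_visits) / eligible
  se <- sqrt(0.3 * 0.7 / eligible)
  expect_lt(abs(frac - 0.3), 3 * se)

  with_miss <- generate_cohort(quick_config(n = 300, seed = 3, missing_prob = 0.4))
  m0 <- with_miss$labs[with_miss$labs$visit_month == 0, ]
  expect_setequal(m0$patient_id, with_miss$baseline$patient_id)
  expect_error(apply_missingness(co, 1), "missing_prob")
})

test_that("observed outcomes are consistent with the latent truth", {
  cfg <- quick_config(n = 400, seed = 13)
  co <- generate_cohort(cfg)
  with(co, {
    expect_equal(outcomes$rfs_months,
                 pmin(truth$event_time, truth$censor_time, 36))
    expect_equal(outcomes$event,
                 as.integer(truth$event_time <= pmin(truth$censor_time, 36)))
  })
  last_visit <- tapply(co$labs$visit_month, co$labs$patient_id, max)
  expect_true(all(last_visit <=
                    co$outcomes$rfs_months[match(as.numeric(names(last_visit)),
                                                 co$outcomes$patient_id)]))
})

test_that("stronger marker-change effects raise the event proportion", {
  tr <- pni_driven_traj()
  rate_at <- function(strength) {
    mean(vapply(1:20, function(s) {
      co <- generate_cohort(quick_config(n = 250, seed = 100 + s,
                                         censor_rate = 0),
                            traj = tr,
                            hazard = pni_driven_hazard(strength))
      mean(co$outcomes$event)
    }, numeric(1)))
  }
  expect_gt(rate_at(3), rate_at(1.5))
})
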