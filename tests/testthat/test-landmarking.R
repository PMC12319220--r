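test_that("landmark cohort keeps exactly the patients at risk at 1 year", {
  o <- data.frame(patient_id = 1:4,
                  rfs_months = c(8, 40, 20, 12),
                  event = c(1, 0, 1, 1))
  lm <- build_landmark_cohort(o, 12, 36)
  expect_setequal(lm$patient_id, c(2, 3))          # event at 8 and at exactly 12 excluded
  expect_equal(lm$residual_time[lm$patient_id == 2], 24)  # capped at horizon
  expect_equal(lm$event[lm$patient_id == 2], 0)
  expect_equal(lm$residual_time[lm$patient_id == 3], 8)
  expect_equal(lm$event[lm$patient_id == 3], 1)

  co <- generate_cohort(quick_config(n = 200, seed = 21))
  lm2 <- build_landmark_cohort(co$outcomes)
  expect_equal(nrow(lm2), 200 - sum(co$outcomes$rfs_months <= 12))
  expect_true(all(lm2$residual_time > 0))
  expect_true(all(lm2$patient_id %in% co$outcomes$patient_id))

  expect_error(build_landmark_cohort(data.frame(patient_id = 1, rfs_months = 5,
                                                event = 1)),
               "empty landmark cohort")
})

test_that("events beyond the horizon are recoded as censored", {
  o <- data.frame(patient_id = 1, rfs_months = 40, event = 1)
  lm <- build_landmark_cohort(o, 12, 36)
  expect_equal(lm$residual_time, 24)
  expect_equal(lm$event, 0)
})

test_that("observed change uses the last measurement at or before the landmark", {
  s <- data.frame(visit_month = c(0, 3, 6, 9, 12), value = c(50, 49, 47, 46, 44))
  expect_equal(as.numeric(lm10_change(s, 12)), -6)
  expect_equal(as.numeric(lm10_change(data.frame(visit_month = c(0, 6, 12),
                                                 value = c(5, 5, 5)), 12)), 0)
  s9 <- data.frame(visit_month = c(0, 3, 6, 9), value = c(50, 49, 47, 46))
  expect_equal(as.numeric(lm10_change(s9, 12)), -4)
  only0 <- data.frame(visit_month = 0, value = 50)
  ch <- lm10_change(only0, 12)
  expect_equal(as.numeric(ch), 0)
  expect_true(attr(ch, "baseline_only"))
})

test_that("closed-form random effects match the GLS oracle", {
  alpha <- c(10, -0.3)
  G <- matrix(c(2.25, 0.1, 0.1, 0.02), 2)
  sigma2 <- 0.25
  d <- data.frame(
    patient_id = rep(1:2, c(3, 4)),
    visit_month = c(0, 6, 12, 0, 3, 6, 9),
    value = c(11.2, 9.1, 7.4, 8.9, 8.2, 7.9, 7.0)
  )
  b <- blup_random_effects(d, alpha, G, sigma2)
  for (i in 1:2) {
    di <- d[d$patient_id == i, ]
    expect_equal(unlist(b[i, c("b0", "b1")], use.names = FALSE),
                 oracle_blup(di$visit_month, di$value, alpha, G, sigma2),
                 tolerance = 1e-8)
  }
})

test_that("package BLUPs agree with lme4 conditional modes at fitted parameters", {
  d <- toy_series(n = 15, seed = 5)
  fit <- fit_trajectory_model(d, 12)
  lfit <- lme4::lmer(value ~ visit_month + (visit_month | patient_id),
                     data = d, REML = FALSE)
  re <- lme4::ranef(lfit)$patient_id
  ord <- match(fit$blups$patient_id, as.numeric(rownames(re)))
  expect_equal(fit$blups$b0, re[ord, 1], tolerance = 1e-5)
  expect_equal(fit$blups$b1, re[ord, 2], tolerance = 1e-5)
})

test_that("degenerate mixed models behave sensibly", {
  # pure noise, no subject heterogeneity: BLUPs collapse toward 0
  set.seed(8)
  d <- data.frame(patient_id = rep(1:30, each = 5),
                  visit_month = rep(c(0, 3, 6, 9, 12), 30))
  d$value <- 20 - 0.5 * d$visit_month + rnorm(nrow(d), 0, 2)
  fit <- suppressWarnings(fit_trajectory_model(d, 12))
  expect_lt(max(abs(fit$blups$b0)), 2)
  expect_lt(max(abs(fit$blups$b1)), 0.5)

  # noiseless limit: the predicted line interpolates a patient's two points
  b <- blup_random_effects(
    data.frame(patient_id = 1, visit_month = c(0, 12), value = c(12, 6)),
    alpha = c(10, -0.3), G = diag(c(4, 0.04)), sigma2 = 1e-10)
  pred <- (10 + b$b0) + (-0.3 + b$b1) * c(0, 12)
  expect_equal(pred, c(12, 6), tolerance = 1e-5)

  expect_error(fit_trajectory_model(
    data.frame(patient_id = 1:3, visit_month = 0, value = 1:3)),
    ">= 2 observations")
})

test_that("BLUP magnitude shrinks as residual noise grows", {
  d1 <- data.frame(patient_id = 1, visit_month = c(0, 3, 6, 9, 12),
                   value = c(14, 12.5, 11, 9, 8))
  alpha <- c(10, -0.3); G <- diag(c(4, 0.04))
  mags <- vapply(c(0.01, 0.1, 1, 10, 100), function(s2) {
    b <- blup_random_effects(d1, alpha, G, s2)
    abs(b$b0) + abs(b$b1)
  }, numeric(1))
  expect_true(all(diff(mags) <= 1e-12))
})

test_that("predicted change at the landmark reduces to the observed change without noise", {
  # complete linear data in the vanishing-noise limit:
  # landmarking 1.5 change -> landmarking 1.0 change
  d <- toy_series(n = 8, seed = 3, sigma = 1e-4)
  fit <- suppressWarnings(fit_trajectory_model(d, 12))
  pred <- lm15_predicted(fit)
  for (i in 1:8) {
    di <- d[d$patient_id == i, c("visit_month", "value")]
    expect_equal(pred$change[pred$patient_id == i],
                 as.numeric(lm10_change(di, 12)), tolerance = 1e-3)
  }
  expect_error(lm15_predicted(fit, patient_ids = 999), "absent")
})

test_that("BLUP predictions beat carried-forward values under missingness", {
  # when post-baseline visits are informative but patchy, the shrunken
  # model prediction tracks the true month-12 value better than LOCF
  wins <- vapply(1:20, function(s) {
    cfg <- quick_config(n = 150, seed = 400 + s, missing_prob = 0.35,
                        censor_rate = 0)
    co <- generate_cohort(cfg, traj = pni_driven_traj(),
                          hazard = pni_driven_hazard(0.5))
    lmc <- build_landmark_cohort(co$outcomes)
    tr <- pni_driven_traj()$albumin
    truth <- co$truth[match(lmc$patient_id, co$truth$patient_id), ]
    true12 <- (tr$fixed_intercept + truth$albumin_b0) +
      (tr$fixed_slope + truth$albumin_b1) * 12
    labs <- co$labs[co$labs$patient_id %in% lmc$patient_id &
                      co$labs$visit_month <= 12, ]
    series <- data.frame(patient_id = labs$patient_id,
                         visit_month = labs$visit_month,
                         value = labs$albumin)
    fit <- suppressWarnings(fit_trajectory_model(series, 12))
    pred <- lm15_predicted(fit, lmc$patient_id, type = "level")
    locf <- locf_impute(series, c(0, 3, 6, 9, 12))
    last <- locf$value[locf$visit_month == 12]
    pid <- locf$patient_id[locf$visit_month == 12]
    last <- last[match(lmc$patient_id, pid)]
    cor(pred$predicted, true12) - cor(last, true12)
  }, numeric(1))
  expect_gt(mean(wins), 0)
})
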