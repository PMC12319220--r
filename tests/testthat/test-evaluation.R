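test_that("concordance handles the degenerate orderings exactly", {
  expect_equal(harrell_c(rep(1, 5), time = 1:5, event = rep(1, 5))$c, 0.5)
  expect_equal(harrell_c(5:1, time = 1:5, event = rep(1, 5))$c, 1)
  expect_equal(harrell_c(1:5, time = 1:5, event = rep(1, 5))$c, 0)
  expect_error(harrell_c(1:3, time = c(1, 1, 1), event = c(1, 1, 1)),
               "no usable pairs")
})

test_that("concordance equals exhaustive pair enumeration on a censored toy set", {
  score <- c(0.9, 0.1, 0.5, 0.7, 0.2, 0.5)
  time <- c(2, 9, 5, 3, 8, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  got <- harrell_c(score, time, event)
  want <- oracle_concordance(score, time, event)
  expect_equal(got$c, want$c)
  expect_equal(got$concordant, want$concordant)
  expect_equal(got$discordant, want$discordant)
  expect_equal(got$tied_score, want$tied_score)
  expect_equal(got$usable, want$usable)
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(19)
  time <- sample(100, 40)          # distinct times
  event <- rbinom(40, 1, 0.6)
  score <- rnorm(40)
  got <- harrell_c(score, time, event)$c
  ref <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)$concordance
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("Kaplan-Meier estimates match hand-computed product-limit values", {
  # 8 subjects, worked by hand: events at 1 (1/8), 3 (1/6), 5 (1/4), 7 (1/2)
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 0, 1, 0, 1, 0)
  km <- km_estimator(time, event)
  expect_equal(km_surv_at(km, 1), 7 / 8)
  expect_equal(km_surv_at(km, 3), 7 / 8 * 5 / 6)
  expect_equal(km_surv_at(km, 5), 7 / 8 * 5 / 6 * 3 / 4)
  expect_equal(km_surv_at(km, 7.5), 7 / 8 * 5 / 6 * 3 / 4 * 1 / 2)
  expect_equal(km_surv_at(km, 0.5), 1)
  # identity: value at the last event time equals the product of factors
  expect_equal(km_surv_at(km, 7),
               oracle_km(time, event, 7))
  # no events
  expect_equal(km_estimator(1:4, rep(0, 4))$surv, rep(1, 4))
})

test_that("log-rank behaves under symmetry and degeneracy", {
  set.seed(23)
  t1 <- rexp(30, 0.1); e1 <- rbinom(30, 1, 0.7)
  lr <- logrank_test(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 30))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$df, 1)
  expect_error(logrank_test(t1, e1, rep("a", 30)), "single group")
})

test_that("tertile groups split evenly and warn when degenerate", {
  probs <- seq(0.005, 0.995, length.out = 99)
  rg <- risk_tertile_groups(probs)
  expect_equal(as.numeric(table(rg$group)), c(33, 33, 33))
  # the lowest survival third is labelled high risk
  expect_true(all(probs[rg$group == "high"] < probs[rg$group == "low"]))
  expect_warning(risk_tertile_groups(rep(0.5, 10)), "degenerate")
})

test_that("well-separated risk groups give ordered survival curves", {
  ok <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 240
    lp <- rnorm(n, sd = 1.2)
    time <- rexp(n, 0.03 * exp(lp))
    event <- as.integer(time <= 24)
    time <- pmin(time, 24)
    rfs_prob <- exp(-0.03 * 24 * exp(lp))   # true model-based RFS at horizon
    rg <- risk_tertile_groups(rfs_prob)
    km_at <- vapply(c("low", "middle", "high"), function(g) {
      sel <- rg$group == g
      km_surv_at(km_estimator(time[sel], event[sel]), 24)
    }, numeric(1))
    all(diff(km_at) < 0)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("calibration groups match predicted and observed risk when well specified", {
  set.seed(29)
  n <- 2000
  lp <- rnorm(n)
  rate <- 0.02 * exp(lp)
  time <- rexp(n, rate)
  cens <- rexp(n, 0.01)
  obs_t <- pmin(time, cens, 30)
  ev <- as.integer(time <= pmin(cens, 30))
  risk <- 1 - exp(-rate * 30)   # the true 30-month risk
  tab <- calibration_table(risk, obs_t, ev, horizon = 30, n_groups = 5)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$mean_predicted) > 0))
  expect_lt(max(abs(tab$mean_predicted - tab$observed)), 0.08)

  # predicted 0 with real events: maximal miscalibration everywhere
  tab0 <- calibration_table(rep(0, n), obs_t, ev, 30, 5)
  expect_true(all(tab0$observed > 0.2))
  expect_true(all(tab0$mean_predicted == 0))

  # quintiles of 187 differ by at most one patient
  tab187 <- calibration_table(runif(187), rexp(187, 0.05), rbinom(187, 1, 0.4),
                              horizon = 12, n_groups = 5)
  expect_lte(diff(range(tab187$n)), 1)
  expect_error(calibration_table(risk, obs_t, ev, 30, n_groups = 4),
               "n_groups")
})

test_that("reclassification tables tabulate moves on the risk scale", {
  risk_ref <- c(0.05, 0.12, 0.20, 0.50, 0.30)
  risk_new <- c(0.05, 0.40, 0.10, 0.50, 0.35)
  event <- c(0, 1, 0, 1, 0)
  tab <- reclassification_table(risk_ref, risk_new, event)
  expect_equal(sum(tab$events), 2)
  expect_equal(sum(tab$nonevents), 3)
  expect_equal(unname(tab$events["cat2", "cat4"]), 1)   # 0.12 -> 0.40
  expect_equal(unname(tab$nonevents["cat3", "cat1"]), 1) # 0.20 -> 0.10
})

test_that("NRI is zero for diagonal tables and flips sign under model swap", {
  diag_tab <- gclandmark:::as_reclassification_table(
    diag(c(5, 6, 7, 8)), diag(c(10, 11, 12, 13)))
  expect_equal(nri_categorical(diag_tab)$nri, 0)

  set.seed(41)
  ev <- matrix(rpois(16, 3), 4)
  ne <- matrix(rpois(16, 8), 4)
  fwd <- nri_categorical(gclandmark:::as_reclassification_table(ev, ne))
  bwd <- nri_categorical(gclandmark:::as_reclassification_table(t(ev), t(ne)))
  expect_equal(fwd$nri, -bwd$nri)

  empty <- gclandmark:::as_reclassification_table(matrix(0, 4, 4), ne)
  expect_error(nri_categorical(empty), "empty")
})

test_that("bootstrap optimism is zero for a constant model and streams are nested", {
  set.seed(47)
  d <- data.frame(residual_time = rexp(60, 0.1), event = rbinom(60, 1, 0.5),
                  x = rnorm(60))
  d$residual_time <- d$residual_time + 0.01
  # a constant model scores every patient identically: C is 1/2 everywhere,
  # so the optimism is exactly zero
  constant_builder <- function(train) function(newdata) rep(1, nrow(newdata))
  res <- bootstrap_optimism(d, constant_builder, B = 25, seed = 5)
  expect_equal(res$optimism, 0)
  expect_equal(res$corrected, res$apparent)
  expect_equal(res$apparent, 0.5)
  expect_equal(res$B, 25)
  expect_equal(res$n_failed, 0)

  x_builder <- function(train) function(newdata) newdata$x
  res25 <- bootstrap_optimism(d, x_builder, B = 25, seed = 5)
  res10 <- bootstrap_optimism(d, x_builder, B = 10, seed = 5)
  expect_equal(res10$replicates$c_boot, res25$replicates$c_boot[1:10])

  rerun <- bootstrap_optimism(d, x_builder, B = 25, seed = 5)
  expect_identical(res25$replicates, rerun$replicates)
})

test_that("identical builders give a C-difference interval centred at zero", {
  set.seed(53)
  d <- data.frame(residual_time = rexp(80, 0.1) + 0.01,
                  event = rbinom(80, 1, 0.5), x = rnorm(80))
  builder <- function(train) {
    m <- fit_cox(train, "x")
    function(newdata) risk_score(m, newdata)
  }
  res <- bootstrap_c_difference(d, builder, builder, B = 20, seed = 3)
  expect_equal(res$ci, c(0, 0))
  expect_equal(res$apparent_delta, 0)
  rerun <- bootstrap_c_difference(d, builder, builder, B = 20, seed = 3)
  expect_identical(res$delta, rerun$delta)
})
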