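test_that("cohort simulation is deterministic under seed and seed-sensitive", {
  p <- cohort_params(n_participants = 20, outcomes = quick_outcomes())
  a <- simulate_cohort(p, seed = 42)
  b <- simulate_cohort(p, seed = 42)
  expect_identical(a$participants, b$participants)
  expect_identical(a$visits, b$visits)
  expect_identical(a$ranef, b$ranef)
  c <- simulate_cohort(p, seed = 43)
  expect_false(identical(a$visits$value, c$visits$value))
})

test_that("trajectories respect visit-schedule and range invariants", {
  co <- quick_cohort(n = 50, seed = 7)
  for (id in unique(co$visits$participant_id)) {
    tv <- sort(unique(co$visits$visit_months[co$visits$participant_id == id]))
    expect_equal(tv[1], 0)
    expect_true(all(diff(tv) > 0))
  }
  p <- co$participants
  expect_true(all(p$event_time_months[p$event_flag == 0] <=
                    co$params$censor_months + 1e-9))
  als <- co$visits[co$visits$outcome == "alsfrs_total", ]
  expect_true(all(als$value >= 0 & als$value <= 48))
  expect_true(all(als$value == round(als$value)))
  expect_true(all(co$visits$value >= 0))
  # visits never extend past death/censoring
  last_visit <- tapply(co$visits$visit_months, co$visits$participant_id, max)
  expect_true(all(last_visit <= p$event_time_months[
    match(names(last_visit), p$participant_id)] + 1e-9))
})

test_that("realized random effects match configured moments", {
  p <- cohort_params(n_participants = 500,
                     outcomes = quick_outcomes("alsfrs_total"))
  co <- simulate_cohort(p, seed = 11)
  sl <- co$ranef$slope
  se <- 0.45 / sqrt(500)
  expect_lt(abs(mean(sl) - (-0.62)), 3 * se)
  expect_lt(abs(sd(sl) - 0.45), 0.1)
  ic <- co$ranef$intercept
  expect_lt(abs(mean(ic) - 37.38), 3 * 5.47 / sqrt(500))
})

test_that("null association decouples event times from trajectories", {
  p <- cohort_params(n_participants = 1000, assoc_coeff = 0,
                     outcomes = quick_outcomes("alsfrs_total"))
  co <- simulate_cohort(p, seed = 5)
  died <- co$participants$event_flag == 1
  sl <- co$ranef$slope[match(co$participants$participant_id,
                             co$ranef$participant_id)]
  r <- cor(sl[died], log(co$participants$event_time_months[died]))
  expect_lt(abs(r), 0.1)
})

test_that("negative association makes faster decliners die sooner", {
  co <- simulate_cohort(cohort_params(
    n_participants = 500, outcomes = quick_outcomes("alsfrs_total")), seed = 13)
  p <- co$participants
  sl <- co$ranef$slope[match(p$participant_id, co$ranef$participant_id)]
  # stochastic ordering of observed follow-up (deaths + administrative
  # censoring): steeper decline -> shorter observed time and more deaths
  ct <- cor.test(sl, p$event_time_months, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)  # less-negative slope -> longer survival
  expect_lt(ct$p.value, 0.01)
  thirds <- cut(sl, quantile(sl, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  death_rate <- tapply(p$event_flag, thirds, mean)
  expect_gt(death_rate[[1]], death_rate[[3]])
})

test_that("default parameters reproduce the cohort's ~64% event fraction", {
  co <- simulate_cohort(cohort_params(n_participants = 2000,
                                      outcomes = quick_outcomes("alsfrs_total")),
                        seed = 3)
  expect_lt(abs(mean(co$participants$event_flag) - 0.64), 0.05)
})

test_that("treatment effect rescales slopes and nothing else", {
  co <- quick_cohort(n = 25, seed = 9)
  expect_identical(apply_treatment_effect(co, 0)$visits, co$visits)
  full <- apply_treatment_effect(co, 1)
  # slope fully removed: regenerated values are intercept + residual (clipped)
  v <- full$visits[full$visits$outcome == "peak6_counts", ]
  re <- full$ranef[full$ranef$outcome == "peak6_counts", ]
  expected <- pmax(0, re$intercept[match(v$participant_id, re$participant_id)] +
                     v$resid)
  expect_equal(v$value, expected)
  # 30% improvement on a -0.62 slope is a -0.434 effective slope
  co30 <- apply_treatment_effect(co, 0.3)
  a <- co30$visits[co30$visits$outcome == "alsfrs_total", ]
  re <- co30$ranef[co30$ranef$outcome == "alsfrs_total", ]
  i <- match(a$participant_id, re$participant_id)
  manual <- round(pmin(48, pmax(0, re$intercept[i] +
                                  0.7 * re$slope[i] * a$visit_months + a$resid)))
  expect_equal(a$value, manual)
  expect_equal(0.7 * -0.62, -0.434)
  expect_error(apply_treatment_effect(co, 1.2), "fraction")
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n_participants = 1), "n_participants")
  expect_error(cohort_params(slope_intercept_corr = 1.5), "slope_intercept_corr")
  expect_error(cohort_params(weibull_shape = 0), "weibull_shape")
  oc <- default_outcomes(); oc$slope_sd[1] <- -1
  expect_error(cohort_params(outcomes = oc), "SDs")
})

test_that("raw-signal generator is deterministic with exact length", {
  sp <- signal_params(duration_days = 0.05)
  a <- simulate_raw_recording(sp, seed = 21)
  b <- simulate_raw_recording(sp, seed = 21)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$samples), 0.05 * 86400 * 30)
  sp8 <- signal_params(duration_days = 8, sample_rate_hz = 1, noise_sd_g = 0)
  expect_equal(nrow(simulate_raw_recording(sp8, seed = 1)$samples), 8 * 86400)
})

test_that("static signal is pure gravity and zero ENMO", {
  sp <- signal_params(duration_days = 0.01, activity_level = 0, noise_sd_g = 0)
  raw <- simulate_raw_recording(sp, seed = 1)
  expect_true(all(raw$samples[, 1] == 0))
  expect_true(all(raw$samples[, 3] == 1))
  expect_true(all(compute_enmo(raw)$values == 0))
})

test_that("mean ENMO increases with the activity level", {
  sp_lo <- signal_params(duration_days = 0.25, activity_level = 0.2)
  sp_hi <- signal_params(duration_days = 0.25, activity_level = 0.8)
  e_lo <- mean(compute_enmo(simulate_raw_recording(sp_lo, seed = 6))$values)
  e_hi <- mean(compute_enmo(simulate_raw_recording(sp_hi, seed = 6))$values)
  expect_gt(e_hi, e_lo)
})

test_that("raw and cohort CSV round-trips preserve the data", {
  raw <- const_recording(c(0, 0, 1.05), secs = 10)
  f <- tempfile(fileext = ".csv")
  write_raw_csv(raw, f)
  back <- read_raw_csv(f)
  expect_equal(back$sample_rate_hz, 30)
  expect_equal(back$samples, raw$samples, tolerance = 1e-6)
  co <- quick_cohort(n = 10, seed = 2)
  ld <- as_longitudinal_dataset(co)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(ld, f1, f2)
  back2 <- read_cohort_csv(f1, f2)
  expect_equal(back2$long$value, ld$long$value)
  expect_equal(back2$survival$time_months, ld$survival$time_months)
  unlink(c(f, paste0(f, ".json"), f1, f2))
})
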