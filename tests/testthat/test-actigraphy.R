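test_that("ENMO matches hand-computed values on constant signals", {
  expect_true(all(compute_enmo(const_recording(c(0, 0, 1)))$values == 0))
  expect_equal(compute_enmo(const_recording(c(0, 0, 1.1)))$values,
               rep(100, 120), tolerance = 1e-9)
  # norm 0.9 g: negatives truncated to zero
  v <- c(0.9, 0, 0)
  expect_true(all(compute_enmo(const_recording(v))$values == 0))
  # trailing partial epoch dropped
  raw <- const_recording(c(0, 0, 1.1), secs = 13)
  expect_length(compute_enmo(raw, 5)$values, 2)
})

test_that("ENMO is invariant to rigid rotation of the sensor frame", {
  raw <- day_recording(0.5)
  idx <- 1:(30 * 1200)
  s <- raw$samples[idx, ]
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- raw_recording(s %*% R, 30)
  expect_equal(compute_enmo(rot)$values,
               compute_enmo(raw_recording(s, 30))$values, tolerance = 1e-10)
})

test_that("activity counts are zero for static input and monotone in amplitude", {
  zero <- raw_recording(matrix(1e-12, 30 * 60, 3), 30)
  expect_true(all(compute_activity_counts(zero)$values == 0))
  # constant gravity, arbitrary orientation: DC removed by the band-pass
  g <- c(0.6, -0.64, 0.48); g <- g / sqrt(sum(g^2))
  expect_true(all(compute_activity_counts(const_recording(g))$values == 0))
  # 1 Hz in-band sinusoid: doubling amplitude increases every epoch's counts
  t <- (0:(30 * 600 - 1)) / 30
  mk <- function(A) raw_recording(cbind(A * sin(2 * pi * t), 0, 1), 30)
  c1 <- compute_activity_counts(mk(0.1))$values
  c2 <- compute_activity_counts(mk(0.2))$values
  expect_true(all(c2 > c1))
})

test_that("activity counts are invariant to axis permutation", {
  raw <- day_recording(0.5)
  s <- raw$samples[1:(30 * 1200), ]
  a <- compute_activity_counts(raw_recording(s, 30))$values
  b <- compute_activity_counts(raw_recording(s[, c(3, 1, 2)], 30))$values
  expect_identical(a, b)
})

test_that("higher sample rates are block-averaged to 30 Hz for counts", {
  t60 <- (0:(60 * 600 - 1)) / 60
  raw60 <- raw_recording(cbind(0.3 * sin(2 * pi * t60), 0, 1), 60)
  t30 <- (0:(30 * 600 - 1)) / 30
  raw30 <- raw_recording(cbind(0.3 * sin(2 * pi * t30), 0, 1), 30)
  c60 <- compute_activity_counts(raw60)$values
  c30 <- compute_activity_counts(raw30)$values
  expect_equal(c60, c30, tolerance = 0.05)
  expect_error(compute_activity_counts(raw_recording(matrix(0, 100, 3), 20)),
               "30 Hz")
})

test_that("MVPA counts strictly-above-threshold epochs per day", {
  n_day <- 86400 / 5
  v <- rep(0, n_day)
  v[1:4] <- c(50, 120, 99, 101)
  es <- epoch_series(v, 5, "enmo")
  expect_equal(mvpa_from_enmo(es)$mvpa_minutes, 2 * 5 / 60)
  expect_equal(mvpa_from_enmo(epoch_series(rep(100, n_day), 5, "enmo"))$mvpa_minutes, 0)
  # raising the threshold can only decrease MVPA (brute force over a grid)
  set.seed(1)
  rnd <- epoch_series(runif(n_day, 0, 300), 5, "enmo")
  mv <- vapply(c(50, 100, 150, 200),
               function(th) mvpa_from_enmo(rnd, th)$mvpa_minutes, numeric(1))
  expect_true(all(diff(mv) <= 0))
  expect_true(all(mv <= 1440))
  expect_error(mvpa_from_enmo(epoch_series(0:10, 10, "counts")), "enmo")
})

test_that("peak rolling ENMO (M5) equals exhaustive window enumeration", {
  n_day <- 86400 / 45  # 1920 epochs of 45 s
  k <- 5 * 3600 / 45
  expect_equal(rolling_peak_enmo(epoch_series(rep(7, n_day), 45, "enmo"))$m5, 7)
  one <- rep(0, n_day); one[500] <- 130
  expect_equal(rolling_peak_enmo(epoch_series(one, 45, "enmo"))$m5, 130 / k)
  set.seed(2)
  v <- rexp(2 * n_day, 1 / 30)  # two days
  es <- epoch_series(v, 45, "enmo")
  got <- rolling_peak_enmo(es)$m5
  want <- c(max(brute_force_window_means(v[1:n_day], k)),
            max(brute_force_window_means(v[(n_day + 1):(2 * n_day)], k)))
  expect_equal(got, want, tolerance = 1e-10)
  expect_warning(rolling_peak_enmo(epoch_series(rep(1, 10), 45, "enmo")), "NA")
})

test_that("peak 6-min percentile matches a brute-force percentile oracle", {
  n_day <- 86400 / 45
  k <- 6 * 60 / 45  # 8 epochs
  cst <- epoch_series(rep(25, n_day), 45, "counts")
  expect_equal(peak_window_percentile(cst)$peak, 25)
  expect_equal(peak_window_percentile(cst, aggregate = "sum")$peak, 25 * k)
  # a single 6-min burst in an otherwise-empty day is below the 95th pct
  burst <- rep(0, n_day); burst[1000:1007] <- 500
  expect_lt(peak_window_percentile(epoch_series(burst, 45, "counts"))$peak, 1)
  set.seed(3)
  v <- rpois(n_day, 40)
  got <- peak_window_percentile(epoch_series(v, 45, "counts"))$peak
  want <- unname(quantile(brute_force_window_means(v, k), 0.95, type = 7))
  expect_equal(got, want, tolerance = 1e-10)
  expect_lte(got, max(brute_force_window_means(v, k)))
  expect_error(peak_window_percentile(cst, percentile = 0), "percentile")
})

test_that("step detection counts injected gait cycles and rejects noise", {
  expect_equal(sum(estimate_steps(const_recording(c(0, 0, 1)))$steps), 0)
  # 60 s of 2 Hz walking: 120 swing cycles
  t <- (0:(30 * 3600 - 1)) / 30
  osc <- ifelse(t < 60, 0.4 * sin(2 * pi * 2 * t), 0)
  raw <- raw_recording(cbind(0, 0, 1 + osc), 30)
  st <- sum(estimate_steps(raw)$steps)
  expect_gt(st, 108)
  expect_lt(st, 132)
  set.seed(4)
  noisy <- raw_recording(matrix(rnorm(3 * 30 * 3600, c(0, 0, 1), 0.1),
                                ncol = 3, byrow = TRUE), 30)
  expect_equal(sum(estimate_steps(noisy)$steps), 0)
})

test_that("weekly summary trims 12-h ends and averages 7 identical days", {
  # build one deterministic 24-h pattern and tile it over 8 days: after the
  # 12-h trims every recording-aligned day sees the same cyclic content
  fs <- 30
  t <- (0:(86400 * fs - 1)) / fs
  gate <- (t %% 3600) < 120  # a 2-min bout every hour
  osc <- 0.35 * sin(2 * pi * 2 * t) * gate
  day <- cbind(0, 0, 1 + osc)
  raw8 <- raw_recording(day[rep(seq_len(nrow(day)), 8), ], fs)
  wf <- summarize_recording(raw8)
  expect_equal(nrow(wf$daily), 7)
  feats <- c("enmo_mean_mg", "mvpa_minutes", "m5_enmo_mg", "peak6_counts", "steps")
  for (f in feats) {
    expect_true(all(abs(wf$daily[[f]] - wf$daily[[f]][1]) < 1e-8))
    expect_equal(wf$weekly[[f]], mean(wf$daily[[f]]))  # recomputation oracle
  }
  expect_gt(wf$weekly[["steps"]], 0)
  expect_gt(wf$weekly[["mvpa_minutes"]], 0)
  expect_error(summarize_recording(raw_recording(day, fs)), "at least 8")
})

test_that("epoch-variant selection picks the fastest decline, ties to shortest epoch", {
  cand <- data.frame(
    family = c("mvpa", "mvpa", "enmo", "steps", "steps"),
    variant = c("mvpa_5s", "mvpa_60s", "enmo_5s", "steps_a", "steps_b"),
    epoch_s = c(5, 60, 5, 60, 5),
    std_slope = c(-0.03, -0.05, -0.04, -0.04, -0.04))
  sel <- select_epoch_variant(cand)
  expect_equal(sel$variant[sel$family == "mvpa"], "mvpa_60s")
  expect_equal(sel$variant[sel$family == "enmo"], "enmo_5s")  # single variant
  expect_equal(sel$variant[sel$family == "steps"], "steps_b") # tie -> 5 s
  cand$std_slope[2] <- NA
  expect_warning(sel2 <- select_epoch_variant(cand), "missing")
  expect_equal(sel2$variant[sel2$family == "mvpa"], "mvpa_5s")
})
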