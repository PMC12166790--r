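test_that("ALSFRS-R scoring reproduces the domain definitions", {
  all4 <- score_alsfrs(rep(4L, 12))
  expect_equal(all4$total, 48)
  expect_equal(all4$motor, 24)
  expect_equal(all4$bulbar, 12)
  expect_equal(all4$respiratory, 12)
  expect_true(all(score_alsfrs(rep(0L, 12)) == 0))
  items <- c(4, 4, 4, 3, 3, 2, 2, 1, 1, 4, 4, 4)
  sc <- score_alsfrs(items)
  expect_equal(sc$motor, 12)
  expect_equal(sc$upper_limb, 6)
  expect_equal(sc$lower_limb, 2)
  expect_equal(sc$total, sum(items))
  expect_error(score_alsfrs(c(rep(2, 11), 5)), "0, 4")
  expect_error(score_alsfrs(rep(2, 10)), "12")
})

test_that("delta FRS follows its defining formula", {
  expect_equal(delta_frs(48, 7), 0)
  expect_equal(delta_frs(36, 24), -0.5)
  expect_equal(delta_frs(38, 20), -0.5)  # the fast/slow threshold boundary
  expect_equal(delta_frs(c(48, 36), c(10, 24)), c(0, -0.5))
  expect_error(delta_frs(40, 0), "months")
  expect_error(delta_frs(50, 10), "48")
})

test_that("Holm adjustment matches closed testing and is monotone", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # closed-testing oracle with Bonferroni local tests (m <= 5):
  # adj p_i = max over subsets S containing i of min(1, |S| * min_{j in S} p_j)
  closed_test <- function(p) {
    m <- length(p)
    sapply(seq_len(m), function(i) {
      worst <- 0
      for (mask in 1:(2^m - 1)) {
        S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
        if (i %in% S)
          worst <- max(worst, min(1, length(S) * min(p[S])))
      }
      worst
    })
  }
  set.seed(7)
  for (r in 1:20) {
    p <- round(runif(sample(2:5, 1)), 3)
    adj <- holm_adjust(p)
    expect_equal(adj, closed_test(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("single-visit correlations are null-calibrated on independent outcomes", {
  # flat trajectories: declining outcomes would correlate spuriously through
  # the shared (random) sampling time, which is exactly the time confounding
  # the residual-partial mode exists to remove
  oc <- quick_outcomes()
  oc$slope <- 0
  co <- simulate_cohort(cohort_params(n_participants = 95, outcomes = oc),
                        seed = 20)
  ok <- vapply(1:10, function(s) {
    cr <- correlation_analysis(co, mode = "single_visit", seed = s)
    expect_equal(diag(cr$r), c(alsfrs_total = 1, peak6_counts = 1))
    r <- cr$r["alsfrs_total", "peak6_counts"]
    abs(r) < 0.3 && cr$p_adj["alsfrs_total", "peak6_counts"] > 0.05
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("single-visit correlations recover a known correlation", {
  rhat <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n <- 95
    x <- rnorm(n)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
    long <- rbind(
      data.frame(participant_id = sprintf("P%03d", 1:n), visit_months = 0,
                 outcome = "a", value = x),
      data.frame(participant_id = sprintf("P%03d", 1:n), visit_months = 0,
                 outcome = "b", value = y))
    surv <- data.frame(participant_id = sprintf("P%03d", 1:n), time_months = 1,
                       event = 1, age_years = 60, sex = "male")
    cr <- correlation_analysis(longitudinal_dataset(long, surv),
                               mode = "single_visit", seed = s)
    cr$r["a", "b"]
  }, numeric(1))
  expect_lt(abs(mean(rhat) - 0.6), 0.05)
})

test_that("residual-mode correlations detect shared structure and flag degeneracy", {
  set.seed(5)
  n <- 120
  ids <- sprintf("P%03d", 1:n)
  grid <- expand.grid(participant_id = ids, visit_months = c(0, 3, 6, 9),
                      stringsAsFactors = FALSE)
  shock <- rnorm(nrow(grid), 0, 3)
  i <- match(grid$participant_id, ids)
  a1 <- rnorm(n, 40, 1); a2 <- rnorm(n, 20, 1)
  long <- rbind(
    cbind(grid, outcome = "o1",
          value = a1[i] - 0.5 * grid$visit_months + shock + rnorm(nrow(grid))),
    cbind(grid, outcome = "o2",
          value = a2[i] - 0.2 * grid$visit_months + shock + rnorm(nrow(grid))))
  surv <- data.frame(participant_id = ids, time_months = 12, event = 1,
                     age_years = 60, sex = "male")
  cr <- correlation_analysis(longitudinal_dataset(long, surv),
                             mode = "residual_partial")
  expect_gt(cr$r["o1", "o2"], 0.5)
  expect_lt(cr$p_adj["o1", "o2"], 0.05)
  expect_true(all(cr$p_adj >= cr$p, na.rm = TRUE))
  # a zero-variance outcome is excluded from the family with a warning
  long2 <- rbind(long, cbind(grid, outcome = "flat", value = 5))
  expect_warning(
    cr2 <- correlation_analysis(longitudinal_dataset(long2, surv),
                                mode = "single_visit", seed = 1),
    "zero-variance")
  expect_false("flat" %in% colnames(cr2$r))
})

test_that("residual PCA has orthonormal loadings and exact normalisations", {
  set.seed(9)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  # unequal block strengths keep the two leading eigenvalues distinct, so
  # each block dominates its own component instead of mixing under a tie
  m <- cbind(a1 = f1 + 0.2 * rnorm(n), a2 = f1 + 0.2 * rnorm(n),
             a3 = f1 + 0.2 * rnorm(n), b1 = f2 + 0.7 * rnorm(n),
             b2 = f2 + 0.7 * rnorm(n), b3 = f2 + 0.7 * rnorm(n))
  pr <- pca_residuals(m)
  expect_equal(sum(pr$variance_explained), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(pr$contributions)), rep(100, 6),
               tolerance = 1e-10)
  expect_equal(t(pr$loadings) %*% pr$loadings, diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  # reconstruction of the correlation matrix from loadings and eigenvalues
  rec <- pr$loadings %*% diag(pr$sdev^2) %*% t(pr$loadings)
  expect_equal(rec, cor(m), tolerance = 1e-8, ignore_attr = TRUE)
  # the two independent blocks dominate separate leading components
  for (k in 1:2) {
    ca <- sum(pr$contributions[1:3, k])
    cb <- sum(pr$contributions[4:6, k])
    expect_gt(max(ca, cb), 70)
  }
  # missing-data handling
  m2 <- m; m2[1, 1] <- NA
  expect_equal(pca_residuals(m2, "complete")$n, n - 1)
  expect_equal(pca_residuals(m2, "mean_impute")$n, n)
  expect_error(pca_residuals(m[1:2, ]), "3 rows")
})

test_that("median split balances groups and assigns ties low", {
  x <- c(5, 1, 3, 9, 7)  # odd n, distinct values
  g <- median_split(x)
  expect_lte(abs(sum(g == "low") - sum(g == "high")), 1)
  expect_equal(as.character(g[x == 5]), "low")  # tie at the median
  expect_equal(levels(delta_frs_group(c(-0.5, -0.4))), c("faster", "slower"))
  expect_equal(as.character(delta_frs_group(-0.5)), "faster")
})

test_that("Kaplan-Meier estimates match hand-computed product-limit values", {
  # group A: times 2,4,6,8,10 with events 1,1,0,1,0
  # S(2) = 4/5, S(4) = 4/5 * 3/4 = 3/5, S(8) = 3/5 * 1/2 = 3/10
  surv <- data.frame(
    time_months = c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9),
    event = c(1, 1, 0, 1, 0, 1, 1, 1, 0, 0))
  g <- factor(rep(c("A", "B"), each = 5))
  km <- km_logrank(surv, g)
  sfA <- summary(km$survfit[1])
  expect_equal(sfA$surv, c(0.8, 0.6, 0.3))
  expect_equal(sfA$time, c(2, 4, 8))
  expect_true(km$logrank_p > 0 && km$logrank_p <= 1)
})

test_that("identical groups give a null log-rank test and unit hazard ratio", {
  set.seed(2)
  base <- data.frame(time_months = rexp(40, 0.1), event = rbinom(40, 1, 0.7))
  surv <- rbind(base, base)
  g <- factor(rep(c("A", "B"), each = 40))
  km <- km_logrank(surv, g)
  expect_gt(km$logrank_p, 0.99)
  expect_equal(km$cox_hr, 1, tolerance = 1e-6)
})

test_that("a strong group effect is detected by the log-rank test", {
  detected <- vapply(1:20, function(s) {
    set.seed(300 + s)
    t1 <- rexp(50, 0.05); t2 <- rexp(50, 0.15)  # HR 3
    surv <- data.frame(time_months = c(t1, t2),
                       event = rep(1, 100))
    km_logrank(surv, factor(rep(c("slow", "fast"), each = 50)))$logrank_p < 0.01
  }, logical(1))
  expect_gte(sum(detected), 19)
  # degenerate groupings are rejected
  expect_error(km_logrank(data.frame(time_months = 1:4, event = c(1, 1, 0, 0)),
                          factor(rep("A", 4))), "two non-empty")
})
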