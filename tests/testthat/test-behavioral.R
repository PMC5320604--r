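test_that("performance error is the mean absolute distance to the EV", {
  tr <- data.frame(session = 1, trial = 1:2, ev = 35, sd = 5,
                   prediction = c(30, 40), reward = c(35, 35),
                   missed = FALSE)
  expect_equal(performance_error(tr, by_sd = FALSE), 5)
  tr$prediction <- tr$ev
  expect_equal(performance_error(tr, by_sd = FALSE), 0)
  tr$missed <- TRUE
  expect_true(is.na(performance_error(tr, by_sd = FALSE)))
})

test_that("performance error grows with SD for a running-mean agent (property)", {
  wins <- 0
  for (s in 1:30) {
    d <- running_mean_predictions(generate_experiment(seed = 400 + s))
    pe <- performance_error(d)
    if (pe[["SD5"]] < pe[["SD10"]] && pe[["SD10"]] < pe[["SD15"]])
      wins <- wins + 1
  }
  expect_gte(wins, 24)  # monotone in the large majority of seeds
})

test_that("scaler contingency reproduces the published worked example", {
  cohort <- data.frame(
    group = rep(c("sulpiride", "placebo"), c(19, 20)),
    nu = c(rep(0, 8), runif(11, 0.1, 1), rep(0, 2), runif(18, 0.1, 1)))
  tab <- scaling_contingency(cohort)
  expect_equal(unname(tab), matrix(c(8L, 2L, 11L, 18L), 2))
  chi <- pearson_chi2(tab)
  expect_equal(round(chi$statistic, 2), 5.27)
  expect_equal(chi$df, 1)
  expect_lt(chi$p_value, 0.025)
  # epsilon = 1 makes everyone a non-scaler
  expect_warning(tab1 <- scaling_contingency(cohort, epsilon = 1))
  expect_equal(unname(tab1[, "scaler"]), c(0L, 0L))
  expect_error(scaling_contingency(cohort, groups = c("sulpiride", "nope")),
               "unknown group")
})

test_that("the Pearson chi-square has no continuity correction", {
  expect_equal(pearson_chi2(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(pearson_chi2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("residualisation removes the covariate and standardises", {
  set.seed(31)
  y <- rnorm(40)
  x <- resid(lm(rnorm(40) ~ y))  # exactly orthogonal covariate
  r <- residualize(y, x)
  expect_equal(r, as.numeric(scale(y)), tolerance = 1e-10)
  expect_equal(mean(r), 0)
  expect_equal(sd(r), 1)
  # idempotent on its own output (z-scoring aside)
  expect_equal(residualize(r, x), r, tolerance = 1e-10)
  expect_error(residualize(2 * x, x), "degenerate")
  expect_error(residualize(y, rep(1, 40)), "constant")
  # group differences on residuals stay unbiased under a covariate effect
  set.seed(32)
  g <- rep(c("placebo", "sulpiride"), each = 30)
  cov <- rnorm(60, 150, 12)
  out <- ifelse(g == "sulpiride", 2, 0) + 0.05 * cov + rnorm(60, 0, 0.5)
  r2 <- residualize(out, cov)
  expect_gt(mean(r2[g == "sulpiride"]) - mean(r2[g == "placebo"]), 1)
})

test_that("group tests: two groups reduce the omnibus to the pairwise test", {
  set.seed(33)
  metric <- c(rnorm(15, 0), rnorm(15, 1))
  groups <- rep(c("placebo", "sulpiride"), each = 15)
  gt <- group_tests(metric, groups, type = "nonparametric")
  # Kruskal-Wallis on two groups is the squared (uncorrected) rank-sum z
  expect_equal(gt$omnibus$p_value,
               wilcox.test(metric[1:15], metric[16:30], exact = FALSE,
                           correct = FALSE)$p.value,
               tolerance = 1e-6)
  expect_equal(nrow(gt$posthoc), 1)
  gp <- group_tests(metric, groups, type = "parametric")
  expect_lt(gp$omnibus$p_value, 0.05)
  expect_error(group_tests(metric, rep("placebo", 30)), "2 groups")
  expect_error(group_tests(metric[1:3], c("a", "a", "b")), "at least 2 agents")
})

test_that("group tests hold their nominal type-I rate under the null", {
  set.seed(34)
  hits <- 0; nsim <- 600
  g <- rep(c("placebo", "sulpiride", "bromocriptine"), each = 15)
  for (i in seq_len(nsim)) {
    p <- group_tests(rnorm(45), g, type = "nonparametric")$omnibus$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / nsim, 0.03)
  expect_lt(hits / nsim, 0.07)
})

test_that("power against a location shift increases with the shift", {
  set.seed(35)
  power_at <- function(shift) {
    mean(replicate(150, {
      m <- c(rnorm(19), rnorm(19, shift))
      g <- rep(c("placebo", "sulpiride"), each = 19)
      group_tests(m, g, type = "nonparametric")$omnibus$p_value < 0.05
    }))
  }
  p0 <- power_at(0.3); p1 <- power_at(1.2)
  expect_gt(p1, p0)
  expect_gt(p1, 0.8)
})

test_that("the performance regression recovers the benefit of PE scaling", {
  set.seed(36)
  n <- 60
  cohort <- data.frame(
    group = rep(c("placebo", "sulpiride", "bromocriptine"), each = n / 3),
    nu = ifelse(runif(n) < 0.3, 0, runif(n, 0.3, 1)),
    k1 = runif(n, 0.4, 0.9), gamma = runif(n, 0.1, 0.6))
  cohort$perf_error <- 8 - 2 * (cohort$nu > 0) - 3 * cohort$k1 +
    2 * cohort$gamma + rnorm(n, 0, 0.8)
  res <- performance_regression(cohort)$coefficients
  est <- setNames(res$estimate, res$term)
  p <- setNames(res$p, res$term)
  expect_lt(est[["scaler"]], 0)
  expect_lt(p[["scaler"]], 0.05)
  expect_lt(est[["k1"]], 0)
  expect_gt(est[["gamma"]], 0)
  # perfect collinearity is refused
  bad <- cohort; bad$gamma <- bad$k1
  expect_error(performance_regression(bad), "rank")
})

test_that("null regressions give roughly uniform p-values", {
  set.seed(37)
  ps <- replicate(300, {
    n <- 30
    cohort <- data.frame(
      group = rep(c("placebo", "sulpiride"), each = 15),
      nu = ifelse(runif(n) < 0.4, 0, runif(n)),
      k1 = runif(n), gamma = runif(n),
      perf_error = rnorm(n))
    performance_regression(cohort)$coefficients$p[2]  # scaler term
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(median(ps), 0.3)
})

test_that("model R2 is high when the generating model predicts the data", {
  m <- model_params("PH2", k1 = 0.7, gamma = 0.3, nu = 0.7, sigma = 2)
  tr <- simulated_agent(m, seed = 38)
  mu <- predict_series(m, tr, mu_init = NULL)
  expect_gt(model_r2(tr, mu), 0.5)
})
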