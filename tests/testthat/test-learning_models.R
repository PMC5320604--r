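test_that("prediction errors are reward minus prediction", {
  expect_equal(prediction_error(40, 55), 15)
  expect_equal(prediction_error(55, 40), -15)
  expect_equal(prediction_error(35, 35), 0)
  expect_true(is.na(prediction_error(NA, 50)))
})

test_that("PE scaling divides by log(SD)^nu and never amplifies on task SDs", {
  expect_equal(scale_pe(10, 7, 0), 10)          # nu = 0: identity
  expect_equal(scale_pe(10, exp(1), 1), 10)     # ln e = 1
  expect_equal(scale_pe(10, 5, 1), 10 / log(5)) # = 6.2133
  expect_equal(round(scale_pe(10, 5, 1), 4), 6.2133)
  for (s in c(5, 10, 15)) for (nu in c(0.25, 0.5, 1))
    expect_lte(abs(scale_pe(10, s, nu)), 10)
  expect_error(scale_pe(10, 1, 0.5), "sd > 1")
  expect_error(scale_pe(10, 5, 1.5), "nu")
})

test_that("a single RW1 step moves the mean by k times the PE", {
  m <- model_params("RW1", k = 0.3)
  st <- model_step(m, list(mu = 50), 60)
  expect_equal(st$mu, 53)
  expect_equal(st$delta, 10)
})

test_that("model nesting is exact: RW2(k,k) = RW1(k) and PH2(nu=0) = PH1", {
  d <- full_design(seed = 2)
  for (s in 1:5) {
    set.seed(s)
    k <- runif(1); k1 <- runif(1); g <- runif(1)
    rw1 <- predict_series(model_params("RW1", k = k), d, mu_init = 50)
    rw2 <- predict_series(model_params("RW2", k_plus = k, k_minus = k), d,
                          mu_init = 50)
    expect_equal(rw1, rw2)
    ph1 <- predict_series(model_params("PH1", k1 = k1, gamma = g), d,
                          mu_init = 50)
    ph2 <- predict_series(model_params("PH2", k1 = k1, gamma = g, nu = 0), d,
                          mu_init = 50)
    expect_equal(ph1, ph2)
  }
})

test_that("degenerate learning rates give constant or one-step-tracking means", {
  d <- small_design(seed = 3)
  mu0 <- predict_series(model_params("RW1", k = 0), d, mu_init = 50)
  expect_true(all(mu0 == 50))
  mu1 <- predict_series(model_params("RW1", k = 1), d, mu_init = 50)
  for (id in unique(d$dist_id)) {
    rows <- which(d$dist_id == id)
    expect_equal(mu1[rows][-1], d$reward[rows][-length(rows)])
  }
})

test_that("the compiled recursion matches a literal fold of model_step", {
  d <- full_design(seed = 4)
  models <- list(
    model_params("RW1", k = 0.37),
    model_params("RW2", k_plus = 0.6, k_minus = 0.25),
    model_params("PH1", k1 = 0.7, gamma = 0.3),
    model_params("PH2", k1 = 0.55, gamma = 0.45, nu = 0.8))
  for (m in models)
    expect_equal(predict_series(m, d, mu_init = 50), oracle_mu_series(m, d))
})

test_that("Pearce-Hall predictions stabilise on a constant reward stream", {
  d <- small_design(seed = 5)
  d$reward <- 40
  m <- model_params("PH1", k1 = 0.8, gamma = 0.4)
  mu <- oracle_mu_series(m, d, mu_init = 60)  # independent oracle path
  last <- mu[d$dist_id == d$dist_id[1]]
  expect_lt(abs(last[length(last)] - 40), 1)
  # and the rate itself decays towards 0 once PEs vanish
  st <- list(mu = 40, k = 0.8)
  for (i in 1:50) st <- model_step(m, st, 40)
  expect_lt(st$k, 1e-3)
  expect_equal(st$mu, 40)
})

test_that("predicted means stay on the 0-100 scale for any admissible parameters", {
  d <- full_design(seed = 6)
  for (s in 1:10) {
    set.seed(s)
    m <- model_params("PH2", k1 = runif(1), gamma = runif(1), nu = runif(1))
    mu <- predict_series(m, d, mu_init = runif(1, 0, 100))
    expect_true(all(mu >= 0 & mu <= 100))
    m2 <- model_params("RW2", k_plus = runif(1), k_minus = runif(1))
    mu2 <- predict_series(m2, d, mu_init = runif(1, 0, 100))
    expect_true(all(mu2 >= 0 & mu2 <= 100))
  }
})

test_that("PE scaling dampens updates more at larger SD (adaptive mechanism)", {
  m <- model_params("PH2", k1 = 0.6, gamma = 0.3, nu = 0.8)
  up5 <- model_step(m, list(mu = 50, k = 0.6), 60, 5)$mu - 50
  up15 <- model_step(m, list(mu = 50, k = 0.6), 60, 15)$mu - 50
  expect_lt(up15, up5)
  expect_gt(up15, 0)
})

test_that("the PH learning rate settles below its start on i.i.d. rewards", {
  set.seed(8)
  m <- model_params("PH1", k1 = 0.9, gamma = 0.3)
  st <- list(mu = 50, k = 0.9)
  ks <- numeric(500)
  for (i in 1:500) {
    st <- model_step(m, st, rnorm(1, 50, 10))
    ks[i] <- st$k
  }
  expect_lt(mean(ks[201:500]), 0.9)
  # stationary band, not a drift: both halves fluctuate about the same level
  expect_lt(abs(mean(ks[201:350]) - mean(ks[351:500])), 0.1)
})

test_that("simulated agents are deterministic and unbiased around the latent mean", {
  m0 <- model_params("RW1", k = 0, sigma = 1e-12)
  d <- small_design(seed = 9)
  tr <- simulate_agent(m0, d, seed = 1)
  expect_true(all(tr$prediction == 50))
  m <- model_params("PH2", k1 = 0.6, gamma = 0.3, nu = 0.5, sigma = 4)
  a <- simulate_agent(m, d, seed = 2)
  b <- simulate_agent(m, d, seed = 2)
  expect_identical(a, b)
  expect_equal(a$pe, a$reward - a$prediction)
  expect_true(all(a$payoff[a$is_control] %in% c(2.5, 5, 7.5)))
  expect_equal(a$payoff[!a$is_control], round(0.1 * a$reward[!a$is_control], 1))
  # large-n: mean emitted prediction converges to the noise-free trajectory
  m_lo <- model_params("RW1", k = 0.4, sigma = 3)
  ref <- simulate_agent(model_params("RW1", k = 0.4, sigma = 1e-12), d,
                        seed = 0)$prediction
  acc <- rowMeans(vapply(1:300, function(s)
    simulate_agent(m_lo, d, seed = s)$prediction, numeric(nrow(d))))
  expect_lt(max(abs(acc - ref)), 1.5)
})

test_that("missed trials carry no prediction, reward, PE or payoff", {
  m <- model_params("RW1", k = 0.5, sigma = 3)
  tr <- simulate_agent(m, full_design(seed = 10), seed = 3, miss_prob = 0.2)
  expect_gt(sum(tr$missed), 0)
  expect_true(all(is.na(tr$prediction[tr$missed])))
  expect_true(all(is.na(tr$reward[tr$missed])))
  expect_true(all(is.na(tr$pe[tr$missed])))
  expect_true(all(tr$payoff[tr$missed] == 0))
})
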