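test_that("the Gaussian log-likelihood matches its closed form", {
  expect_equal(gaussian_loglik(5, 5, 1), -0.5 * log(2 * pi))
  expect_equal(round(gaussian_loglik(5, 5, 1), 4), -0.9189)
  expect_equal(gaussian_loglik(10, 12, 4), -0.5 * log(8 * pi) - 0.5)
  expect_equal(round(gaussian_loglik(10, 12, 4), 4), -2.1121)
  # doubling the variance at zero residual costs (M/2) log 2
  y <- rep(3, 10)
  expect_equal(gaussian_loglik(y, y, 2) - gaussian_loglik(y, y, 1),
               -5 * log(2))
  expect_error(gaussian_loglik(1:3, 1:2, 1), "equal length")
  expect_error(gaussian_loglik(1, 1, 0), "sigma2")
})

test_that("the profiled variance is the mean squared residual with a floor", {
  expect_equal(profile_sigma(c(-1, 1), c(0, 0)), 1)
  expect_equal(profile_sigma(c(3, 4), c(0, 0)), 12.5)
  expect_equal(profile_sigma(c(5, 5, 5), c(5, 5, 5)), 1e-4)  # degenerate floor
  expect_error(profile_sigma(5, 5), "at least two")
})

test_that("profiling sigma equals joint maximisation over (theta, sigma)", {
  m <- model_params("RW1", k = 0.5, sigma = 3)
  tr <- simulated_agent(m, seed = 21)
  mu <- predict_series(model_params("RW1", k = 0.4), tr, mu_init = NULL)
  ok <- !is.na(mu) & !is.na(tr$prediction)
  s2_hat <- profile_sigma(tr$prediction[ok], mu[ok])
  ll_prof <- gaussian_loglik(tr$prediction[ok], mu[ok], s2_hat)
  for (s2 in c(0.5, 1, 2, 5, 10, 20) * s2_hat)
    expect_lte(gaussian_loglik(tr$prediction[ok], mu[ok], s2), ll_prof + 1e-10)
})

test_that("fitting recovers RW1 and reaches at least the truth's likelihood", {
  m <- model_params("RW1", k = 0.5, sigma = 3)
  tr <- simulated_agent(m, seed = 22)
  f <- fit_model("RW1", tr, restarts = 10, seed = 1)
  expect_lt(abs(f$params$k - 0.5), 0.1)
  ll_true <- adaptivepe:::profiled_loglik(c(k = 0.5), "RW1", tr)
  expect_gte(f$loglik, ll_true - 1e-6)
  expect_equal(f$aic, 2 * f$n_free - 2 * f$loglik)
  expect_equal(f$bic, f$n_free * log(f$n_obs) - 2 * f$loglik)
  expect_equal(f$n_free, 2L)
  expect_true(f$converged)
})

test_that("fitting the asymmetric model to symmetric data gives k_plus = k_minus", {
  m <- model_params("RW1", k = 0.45, sigma = 3)
  tr <- simulated_agent(m, seed = 23)
  f <- fit_model("RW2", tr, restarts = 10, seed = 2)
  expect_lt(abs(f$params$k_plus - f$params$k_minus), 0.12)
})

test_that("identical options and seed give bit-identical fits", {
  m <- model_params("PH2", k1 = 0.6, gamma = 0.3, nu = 0.6, sigma = 3)
  tr <- simulated_agent(m, seed = 24)
  a <- fit_model("PH2", tr, restarts = 8, seed = 9)
  b <- fit_model("PH2", tr, restarts = 8, seed = 9)
  expect_identical(a, b)
})

test_that("the grid oracle brackets the optimiser", {
  m <- model_params("RW1", k = 0.5, sigma = 3)
  tr <- simulated_agent(m, seed = 25)
  g <- grid_oracle("RW1", tr, list(k = seq(0, 1, length.out = 21)))
  expect_equal(g$n_points, 21)
  # argmax within one grid step of the generating rate
  expect_lte(abs(g$params[1] - 0.5), 0.05 + 1e-9)
  f <- fit_model("RW1", tr, restarts = 6, seed = 3)
  expect_gte(f$loglik, g$loglik - 1e-3)
  # a single-point grid returns that point
  g1 <- grid_oracle("RW1", tr, list(k = 0.3))
  expect_equal(g1$params, 0.3)
  expect_error(grid_oracle("RW1", tr, list(bad = 1)), "grid_spec")
})

test_that("fitted likelihoods are monotone along the nesting chains", {
  m <- model_params("PH2", k1 = 0.6, gamma = 0.3, nu = 0.7, sigma = 4)
  for (s in 1:3) {
    tr <- simulated_agent(m, seed = 30 + s)
    fits <- lapply(c("RW1", "RW2", "PH1", "PH2"), fit_model, trials = tr,
                   restarts = 10, seed = s)
    ll <- setNames(vapply(fits, `[[`, numeric(1), "loglik"),
                   vapply(fits, `[[`, character(1), "model_id"))
    expect_gte(ll["RW2"], ll["RW1"] - 1e-6)
    expect_gte(ll["PH2"], ll["PH1"] - 1e-6)
  }
})

test_that("model comparison orients pairwise deltas and breaks ties by parsimony", {
  mk <- function(agent, model, ll, p, M = 100) {
    data.frame(agent_id = agent, model_id = model, loglik = ll, n_free = p,
               n_obs = M, aic = 2 * p - 2 * ll, bic = p * log(M) - 2 * ll,
               stringsAsFactors = FALSE)
  }
  # identical likelihood and complexity in two models: delta is exactly 0
  df <- rbind(mk("a1", "RW1", -100, 2), mk("a1", "RW2", -100, 2),
              mk("a2", "RW1", -120, 2), mk("a2", "RW2", -120, 2))
  cmp <- compare_models(df)
  expect_equal(cmp$d_aic["RW2", "RW1"], 0)
  expect_equal(cmp$d_bic["RW2", "RW1"], 0)
  # ties go to the model with fewer parameters
  df2 <- rbind(mk("a1", "RW1", -100, 2), mk("a1", "RW2", -97.67834, 3))
  df2$bic <- df2$n_free * log(df2$n_obs) - 2 * df2$loglik
  df2$bic <- rep(min(df2$bic), 2)  # force an exact tie on BIC
  cmp2 <- compare_models(df2)
  expect_equal(cmp2$best$best_model, "RW1")
  # missing fits are an error
  expect_error(compare_models(mk("a1", "RW1", -100, 2)[0, ]))
  expect_error(compare_models(rbind(mk("a1", "RW1", -100, 2),
                                    mk("a1", "RW2", -99, 3),
                                    mk("a2", "RW1", -100, 2))),
               "missing fits|missing")
})

test_that("fit_model refuses sparse data and reports observation counts", {
  m <- model_params("RW1", k = 0.5, sigma = 3)
  tr <- simulated_agent(m, seed = 26)
  expect_error(fit_model("RW1", tr[1:20, ]), "30")
  f <- fit_model("RW1", tr, restarts = 4, seed = 1)
  expect_equal(f$n_obs, sum(!tr$missed & !is.na(tr$prediction)))
})
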