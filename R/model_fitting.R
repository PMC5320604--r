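#' Gaussian observation log-likelihood
#'
#' Sum of Gaussian log densities of observed predictions around the
#' model-predicted means, in nats.
#'
#' @param y observed predictions.
#' @param mu model-predicted means (same length).
#' @param sigma2 observation variance (> 0).
#' @return Log-likelihood in nats.
#' @export
gaussian_loglik <- function(y, mu, sigma2) {
  if (length(y) != length(mu)) stop("y and mu must have equal length")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  sum(dnorm(y, mu, sqrt(sigma2), log = TRUE))
}

#' Profiled observation variance
#'
#' The Gaussian maximum-likelihood estimate of the observation variance is
#' the mean squared residual; profiling it out analytically leaves the
#' outer optimisation over the learning parameters only. A small floor
#' guards against degenerate (noiseless) input.
#'
#' @param y observed predictions.
#' @param mu model-predicted means.
#' @param floor minimum admissible variance.
#' @return The profiled variance estimate.
#' @export
profile_sigma <- function(y, mu, floor = 1e-4) {
  ok <- !is.na(y) & !is.na(mu)
  if (sum(ok) < 2) stop("need at least two observed (y, mu) pairs")
  max(mean((y[ok] - mu[ok])^2), floor)
}

# rows usable for the likelihood: non-missed, prediction observed
usable_rows <- function(trials) {
  m <- as.logical(trials$missed)
  m[is.na(m)] <- FALSE
  !m & !is.na(trials$prediction) & !is.na(trials$reward)
}

# profiled log-likelihood of a rate-parameter vector for one model
profiled_loglik <- function(theta, model_id, trials, sigma_floor = 1e-4) {
  names(theta) <- model_par_names(model_id)
  model <- do.call(model_params, c(list(model_id = model_id), as.list(theta),
                                   list(sigma = 1)))
  mu <- predict_series(model, trials, mu_init = NULL)
  ok <- usable_rows(trials) & !is.na(mu)
  s2 <- profile_sigma(trials$prediction[ok], mu[ok], sigma_floor)
  gaussian_loglik(trials$prediction[ok], mu[ok], s2)
}

#' Fit one learning model to one agent's trial table
#'
#' Maximum-likelihood estimation with the observation variance profiled out
#' analytically. The learning parameters are optimised by bounded
#' multi-start local search (`L-BFGS-B` on the unit box): starting points
#' are a Latin hypercube over the parameter box plus the box centre, and -
#' for the adaptive model - a start on the no-scaling boundary `nu = 0`,
#' where genuine boundary maxima occur. Each distribution's initial
#' predicted mean is anchored at its first observed prediction.
#'
#' @param model_id one of `"RW1"`, `"RW2"`, `"PH1"`, `"PH2"`.
#' @param trials trial table with predictions (>= 30 usable trials).
#' @param restarts number of optimisation starts.
#' @param seed integer seed controlling the start set.
#' @param sigma_floor variance floor passed to [profile_sigma()].
#' @return A `fit_result` list: fitted `params` (including the profiled
#'   `sigma`), `loglik` (nats), `n_free` (sigma counted as free), `n_obs`,
#'   `aic`, `bic`, `n_restarts`, `converged` (two or more starts agree
#'   within 1e-4 nats), and `best_start`.
#' @export
fit_model <- function(model_id, trials, restarts = 20L, seed = 1L,
                      sigma_floor = 1e-4) {
  model_id <- match.arg(model_id, MODEL_IDS)
  trials <- trials[order(trials$session, trials$trial), ]
  if (sum(usable_rows(trials)) < 30)
    stop("fit_model needs at least 30 usable (non-missed) trials")
  par_names <- model_par_names(model_id)
  npar <- length(par_names)

  set.seed(derive_seed(seed, "fit"))
  starts <- lhs::randomLHS(max(restarts - 1L, 1L), npar)
  starts <- rbind(rep(0.5, npar), starts)
  # boundary basins are genuine maxima here: nu = 0 (no scaling) and
  # gamma = 0 (constant rate, RW-like) deserve dedicated starts
  if (model_id == "PH2" && restarts >= 3) starts[2, npar] <- 0
  if (model_id %in% c("PH1", "PH2") && restarts >= 4) starts[3, 2] <- 0
  starts <- starts[seq_len(min(restarts, nrow(starts))), , drop = FALSE]

  neg_obj <- function(theta) -profiled_loglik(theta, model_id, trials, sigma_floor)
  runs <- apply(starts, 1, function(s) {
    fit <- tryCatch(
      optim(s, neg_obj, method = "L-BFGS-B", lower = rep(0, npar),
            upper = rep(1, npar), control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) list(value = Inf, par = s) else fit
  })
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(values))) stop("optimiser failed on every restart")
  best <- which.min(values)
  theta <- runs[[best]]$par
  # derivative-free polish: L-BFGS-B can stall on the kinked |PE| surface
  if (npar > 1) {
    clamped <- function(th) neg_obj(pmin(pmax(th, 0), 1))
    pol <- tryCatch(optim(theta, clamped, method = "Nelder-Mead",
                          control = list(maxit = 400)),
                    error = function(e) NULL)
    if (!is.null(pol) && pol$value < values[best]) {
      theta <- pmin(pmax(pol$par, 0), 1)
      values[best] <- pol$value
    }
  }
  names(theta) <- par_names

  model <- do.call(model_params, c(list(model_id = model_id), as.list(theta),
                                   list(sigma = 1)))
  mu <- predict_series(model, trials, mu_init = NULL)
  ok <- usable_rows(trials) & !is.na(mu)
  s2 <- profile_sigma(trials$prediction[ok], mu[ok], sigma_floor)
  ll <- gaussian_loglik(trials$prediction[ok], mu[ok], s2)
  model$sigma <- sqrt(s2)
  M <- sum(ok)
  n_free <- npar + 1L  # sigma counted as free even though profiled
  sorted <- sort(values[is.finite(values)])
  converged <- length(sorted) >= 2 && (sorted[2] - sorted[1]) <= 1e-4

  structure(list(
    agent_id = if (!is.null(trials$agent_id)) trials$agent_id[1] else NA_character_,
    model_id = model_id, params = model, loglik = ll, n_free = n_free,
    n_obs = M, aic = 2 * n_free - 2 * ll, bic = n_free * log(M) - 2 * ll,
    n_restarts = nrow(starts), converged = converged,
    best_start = starts[best, ]
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  pars <- unlist(unclass(x$params)[model_par_names(x$model_id)])
  cat(sprintf("%s fit for %s: logLik %.2f (M = %d), AIC %.1f, BIC %.1f\n",
              x$model_id, x$agent_id, x$loglik, x$n_obs, x$aic, x$bic))
  cat("  ", paste(sprintf("%s = %.3f", names(pars), pars), collapse = ", "),
      sprintf(", sigma = %.3f\n", x$params$sigma))
  invisible(x)
}

#' Brute-force grid oracle for the profiled likelihood
#'
#' Exhaustively evaluates the profiled log-likelihood on a parameter grid.
#' Serves as an independent check on the optimiser: the optimiser's
#' log-likelihood must reach at least the best grid value (up to grid
#' resolution).
#'
#' @param model_id model identifier.
#' @param trials trial table with predictions.
#' @param grid_spec named list of grid vectors, one per rate parameter of
#'   the model (at most 1e5 combinations).
#' @return List with `params` (best grid point), `loglik`, and `n_points`.
#' @export
grid_oracle <- function(model_id, trials, grid_spec) {
  model_id <- match.arg(model_id, MODEL_IDS)
  par_names <- model_par_names(model_id)
  if (!setequal(names(grid_spec), par_names))
    stop("grid_spec must name exactly: ", paste(par_names, collapse = ", "))
  grid <- expand.grid(grid_spec[par_names])
  if (nrow(grid) > 1e5) stop("grid too large (> 1e5 points)")
  trials <- trials[order(trials$session, trials$trial), ]
  ll <- apply(as.matrix(grid), 1, function(theta)
    profiled_loglik(theta, model_id, trials))
  best <- which.max(ll)
  list(params = as.numeric(grid[best, ]), par_names = par_names,
       loglik = ll[best], n_points = nrow(grid))
}

#' Collect fit results into a data frame
#'
#' @param fits list of `fit_result` objects.
#' @return Data frame with one row per fit and columns for every parameter
#'   (NA where not applicable), likelihood and information criteria.
#' @export
fits_to_df <- function(fits) {
  all_pars <- c("k", "k_plus", "k_minus", "k1", "gamma", "nu")
  rows <- lapply(fits, function(f) {
    p <- unclass(f$params)
    row <- data.frame(agent_id = f$agent_id, model_id = f$model_id,
                      stringsAsFactors = FALSE)
    for (nm in all_pars) row[[nm]] <- if (!is.null(p[[nm]])) p[[nm]] else NA_real_
    row$sigma <- p$sigma
    row$loglik <- f$loglik; row$n_free <- f$n_free; row$n_obs <- f$n_obs
    row$aic <- f$aic; row$bic <- f$bic; row$converged <- f$converged
    row
  })
  do.call(rbind, rows)
}

#' Pairwise AIC/BIC model comparison across agents
#'
#' For every ordered model pair, the mean across agents of the row model's
#' criterion minus the column model's criterion; negative values favour the
#' row model. Also reports each agent's best model by the chosen criterion,
#' with ties broken towards the model with fewer parameters.
#'
#' @param fit_df data frame from [fits_to_df()] with all models per agent.
#' @param criterion criterion used for best-model selection.
#' @return List with matrices `d_aic` and `d_bic` (rows/columns in model
#'   order, lower-triangle orientation), and `best` (per-agent winner).
#' @export
compare_models <- function(fit_df, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (is.null(fit_df) || nrow(fit_df) == 0) stop("missing fits: empty input")
  models <- MODEL_IDS[MODEL_IDS %in% unique(fit_df$model_id)]
  agents <- unique(fit_df$agent_id)
  for (a in agents) {
    have <- fit_df$model_id[fit_df$agent_id == a]
    if (!all(models %in% have))
      stop("agent ", a, " is missing fits for: ",
           paste(setdiff(models, have), collapse = ", "))
  }
  get <- function(crit) {
    m <- matrix(NA_real_, length(models), length(models),
                dimnames = list(models, models))
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i == j) next
      ci <- fit_df[[crit]][fit_df$model_id == models[i]][
        match(agents, fit_df$agent_id[fit_df$model_id == models[i]])]
      cj <- fit_df[[crit]][fit_df$model_id == models[j]][
        match(agents, fit_df$agent_id[fit_df$model_id == models[j]])]
      m[i, j] <- mean(ci - cj)
    }
    m
  }
  best <- vapply(agents, function(a) {
    sub <- fit_df[fit_df$agent_id == a, ]
    crit <- sub[[criterion]]
    cand <- which(crit <= min(crit) + 1e-12)
    if (length(cand) > 1) cand <- cand[which.min(sub$n_free[cand])]
    sub$model_id[cand]
  }, character(1))
  list(d_aic = get("aic"), d_bic = get("bic"),
       best = data.frame(agent_id = agents, best_model = best,
                         stringsAsFactors = FALSE))
}

#' Fit several models to every agent in a cohort
#'
#' @param trials trial table containing one or more `agent_id`s.
#' @param models character vector of model identifiers.
#' @param restarts,seed passed to [fit_model()]; each agent gets its own
#'   derived seed, so cohort composition does not perturb other agents.
#' @return Data frame of fits (see [fits_to_df()]).
#' @export
fit_cohort <- function(trials, models = MODEL_IDS, restarts = 20L, seed = 1L) {
  agents <- unique(trials$agent_id)
  fits <- list()
  for (i in seq_along(agents)) {
    sub <- trials[trials$agent_id == agents[i], ]
    for (m in models) {
      fits[[length(fits) + 1L]] <-
        fit_model(m, sub, restarts = restarts,
                  seed = derive_seed(seed, paste0("fit_", m), i))
    }
  }
  fits_to_df(fits)
}
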