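MODEL_IDS <- c("RW1", "RW2", "PH1", "PH2")

#' Construct a learning-model parameter set
#'
#' The four models share the delta-rule skeleton mu' = mu + k_n * delta but
#' differ in the learning rate k_n:
#' \describe{
#'   \item{RW1}{Rescorla-Wagner, constant rate `k`.}
#'   \item{RW2}{Rescorla-Wagner with separate rates `k_plus` / `k_minus`
#'     for positive and negative prediction errors.}
#'   \item{PH1}{Pearce-Hall: the rate evolves with the recent absolute PE,
#'     `k_n = (1 - gamma) k_(n-1) + gamma |delta|/20` (clipped to \[0, 1\];
#'     20 GBP is the reference error at which the drive saturates),
#'     initialised at `k1`.}
#'   \item{PH2}{Adaptive Pearce-Hall: as PH1, but the PE entering the
#'     update is divided by `log(SD)^nu`, so larger reward variability
#'     restrains learning. `nu = 0` means no scaling (identical to PH1).}
#' }
#' `sigma` is the Gaussian response-noise SD of the observation model shared
#' by all models.
#'
#' @param model_id one of `"RW1"`, `"RW2"`, `"PH1"`, `"PH2"`.
#' @param k,k_plus,k_minus,k1,gamma,nu rate-type parameters in \[0, 1\].
#' @param sigma response-noise SD in GBP, > 0.
#' @return An object of class `model_params` (a named list).
#' @export
model_params <- function(model_id, k = NULL, k_plus = NULL, k_minus = NULL,
                         k1 = NULL, gamma = NULL, nu = NULL, sigma = 3) {
  model_id <- match.arg(model_id, MODEL_IDS)
  need <- model_par_names(model_id)
  given <- list(k = k, k_plus = k_plus, k_minus = k_minus,
                k1 = k1, gamma = gamma, nu = nu)
  vals <- given[need]
  missing <- need[vapply(vals, is.null, logical(1))]
  if (length(missing))
    stop(model_id, " requires parameter(s): ", paste(missing, collapse = ", "))
  vals <- unlist(vals)
  if (any(vals < 0 | vals > 1))
    stop("rate-type parameters must lie in [0, 1]")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(c(as.list(vals), list(sigma = sigma, model_id = model_id)),
            class = "model_params")
}

# free rate-type parameters per model (sigma handled separately)
model_par_names <- function(model_id) {
  switch(model_id,
         RW1 = "k",
         RW2 = c("k_plus", "k_minus"),
         PH1 = c("k1", "gamma"),
         PH2 = c("k1", "gamma", "nu"),
         stop("unknown model_id: ", model_id))
}

model_code <- function(model_id) match(model_id, MODEL_IDS)

#' Trial prediction error
#'
#' @param y predicted reward in GBP.
#' @param r received reward in GBP.
#' @return `r - y`; `NA` when either input is missing.
#' @export
prediction_error <- function(y, r) r - y

#' Scale a prediction error by reward variability
#'
#' Divides the PE by `(D * log(sd))^nu` (natural log). `nu = 0` leaves the
#' PE untouched; `nu = 1` applies the full log-SD scaling. With the task's
#' SDs (5, 10, 15) the divisor exceeds 1, so scaling always shrinks the PE.
#'
#' @param delta prediction error in GBP.
#' @param sd_nominal distribution SD in GBP, must exceed 1.
#' @param nu scaling extent in \[0, 1\].
#' @param D fixed scaling coefficient (default 1).
#' @return Scaled PE (vectorised over `delta`).
#' @export
scale_pe <- function(delta, sd_nominal, nu, D = 1) {
  if (any(sd_nominal <= 1))
    stop("scale_pe requires sd > 1 (log(sd) must be positive)")
  if (any(nu < 0 | nu > 1)) stop("nu must lie in [0, 1]")
  delta / (D * log(sd_nominal))^nu
}

#' One learning-model update step
#'
#' Applies a single trial's reward to the learner state: computes the PE
#' `delta = r - mu`, updates the learning rate (PH models), and moves the
#' predicted mean by the (possibly scaled) PE. The new mean is clipped to
#' the 0-100 GBP scale.
#'
#' @param model a [model_params()] object.
#' @param state list with `mu` (predicted mean) and, for PH models, `k`
#'   (current learning rate).
#' @param r reward in GBP.
#' @param sd_nominal distribution SD (used by PH2 only).
#' @return Updated state list (`mu`, `k`, `delta`).
#' @export
model_step <- function(model, state, r, sd_nominal = NA_real_) {
  delta <- r - state$mu
  id <- model$model_id
  if (id == "RW1") {
    upd <- model$k * delta
  } else if (id == "RW2") {
    upd <- if (delta >= 0) model$k_plus * delta else model$k_minus * delta
  } else {
    # associability: recent absolute PEs relative to a 20-GBP reference
    # error drive the rate, which decays with constant gamma
    k <- min(1, (1 - model$gamma) * state$k + model$gamma * (abs(delta) / 20))
    state$k <- k
    eff <- if (id == "PH2") scale_pe(delta, sd_nominal, model$nu) else delta
    upd <- k * eff
  }
  state$mu <- min(max(state$mu + upd, 0), 100)
  state$delta <- delta
  state
}

# initial learner state for a model
init_state <- function(model, mu_init) {
  st <- list(mu = mu_init, delta = NA_real_)
  if (model$model_id %in% c("PH1", "PH2")) st$k <- model$k1
  st
}

#' Predicted-mean series over a trial table
#'
#' Folds the model recursion over the observed rewards, keeping one learner
#' state per distribution (the cue identifies which "pot" is active, so
#' predictions are pot-specific). Missed trials leave the state untouched
#' and receive an `NA` predicted mean. The series gives, for each trial,
#' the model's predicted mean before that trial's reward is revealed.
#'
#' @param model a [model_params()] object.
#' @param trials trial-table data frame, sorted by session and trial,
#'   with rewards on non-missed rows.
#' @param mu_init either a single number used for every distribution, or
#'   `NULL` to anchor each distribution's initial mean at its first
#'   observed prediction (the convention used in fitting, which removes an
#'   unidentified initial condition).
#' @param anchor `"latent"` folds the recursion forward on its own state
#'   (pure simulation of the model); `"observed"` steps each update from
#'   the observed prediction, so the PE entering the update is the one the
#'   agent actually saw on screen. Fitting uses `"observed"`, the
#'   one-step-ahead conditional form matching the generative process of
#'   [simulate_agent()].
#' @return Numeric vector of predicted means, `NA` on missed trials.
#' @export
predict_series <- function(model, trials, mu_init = NULL,
                           anchor = c("latent", "observed")) {
  anchor <- match.arg(anchor)
  o <- order(trials$session, trials$trial)
  if (any(o != seq_along(o))) stop("trials must be sorted by session, trial")
  ids <- unique(trials$dist_id)
  dist_index <- match(trials$dist_id, ids)
  missed <- as.logical(trials$missed)
  missed[is.na(missed)] <- FALSE
  if (is.null(mu_init)) {
    mu0 <- vapply(ids, function(id) {
      y <- trials$prediction[trials$dist_id == id & !missed]
      y <- y[!is.na(y)]
      if (!length(y)) stop("no observed prediction to anchor mu_init for ", id)
      y[1]
    }, numeric(1))
  } else {
    mu0 <- rep(mu_init, length(ids))
  }
  pars <- unlist(unclass(model)[model_par_names(model$model_id)])
  preds <- if (!is.null(trials$prediction)) as.numeric(trials$prediction) else
    rep(NA_real_, nrow(trials))
  mu <- mu_series_cpp(model_code(model$model_id), as.numeric(pars),
                      as.numeric(trials$reward), as.numeric(trials$sd),
                      as.integer(dist_index), missed, as.numeric(mu0),
                      anchor == "observed", preds)
  mu[missed] <- NA_real_
  mu
}

#' Simulate an agent performing the task
#'
#' Plays a learning model through a generated design: the latent predicted
#' mean follows the model recursion over the observed rewards, and on each
#' trial the agent emits `y = mu + N(0, sigma)` (clipped to the scale,
#' rounded to 0.1 GBP). Response noise is purely observational - it
#' perturbs the stated prediction but not the learning state, the standard
#' observation-model assumption under which the fitted likelihood is
#' correctly specified. The recorded `pe` column is the PE displayed on
#' screen (reward minus the emitted prediction). Missed trials (probability
#' `miss_prob`) emit no prediction, see no reward, skip the update, and
#' earn a payoff of 0.
#'
#' @param model a [model_params()] object.
#' @param design trial table from [generate_experiment()] (rewards present).
#' @param seed integer seed for response noise and misses.
#' @param mu_init initial predicted mean (scale midpoint by default).
#' @param miss_prob per-trial miss probability.
#' @return The design with `prediction`, `missed`, `pe`, `payoff` completed.
#' @export
simulate_agent <- function(model, design, seed = 1L, mu_init = 50,
                           miss_prob = 0) {
  set.seed(derive_seed(seed, "agent"))
  design <- design[order(design$session, design$trial), ]
  n <- nrow(design)
  miss <- if (miss_prob > 0) runif(n) < miss_prob else rep(FALSE, n)
  noise <- rnorm(n, 0, model$sigma)
  design$missed <- miss
  mu <- predict_series(model, design, mu_init = mu_init)
  y <- round(pmin(pmax(mu + noise, 0), 100), 1)
  y[miss] <- NA_real_
  design$prediction <- y
  design$pe <- ifelse(miss, NA_real_, design$reward - y)
  design$payoff <- ifelse(miss, 0,
                          ifelse(design$is_control,
                                 control_payoff(y, design$ev, design$sd),
                                 test_payoff(design$reward)))
  design$payoff <- round(design$payoff, 1)
  design$reward[miss] <- NA_real_
  design
}
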