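# Shared fixtures: all synthetic, built in code at test time.

# a compact design (3 sessions x 20 trials) for fast unit tests
small_design <- function(seed = 1L) {
  generate_experiment(task_config(trials_per_dist = 10L), seed = seed)
}

# full-scale design (186 trials), the published geometry
full_design <- function(seed = 1L) generate_experiment(seed = seed)

# simulate one agent of the given model on a fresh design
simulated_agent <- function(model, seed = 1L, design = full_design(seed)) {
  simulate_agent(model, design, seed = seed)
}

# independent R-level oracle for the model recursion (latent form):
# a literal fold of model_step, kept free of the compiled path
oracle_mu_series <- function(model, trials, mu_init = 50) {
  states <- lapply(unique(trials$dist_id), function(id) {
    st <- list(mu = mu_init)
    if (model$model_id %in% c("PH1", "PH2")) st$k <- model$k1
    st
  })
  names(states) <- unique(trials$dist_id)
  mu <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    id <- trials$dist_id[t]
    mu[t] <- states[[id]]$mu
    if (isTRUE(trials$missed[t])) next
    states[[id]] <- model_step(model, states[[id]], trials$reward[t],
                               trials$sd[t])
  }
  mu
}
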