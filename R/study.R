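TRIAL_COLUMNS <- c("agent_id", "session", "block", "trial", "dist_id", "ev",
                   "sd", "cue_level", "is_control", "reward", "prediction",
                   "missed", "pe", "payoff")

#' Write a trial table to CSV
#'
#' Fixed column order, missing values as empty strings.
#'
#' @param trials trial-table data frame.
#' @param path output file path.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE, na = "")
}

#' Read and validate a trial table from CSV
#'
#' Checks the declared schema and value ranges; violations are reported
#' with their row numbers.
#'
#' @param path CSV file with the trial-table header.
#' @return Validated trial-table data frame.
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(trials) == 0) stop("empty trial table: ", path)
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  trials$is_control <- as.logical(trials$is_control)
  trials$missed <- as.logical(trials$missed)
  problems <- character(0)
  bad_range <- function(x) which(!is.na(x) & (x < 0 | x > 100))
  for (col in c("reward", "prediction")) {
    rows <- bad_range(trials[[col]])
    if (length(rows))
      problems <- c(problems, paste0(col, " outside [0, 100] at row(s): ",
                                     paste(utils::head(rows, 10), collapse = ", ")))
  }
  ok <- !trials$missed & !is.na(trials$pe) & !is.na(trials$prediction) &
    !is.na(trials$reward)
  rows <- which(ok & abs(trials$pe - (trials$reward - trials$prediction)) > 1e-6)
  if (length(rows))
    problems <- c(problems, paste0("pe != reward - prediction at row(s): ",
                                   paste(utils::head(rows, 10), collapse = ", ")))
  if (length(problems))
    stop("invalid trial table ", path, ":\n  ", paste(problems, collapse = "\n  "))
  trials
}

#' Default full-study configuration
#'
#' Defaults reproduce the study structure: three treatment groups (placebo,
#' sulpiride, bromocriptine) of 19 agents each, the standard task design
#' (186 trials), adaptive Pearce-Hall agents whose parameter regimes follow
#' the reported group differences (fewer scalers and lower initial learning
#' rates under sulpiride), group-dependent neural adaptation strengths
#' (weakest under sulpiride), and a dose-to-scan-time covariate that
#' differs slightly between groups.
#'
#' @param n_per_group agents per treatment group.
#' @param restarts optimisation restarts per model fit.
#' @return Nested configuration list.
#' @export
study_config <- function(n_per_group = 19L, restarts = 20L) {
  list(
    task = task_config(),
    cohort = list(
      groups = c("placebo", "sulpiride", "bromocriptine"),
      n_per_group = as.integer(n_per_group),
      regimes = list(
        placebo = list(nu_zero_prob = 0.10, nu_range = c(0.4, 1.0),
                       k1_range = c(0.5, 0.9), gamma_range = c(0.1, 0.5),
                       sigma_range = c(3, 6), adaptation_mean = 0.8,
                       dose_to_scan_mean = 150),
        sulpiride = list(nu_zero_prob = 0.40, nu_range = c(0.2, 0.8),
                         k1_range = c(0.35, 0.75), gamma_range = c(0.1, 0.5),
                         sigma_range = c(3, 6), adaptation_mean = 0.15,
                         dose_to_scan_mean = 160),
        bromocriptine = list(nu_zero_prob = 0.15, nu_range = c(0.4, 1.0),
                             k1_range = c(0.45, 0.85), gamma_range = c(0.1, 0.5),
                             sigma_range = c(3, 6), adaptation_mean = 0.7,
                             dose_to_scan_mean = 145)
      ),
      adaptation_sd = 0.1, dose_to_scan_sd = 12, miss_prob = 0
    ),
    neural = list(beta0 = 0, beta_value = 0.02, beta_pe_pos = 0.8,
                  beta_pe_neg = 1.0, noise_sd = 2, slope_jitter_sd = 0.2),
    fitting = list(models = MODEL_IDS, restarts = as.integer(restarts)),
    analysis = list(epsilon = 1e-3, posthoc_alpha = 0.025,
                    covariate = "dose_to_scan")
  )
}

# draw one agent's generating parameters from its group regime
draw_agent_params <- function(regime, neural_cfg, adaptation_sd,
                              dose_to_scan_sd) {
  nu <- if (runif(1) < regime$nu_zero_prob) 0 else
    runif(1, regime$nu_range[1], regime$nu_range[2])
  a <- min(max(rnorm(1, regime$adaptation_mean, adaptation_sd), 0), 1)
  jitter <- exp(rnorm(1, 0, neural_cfg$slope_jitter_sd))
  list(
    model = model_params("PH2",
                         k1 = runif(1, regime$k1_range[1], regime$k1_range[2]),
                         gamma = runif(1, regime$gamma_range[1], regime$gamma_range[2]),
                         nu = nu,
                         sigma = runif(1, regime$sigma_range[1], regime$sigma_range[2])),
    gen = neural_gen_params(beta0 = neural_cfg$beta0,
                            beta_value = neural_cfg$beta_value,
                            beta_pe_pos = neural_cfg$beta_pe_pos * jitter,
                            beta_pe_neg = neural_cfg$beta_pe_neg * jitter,
                            adaptation_strength = a,
                            noise_sd = neural_cfg$noise_sd),
    dose_to_scan = rnorm(1, regime$dose_to_scan_mean, dose_to_scan_sd)
  )
}

#' Simulate a full synthetic cohort
#'
#' For every agent: an independent task design, an adaptive Pearce-Hall
#' agent playing it, and a synthetic ROI response series. Agents get
#' deterministic per-agent seed substreams, so enlarging the cohort never
#' changes earlier agents' data.
#'
#' @param config configuration from [study_config()].
#' @param seed integer study seed.
#' @return List with `trials` (all agents), `agents` (one row per agent:
#'   group, true generating parameters, covariate), and `neural` (ROI
#'   responses, all agents).
#' @export
simulate_cohort <- function(config = study_config(), seed = 1L) {
  cc <- config$cohort
  trials_list <- list(); neural_list <- list(); agent_rows <- list()
  idx <- 0L
  for (g in cc$groups) {
    regime <- cc$regimes[[g]]
    for (i in seq_len(cc$n_per_group)) {
      idx <- idx + 1L
      aseed <- derive_seed(seed, paste0("agent_", g), i)
      set.seed(derive_seed(aseed, "params"))
      ap <- draw_agent_params(regime, config$neural, cc$adaptation_sd,
                              cc$dose_to_scan_sd)
      aid <- sprintf("%s_%02d", g, i)
      design <- generate_experiment(config$task, seed = aseed, agent_id = aid)
      trials <- simulate_agent(ap$model, design, seed = aseed,
                               miss_prob = cc$miss_prob)
      neural <- simulate_roi_responses(trials, ap$gen, seed = aseed)
      trials_list[[idx]] <- trials
      neural_list[[idx]] <- neural
      agent_rows[[idx]] <- data.frame(
        agent_id = aid, group = g, true_k1 = ap$model$k1,
        true_gamma = ap$model$gamma, true_nu = ap$model$nu,
        true_sigma = ap$model$sigma,
        true_adaptation = ap$gen$adaptation_strength,
        dose_to_scan = ap$dose_to_scan, stringsAsFactors = FALSE)
    }
  }
  list(trials = do.call(rbind, trials_list),
       agents = do.call(rbind, agent_rows),
       neural = do.call(rbind, neural_list))
}

#' Run the full synthetic study end to end
#'
#' Chains task simulation, agent simulation, model fitting, model
#' comparison, behavioural statistics, and the neural adaptive-coding
#' analysis, writing every artefact into `out_dir`:
#' `trials.csv`, `agents.csv`, `fits.csv`, `model_comparison_{aic,bic}.csv`,
#' `neural_contrasts.csv`, and `summary.json` (all statistics with their
#' tests and p values, plus the configuration digest and seed).
#'
#' @param config configuration from [study_config()].
#' @param seed integer study seed; the same seed reproduces every output
#'   byte for byte.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary list.
#' @export
run_study <- function(config = study_config(), seed = 1L,
                      out_dir = "study_out", quiet = FALSE) {
  say <- function(...) if (!quiet) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("simulate_cohort", simulate_cohort(config, seed))
  write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
  write.csv(cohort$agents, file.path(out_dir, "agents.csv"), row.names = FALSE)

  fit_df <- stage("fit_models", fit_cohort(
    cohort$trials, models = config$fitting$models,
    restarts = config$fitting$restarts, seed = seed))
  write.csv(fit_df, file.path(out_dir, "fits.csv"), row.names = FALSE)

  comparison <- stage("compare_models", compare_models(fit_df))
  write.csv(comparison$d_aic, file.path(out_dir, "model_comparison_aic.csv"))
  write.csv(comparison$d_bic, file.path(out_dir, "model_comparison_bic.csv"))

  behav <- stage("behavioral_analysis", {
    agents <- cohort$agents
    ph2 <- fit_df[fit_df$model_id == "PH2", ]
    ph2 <- ph2[match(agents$agent_id, ph2$agent_id), ]
    agents$k1 <- ph2$k1; agents$gamma <- ph2$gamma; agents$nu <- ph2$nu
    agents$perf_error <- vapply(agents$agent_id, function(a)
      performance_error(cohort$trials[cohort$trials$agent_id == a, ],
                        by_sd = FALSE), numeric(1))
    agents$model_r2 <- vapply(agents$agent_id, function(a) {
      sub <- cohort$trials[cohort$trials$agent_id == a, ]
      pars <- ph2[ph2$agent_id == a, ]
      m <- model_params("PH2", k1 = pars$k1, gamma = pars$gamma, nu = pars$nu,
                        sigma = pars$sigma)
      model_r2(sub, predict_series(m, sub))
    }, numeric(1))
    eps <- config$analysis$epsilon
    tab <- suppressWarnings(
      scaling_contingency(agents, c("sulpiride", "placebo"), eps))
    # small cohorts can be degenerate (empty scaler column, collinear
    # predictors); report NA rather than aborting the whole study
    chi2 <- tryCatch(pearson_chi2(tab), error = function(e)
      list(statistic = NA_real_, df = 1L, p_value = NA_real_,
           note = conditionMessage(e)))
    regression <- tryCatch(performance_regression(agents, eps)$coefficients,
                           error = function(e)
                             data.frame(term = "unavailable", estimate = NA,
                                        t = NA, p = NA,
                                        note = conditionMessage(e)))
    list(agents = agents,
         contingency = tab,
         chi2 = chi2,
         perf_raw = group_tests(agents$perf_error, agents$group,
                                type = "parametric",
                                posthoc_alpha = config$analysis$posthoc_alpha),
         perf_resid = group_tests(
           residualize(agents$perf_error, agents$dose_to_scan), agents$group,
           type = "parametric", posthoc_alpha = config$analysis$posthoc_alpha),
         r2_tests = group_tests(agents$model_r2, agents$group,
                                type = "parametric",
                                posthoc_alpha = config$analysis$posthoc_alpha),
         regression = regression)
  })
  write.csv(behav$agents, file.path(out_dir, "cohort_metrics.csv"),
            row.names = FALSE)

  neural <- stage("neural_analysis", {
    agents <- behav$agents
    contrast_of <- function(a, signs) {
      sel <- cohort$neural$agent_id == a
      slopes <- estimate_pe_slopes(cohort$neural[sel, ],
                                   cohort$trials[cohort$trials$agent_id == a, ])
      # an agent can lack a slope cell on small designs; drop them from
      # the group tests instead of aborting
      tryCatch(adaptive_contrast(slopes, signs = signs),
               error = function(e) NA_real_)
    }
    contrasts <- vapply(agents$agent_id, contrast_of, numeric(1), signs = "both")
    contrasts_pos <- vapply(agents$agent_id, contrast_of, numeric(1), signs = "pos")
    df <- data.frame(agent_id = agents$agent_id, group = agents$group,
                     adaptive_contrast = contrasts,
                     adaptive_contrast_pos = contrasts_pos,
                     stringsAsFactors = FALSE)
    list(contrasts = df,
         comparison_raw = group_adaptive_comparison(
           contrasts, agents$group,
           posthoc_alpha = config$analysis$posthoc_alpha),
         comparison_resid = group_adaptive_comparison(
           contrasts, agents$group, covariate = agents$dose_to_scan,
           posthoc_alpha = config$analysis$posthoc_alpha),
         comparison_pos = group_adaptive_comparison(
           contrasts_pos, agents$group,
           posthoc_alpha = config$analysis$posthoc_alpha))
  })
  write.csv(neural$contrasts, file.path(out_dir, "neural_contrasts.csv"),
            row.names = FALSE)

  summary <- list(
    seed = seed,
    config_digest = paste0("n_per_group=", config$cohort$n_per_group,
                           ";restarts=", config$fitting$restarts,
                           ";models=", paste(config$fitting$models, collapse = "+")),
    n_agents = nrow(behav$agents),
    model_comparison = list(d_aic = comparison$d_aic, d_bic = comparison$d_bic,
                            best_counts = table(comparison$best$best_model)),
    contingency = behav$contingency, chi2 = behav$chi2,
    performance_raw = behav$perf_raw, performance_residualized = behav$perf_resid,
    model_r2_tests = behav$r2_tests, performance_regression = behav$regression,
    neural_raw = neural$comparison_raw,
    neural_residualized = neural$comparison_resid,
    neural_positive_pe = neural$comparison_pos
  )
  writeLines(format_study_summary(summary), file.path(out_dir, "summary.txt"))
  say("done: ", out_dir)
  invisible(summary)
}

# plain-text rendering of the study summary
format_study_summary <- function(s) {
  fmt_tests <- function(t, label) {
    lines <- sprintf("%s omnibus (%s): statistic = %.3f, p = %.4f%s",
                     label, t$omnibus$method, t$omnibus$statistic,
                     t$omnibus$p_value,
                     if (isTRUE(t$underpowered)) "  [under-powered groups]" else "")
    if (!is.null(t$posthoc))
      lines <- c(lines, sprintf("  post hoc %s: p = %.4f%s", t$posthoc$comparison,
                                t$posthoc$p_value,
                                ifelse(t$posthoc$significant, " *", "")))
    lines
  }
  c(sprintf("synthetic study summary (seed %d; %s)", s$seed, s$config_digest),
    sprintf("agents: %d", s$n_agents),
    "", "pairwise mean dBIC (row model minus column model):",
    utils::capture.output(print(round(s$model_comparison$d_bic, 2))),
    sprintf("best model by BIC: %s",
            paste(names(s$model_comparison$best_counts),
                  s$model_comparison$best_counts, collapse = ", ")),
    "", "scaler contingency (rows sulpiride, placebo; cols non-scaler, scaler):",
    utils::capture.output(print(s$contingency)),
    sprintf("chi-square(df=%d) = %.2f, p = %.4f", s$chi2$df, s$chi2$statistic,
            s$chi2$p_value),
    "",
    fmt_tests(s$performance_raw, "performance error (raw)"),
    fmt_tests(s$performance_residualized, "performance error (residualised)"),
    fmt_tests(s$model_r2_tests, "model R2"),
    "",
    fmt_tests(s$neural_raw, "adaptive contrast (raw)"),
    fmt_tests(s$neural_residualized, "adaptive contrast (residualised)"),
    fmt_tests(s$neural_positive_pe, "adaptive contrast (positive PEs)"),
    sprintf("placebo contrast > 0 (one-sided signed rank): p = %.4f",
            s$neural_raw$ref_positive$p_value))
}
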