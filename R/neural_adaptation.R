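#' Generating parameters for synthetic ROI responses
#'
#' A trial-level forward model for a reward-responsive region of interest:
#' the response at reward delivery is a baseline plus a reward-value term,
#' plus a prediction-error term whose slope depends on the SD condition and
#' on the sign of the PE, plus Gaussian noise. Adaptive coding is
#' controlled by `adaptation_strength`: the PE slope for condition SD `s`
#' is `base * (1 + adaptation_strength * (sd_ref/s - 1))`, so at strength 1
#' slopes are exactly proportional to 1/SD and at strength 0 they are flat.
#' Separate base slopes for positive and negative PEs mirror the commonly
#' larger responses to negative PEs.
#'
#' @param beta0 baseline response (a.u.).
#' @param beta_value reward-value slope (a.u. per GBP).
#' @param beta_pe_pos,beta_pe_neg base PE slopes at the reference SD.
#' @param adaptation_strength in \[0, 1\].
#' @param noise_sd trial noise SD (a.u.), > 0.
#' @param sd_ref reference SD (the smallest task SD).
#' @return An object of class `neural_gen_params`.
#' @export
neural_gen_params <- function(beta0 = 0, beta_value = 0.02,
                              beta_pe_pos = 0.8, beta_pe_neg = 1.0,
                              adaptation_strength = 0.8, noise_sd = 2,
                              sd_ref = 5) {
  stopifnot(noise_sd > 0, adaptation_strength >= 0, adaptation_strength <= 1,
            sd_ref > 0)
  structure(list(beta0 = beta0, beta_value = beta_value,
                 beta_pe_pos = beta_pe_pos, beta_pe_neg = beta_pe_neg,
                 adaptation_strength = adaptation_strength,
                 noise_sd = noise_sd, sd_ref = sd_ref),
            class = "neural_gen_params")
}

# generating PE slope for given SD(s) and sign(s) ("pos"/"neg")
generating_slope <- function(gen, sd_nominal, sign) {
  base <- ifelse(sign == "pos", gen$beta_pe_pos, gen$beta_pe_neg)
  base * (1 + gen$adaptation_strength * (gen$sd_ref / sd_nominal - 1))
}

#' Simulate trial-wise ROI responses
#'
#' Applies the forward model of [neural_gen_params()] to a completed trial
#' table. Trials with a PE of exactly 0 are assigned to the positive-PE
#' cell (a deterministic convention; the event has measure zero under
#' continuous response noise). Missed trials get `NA` responses.
#'
#' @param trials trial table with `pe` and `reward` columns filled.
#' @param gen a [neural_gen_params()] object.
#' @param seed integer seed for the trial noise.
#' @return Data frame `agent_id, session, trial, sd, pe_sign, response`.
#' @export
simulate_roi_responses <- function(trials, gen, seed = 1L) {
  set.seed(derive_seed(seed, "roi"))
  ok <- !is.na(trials$pe)
  sign <- ifelse(trials$pe >= 0, "pos", "neg")
  slope <- generating_slope(gen, trials$sd, sign)
  response <- gen$beta0 + gen$beta_value * trials$reward +
    slope * trials$pe + rnorm(nrow(trials), 0, gen$noise_sd)
  response[!ok] <- NA_real_
  data.frame(agent_id = trials$agent_id, session = trials$session,
             trial = trials$trial, sd = trials$sd,
             pe_sign = ifelse(ok, sign, NA_character_),
             response = response, stringsAsFactors = FALSE)
}

#' Estimate PE coding slopes per SD condition and PE sign
#'
#' Within each SD-by-sign cell, regresses the ROI response on an intercept,
#' the reward outcome value, and the PE, with the PE regressor first
#' residualised against outcome value (serial orthogonalisation). The
#' returned coefficient is the PE slope: response variance that tracks the
#' PE independently of reward magnitude.
#'
#' @param series response data frame from [simulate_roi_responses()].
#' @param trials the matching trial table.
#' @param min_trials minimum trials per cell to attempt estimation.
#' @return Data frame `sd, pe_sign, slope, n`; cells below `min_trials`
#'   get `NA` slopes.
#' @export
estimate_pe_slopes <- function(series, trials, min_trials = 5L) {
  stopifnot(nrow(series) == nrow(trials))
  ok <- !is.na(series$response) & !is.na(trials$pe)
  sds <- sort(unique(trials$sd))
  out <- expand.grid(sd = sds, pe_sign = c("pos", "neg"),
                     stringsAsFactors = FALSE)
  out$slope <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- ok & trials$sd == out$sd[i] & series$pe_sign == out$pe_sign[i]
    out$n[i] <- sum(sel)
    if (out$n[i] < min_trials) next
    value <- trials$reward[sel]
    pe <- trials$pe[sel]
    resp <- series$response[sel]
    pe_orth <- if (sd(value) > 0) resid(lm(pe ~ value)) else pe - mean(pe)
    if (sd(pe_orth) < 1e-10) stop("rank-deficient cell: PE collinear with value")
    fit <- lm(resp ~ value + pe_orth)
    out$slope[i] <- coef(fit)[["pe_orth"]]
  }
  out
}

#' Inverse-SD adaptive-coding contrast weights
#'
#' Weights proportional to 1/SD, mean-centred so they sum to zero (the
#' usual contrast convention: a flat slope profile scores exactly 0, and
#' slopes that fall with SD score positive).
#'
#' @param sds distinct positive SD values.
#' @return Named numeric vector of centred weights, in increasing SD order.
#' @export
contrast_weights <- function(sds = c(5, 10, 15)) {
  if (any(sds <= 0)) stop("SDs must be positive")
  if (anyDuplicated(sds)) stop("SDs must be distinct")
  sds <- sort(sds)
  w <- 1 / sds
  w <- w - mean(w)
  setNames(w, sprintf("SD%g", sds))
}

#' Adaptive-coding contrast for one agent
#'
#' Weighted combination of the estimated PE slopes across SD conditions
#' (weights from [contrast_weights()]), after averaging the slopes over
#' the requested PE signs. Positive values indicate PE coding that scales
#' down as reward variability grows.
#'
#' @param slopes data frame from [estimate_pe_slopes()].
#' @param weights contrast weights; computed from the slopes' SDs if `NULL`.
#' @param signs `"both"`, `"pos"`, or `"neg"`.
#' @return Scalar contrast value.
#' @export
adaptive_contrast <- function(slopes, weights = NULL, signs = c("both", "pos", "neg")) {
  signs <- match.arg(signs)
  use <- if (signs == "both") slopes else slopes[slopes$pe_sign == signs, ]
  sds <- sort(unique(use$sd))
  if (is.null(weights)) weights <- contrast_weights(sds)
  if (length(weights) != length(sds)) stop("weights do not match SD levels")
  per_sd <- vapply(sds, function(s) {
    v <- use$slope[use$sd == s]
    if (any(is.na(v))) stop("missing slope cell for SD", s)
    mean(v)
  }, numeric(1))
  # centring the slope profile too makes a flat profile score exactly 0
  # (the weights already sum to zero up to floating-point error)
  sum(weights * (per_sd - mean(per_sd)))
}

#' Group comparison of adaptive-coding contrasts
#'
#' The extracted contrast values are typically non-normal, so the omnibus
#' test is Kruskal-Wallis, with Wilcoxon rank-sum post hocs restricted to
#' placebo versus each drug group (threshold 0.025). If a covariate is
#' supplied, contrasts are first residualised on it (see [residualize()]).
#' A one-sided Wilcoxon signed-rank test additionally asks whether the
#' reference group's raw contrast exceeds zero, i.e. whether adaptive
#' coding is present at all under placebo.
#'
#' @param contrasts numeric contrast per agent.
#' @param groups group labels per agent.
#' @param covariate optional nuisance covariate per agent.
#' @param ref reference group.
#' @param posthoc_alpha post hoc significance threshold.
#' @return List with `omnibus`, `posthoc` (both as in [group_tests()]),
#'   and `ref_positive` (one-sided signed-rank test of contrast > 0 in the
#'   reference group, on raw contrasts).
#' @export
group_adaptive_comparison <- function(contrasts, groups, covariate = NULL,
                                      ref = "placebo", posthoc_alpha = 0.025) {
  keep <- !is.na(contrasts)
  contrasts <- contrasts[keep]; groups <- groups[keep]
  if (!is.null(covariate)) covariate <- covariate[keep]
  raw <- contrasts
  if (!is.null(covariate)) contrasts <- residualize(contrasts, covariate)
  tests <- group_tests(contrasts, groups, type = "nonparametric",
                       ref = ref, posthoc_alpha = posthoc_alpha)
  ref_positive <- NULL
  if (ref %in% groups) {
    w <- suppressWarnings(
      wilcox.test(raw[groups == ref], mu = 0, alternative = "greater"))
    ref_positive <- list(statistic = unname(w$statistic), p_value = w$p.value)
  }
  c(tests, list(ref_positive = ref_positive))
}
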