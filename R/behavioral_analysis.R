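#' Performance error
#'
#' Mean absolute difference between predictions and the expected value of
#' the active reward distribution, the most accurate possible prediction on
#' this task. Reported overall and, optionally, per SD condition. Missed
#' trials are excluded.
#'
#' @param trials trial table with predictions.
#' @param by_sd also return the per-SD-condition breakdown.
#' @return If `by_sd`, a named numeric vector (`overall`, then one entry
#'   per SD, e.g. `SD5`); otherwise the overall scalar. Conditions with no
#'   usable trials yield `NA`.
#' @export
performance_error <- function(trials, by_sd = TRUE) {
  ok <- usable_rows(trials)
  err <- abs(trials$prediction - trials$ev)
  overall <- if (any(ok)) mean(err[ok]) else NA_real_
  if (!by_sd) return(overall)
  sds <- sort(unique(trials$sd))
  per <- vapply(sds, function(s) {
    sel <- ok & trials$sd == s
    if (any(sel)) mean(err[sel]) else NA_real_
  }, numeric(1))
  c(overall = overall, setNames(per, sprintf("SD%g", sds)))
}

#' Scaler / non-scaler contingency table
#'
#' Cross-tabulates agents by treatment group and by whether their fitted
#' PE-scaling parameter indicates scaling (`nu > epsilon`) or not. Boundary
#' maximum-likelihood estimates at exactly 0 are genuine non-scalers.
#'
#' @param cohort data frame with columns `group` and `nu`.
#' @param groups the two groups to tabulate (rows, in order).
#' @param epsilon threshold below which `nu` counts as absent.
#' @return 2 x 2 integer matrix, rows = groups, columns
#'   `c("non_scaler", "scaler")`.
#' @export
scaling_contingency <- function(cohort, groups = c("sulpiride", "placebo"),
                                epsilon = 1e-3) {
  if (!all(groups %in% cohort$group))
    stop("unknown group label(s): ",
         paste(setdiff(groups, cohort$group), collapse = ", "))
  tab <- t(vapply(groups, function(g) {
    nu <- cohort$nu[cohort$group == g]
    c(non_scaler = sum(nu <= epsilon), scaler = sum(nu > epsilon))
  }, numeric(2)))
  storage.mode(tab) <- "integer"
  if (any(colSums(tab) == 0))
    warning("degenerate contingency table: a scaler column is empty")
  tab
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Plain Pearson chi-square without continuity correction (df = 1).
#'
#' @param table 2 x 2 count matrix.
#' @return List with `statistic`, `df`, and `p_value`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Remove a covariate's variance and standardise
#'
#' Ordinary least-squares residuals of the outcome on the covariate (with
#' intercept), z-scored to mean 0, SD 1. Used to adjust group comparisons
#' for nuisance variables such as the time between dosing and scan start.
#'
#' @param outcome numeric outcome, one value per agent.
#' @param covariate numeric covariate, same length.
#' @return Standardised residuals.
#' @export
residualize <- function(outcome, covariate) {
  if (length(outcome) < 3) stop("need at least 3 observations")
  if (length(covariate) != length(outcome)) stop("length mismatch")
  if (sd(covariate, na.rm = TRUE) == 0) stop("constant covariate")
  r <- resid(lm(outcome ~ covariate))
  s <- sd(r)
  if (s < 1e-12)
    stop("degenerate residuals: outcome fully explained by covariate")
  as.numeric((r - mean(r)) / s)
}

#' Omnibus and post hoc group tests on a per-agent metric
#'
#' Parametric route (for normally distributed behavioural measures):
#' one-way ANOVA omnibus with Welch t post hocs. Nonparametric route (for
#' non-normal measures such as extracted contrast values): Kruskal-Wallis
#' omnibus with Wilcoxon rank-sum post hocs. Post hoc comparisons are
#' restricted to the reference (placebo) group versus each other group,
#' with a Bonferroni-corrected threshold of 0.025 for the two comparisons.
#'
#' @param metric numeric vector, one value per agent.
#' @param groups group labels, same length.
#' @param type `"parametric"` or `"nonparametric"`.
#' @param ref reference group for post hoc contrasts.
#' @param posthoc_alpha significance threshold for post hoc tests.
#' @return List with `omnibus` (statistic, df, p_value, method) and
#'   `posthoc` (data frame: comparison, statistic, p_value, significant).
#' @export
group_tests <- function(metric, groups, type = c("parametric", "nonparametric"),
                        ref = "placebo", posthoc_alpha = 0.025) {
  type <- match.arg(type)
  groups <- as.character(groups)
  ok <- !is.na(metric) & !is.na(groups)
  metric <- metric[ok]; groups <- groups[ok]
  counts <- table(groups)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2)) stop("every group needs at least 2 agents")
  g <- factor(groups)

  if (type == "parametric") {
    fit <- aov(metric ~ g)
    tab <- summary(fit)[[1]]
    omnibus <- list(statistic = tab$`F value`[1],
                    df = unname(tab$Df[1:2]), p_value = tab$`Pr(>F)`[1],
                    method = "one-way ANOVA")
  } else {
    kw <- kruskal.test(metric, g)
    omnibus <- list(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value,
                    method = "Kruskal-Wallis rank sum")
  }

  others <- setdiff(levels(g), ref)
  if (!ref %in% levels(g)) {
    posthoc <- NULL
  } else {
    posthoc <- do.call(rbind, lapply(others, function(o) {
      x <- metric[groups == ref]; y <- metric[groups == o]
      res <- if (type == "parametric") t.test(x, y) else
        suppressWarnings(wilcox.test(x, y))
      data.frame(comparison = paste(ref, "vs", o),
                 statistic = unname(res$statistic), p_value = res$p.value,
                 significant = res$p.value < posthoc_alpha,
                 stringsAsFactors = FALSE)
    }))
  }
  list(omnibus = omnibus, posthoc = posthoc, posthoc_alpha = posthoc_alpha,
       underpowered = any(counts < 5))
}

#' Regression of performance error on learning parameters
#'
#' Multiple linear regression of overall performance error on the fitted
#' adaptive-model parameters - the presence/absence of PE scaling (an
#' indicator, not continuous `nu`), the initial learning rate `k1`, and
#' the decay constant `gamma` - with treatment group as a categorical
#' covariate.
#'
#' @param cohort data frame with columns `perf_error`, `nu`, `k1`, `gamma`,
#'   `group`.
#' @param epsilon threshold defining the scaler indicator.
#' @return List with `coefficients` (term, estimate, t, p) and the fitted
#'   `lm` object.
#' @export
performance_regression <- function(cohort, epsilon = 1e-3) {
  need <- c("perf_error", "nu", "k1", "gamma", "group")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  dat <- data.frame(perf_error = cohort$perf_error,
                    scaler = as.numeric(cohort$nu > epsilon),
                    k1 = cohort$k1, gamma = cohort$gamma,
                    group = factor(cohort$group))
  X <- cbind(dat$scaler, dat$k1, dat$gamma)
  if (qr(cbind(1, X))$rank < 4) stop("rank-deficient design (collinear predictors)")
  fit <- lm(perf_error ~ scaler + k1 + gamma + group, data = dat)
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                 t = sm[, 3], p = sm[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE),
       fit = fit)
}

#' Model fit quality per agent
#'
#' Squared correlation between observed predictions and model-predicted
#' means, computed within each SD condition and averaged across conditions.
#'
#' @param trials one agent's trial table with predictions.
#' @param mu model-predicted means (e.g. from [predict_series()]).
#' @return Mean R-squared across SD conditions.
#' @export
model_r2 <- function(trials, mu) {
  ok <- usable_rows(trials) & !is.na(mu)
  sds <- sort(unique(trials$sd))
  r2 <- vapply(sds, function(s) {
    sel <- ok & trials$sd == s
    if (sum(sel) < 3) return(NA_real_)
    suppressWarnings(cor(trials$prediction[sel], mu[sel]))^2
  }, numeric(1))
  mean(r2, na.rm = TRUE)
}
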