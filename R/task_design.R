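#' The six reward distributions of the prediction task
#'
#' Builds the full crossing of reward variability (SD 5, 10, 15 GBP) and
#' expected value (EV 35, 65 GBP). Each distribution carries a cue level
#' (`small`, `medium`, `large`) given by the rank of its SD: cues signal only
#' the relative variability of the upcoming rewards, never the EV.
#'
#' @param evs numeric vector of expected values in GBP.
#' @param sds numeric vector of standard deviations in GBP.
#' @return A data frame with one row per distribution and columns
#'   `dist_id`, `ev`, `sd`, `cue_level` (ordered factor).
#' @examples
#' make_distribution_set()
#' @export
make_distribution_set <- function(evs = c(35, 65), sds = c(5, 10, 15)) {
  stopifnot(length(evs) >= 1, length(sds) >= 1, all(sds > 0))
  grid <- expand.grid(sd = sort(sds), ev = sort(evs))
  cue_labels <- c("small", "medium", "large")[rank(sort(sds))]
  data.frame(
    dist_id = sprintf("EV%g_SD%g", grid$ev, grid$sd),
    ev = grid$ev,
    sd = grid$sd,
    cue_level = factor(cue_labels[match(grid$sd, sort(sds))],
                       levels = c("small", "medium", "large"),
                       ordered = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Enumerate all valid session pairings of the six distributions
#'
#' A session presents two distributions that differ in both EV and SD, and
#' every distribution is used exactly once across the three sessions. With
#' the full 2 x 3 design this is a perfect matching pairing each EV-35
#' distribution with an EV-65 distribution of a different SD: a derangement
#' of the three SD levels, of which exactly two exist.
#'
#' @param distributions data frame from [make_distribution_set()].
#' @return A list of matchings; each matching is a list of three
#'   character pairs of `dist_id`s.
#' @export
enumerate_session_pairings <- function(distributions = make_distribution_set()) {
  evs <- sort(unique(distributions$ev))
  sds <- sort(unique(distributions$sd))
  stopifnot(length(evs) == 2, length(sds) == 3, nrow(distributions) == 6)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  derangements <- Filter(function(p) all(p != seq_along(p)), perms)
  lapply(derangements, function(p) {
    lapply(seq_along(sds), function(i) {
      c(sprintf("EV%g_SD%g", evs[1], sds[i]),
        sprintf("EV%g_SD%g", evs[2], sds[p[i]]))
    })
  })
}

#' Pseudo-randomly pair distributions into sessions
#'
#' Draws one of the valid matchings (see [enumerate_session_pairings()])
#' uniformly, then randomises session order and the within-pair order.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param distributions data frame from [make_distribution_set()].
#' @return A list of three character vectors of length 2 (`dist_id` pairs),
#'   one per session.
#' @export
pair_sessions <- function(distributions = make_distribution_set()) {
  matchings <- enumerate_session_pairings(distributions)
  m <- matchings[[sample.int(length(matchings), 1L)]]
  m <- m[sample.int(length(m))]
  lapply(m, function(pair) pair[sample.int(2L)])
}

#' Sample a moment-matched pseudo-Gaussian reward sequence
#'
#' Rewards are drawn from a Gaussian truncated to the 0-100 GBP scale and
#' then affinely rescaled so that the sample mean and sample SD match the
#' nominal EV and SD, re-clipped and rounded to 0.1 GBP. The exact matching
#' (before rounding) guarantees that every simulated agent faces the nominal
#' reward statistics the behavioural metrics assume.
#'
#' @param ev expected value in GBP.
#' @param sd_nominal standard deviation in GBP.
#' @param n number of rewards (>= 2).
#' @param lower,upper bounds of the reward scale in GBP.
#' @return Numeric vector of `n` rewards in `[lower, upper]`, with sample
#'   mean within 0.5 of `ev` and sample SD within 0.5 of `sd_nominal`.
#' @export
sample_rewards <- function(ev, sd_nominal, n, lower = 0, upper = 100) {
  stopifnot(n >= 2, sd_nominal > 0, ev > lower, ev < upper)
  if (n == 2) {
    d <- sd_nominal / sqrt(2)
    x <- c(ev - d, ev + d)[sample.int(2L)]
  } else {
    # redraw until the moment-matched sample sits fully inside the scale;
    # rescaling (not clipping) keeps the sample moments exact
    for (attempt in seq_len(200)) {
      x <- rnorm(n, ev, sd_nominal)
      x <- (x - mean(x)) / sd(x) * sd_nominal + ev
      if (all(x >= lower & x <= upper)) break
      if (attempt == 200)
        stop("moment matching failed within scale bounds for EV=", ev,
             ", SD=", sd_nominal)
    }
  }
  x <- round(x, 1)
  if (abs(mean(x) - ev) > 0.5 || abs(sd(x) - sd_nominal) > 0.5)
    stop("moment matching failed within scale bounds for EV=", ev,
         ", SD=", sd_nominal)
  x
}

#' Pseudo-random control-trial mask
#'
#' Marks `round(fraction * n)` trial positions of a session as control
#' trials, placed uniformly at random.
#'
#' @param n number of trials in the session.
#' @param fraction control-trial fraction (default 0.20).
#' @return Logical vector of length `n`.
#' @export
assign_control_trials <- function(n, fraction = 0.20) {
  stopifnot(n >= 1, fraction >= 0, fraction < 1)
  k <- round(fraction * n)
  mask <- rep(FALSE, n)
  if (k > 0) mask[sample.int(n, k)] <- TRUE
  mask
}

#' Control-trial payoff
#'
#' On control trials the payoff depends on accuracy relative to the EV of
#' the active distribution: predictions within one SD of the EV pay 7.50
#' GBP, within two SDs 5.00 GBP, and all other predictions 2.50 GBP. A
#' missing prediction (missed trial) pays 0.
#'
#' @param prediction predicted reward in GBP (may be `NA`).
#' @param ev,sd_nominal distribution parameters in GBP.
#' @return Payoff in GBP (vectorised).
#' @examples
#' control_payoff(37, 35, 5)  # 7.50
#' control_payoff(46, 35, 5)  # 2.50
#' @export
control_payoff <- function(prediction, ev, sd_nominal) {
  d <- abs(prediction - ev)
  out <- ifelse(d <= sd_nominal, 7.50, ifelse(d <= 2 * sd_nominal, 5.00, 2.50))
  out[is.na(prediction)] <- 0
  out
}

#' Test-trial payoff
#'
#' On ordinary (test) trials the payoff is 10% of the reward drawn.
#'
#' @param reward reward in GBP.
#' @return Payoff in GBP (vectorised).
#' @export
test_payoff <- function(reward) 0.10 * reward

# Random composition of `total` into block lengths drawn from
# `range[1]..range[2]`; the final block absorbs the remainder but is kept
# inside the range by constraining the penultimate draw.
block_lengths_for <- function(total, range = c(4L, 6L)) {
  lo <- range[1]; hi <- range[2]
  stopifnot(total >= lo, hi >= lo)
  # a remainder is completable iff it is 0, lies in [lo, hi], or is at least
  # 2 * lo (every n >= 2 * lo decomposes into parts from [lo, hi])
  feasible <- if (hi == lo) function(r) r %% lo == 0 else
    function(r) r == 0 || (r >= lo && r <= hi) || r >= 2 * lo
  stopifnot(feasible(total))
  lengths <- integer(0)
  remaining <- total
  while (remaining > hi) {
    cand <- seq(lo, hi)
    cand <- cand[vapply(cand, function(l) feasible(remaining - l), logical(1))]
    len <- if (length(cand) == 1) cand else sample(cand, 1L)
    lengths <- c(lengths, len)
    remaining <- remaining - len
  }
  c(lengths, remaining)
}

#' Default task configuration
#'
#' Defaults reproduce the published design: six distributions (SD 5/10/15
#' crossed with EV 35/65 GBP), 31 trials per distribution, blocks of 4-6
#' trials alternating between the two session distributions, 20% control
#' trials, no missed trials.
#'
#' @param evs,sds distribution parameter sets in GBP.
#' @param trials_per_dist trials per distribution per experiment.
#' @param block_range integer range of block lengths.
#' @param control_fraction fraction of control trials per session.
#' @param miss_prob probability that a trial is missed (no prediction).
#' @return A named list, validated by [validate_task_config()].
#' @export
task_config <- function(evs = c(35, 65), sds = c(5, 10, 15),
                        trials_per_dist = 31L, block_range = c(4L, 6L),
                        control_fraction = 0.20, miss_prob = 0) {
  cfg <- list(evs = evs, sds = sds, trials_per_dist = as.integer(trials_per_dist),
              block_range = as.integer(block_range),
              control_fraction = control_fraction, miss_prob = miss_prob)
  validate_task_config(cfg)
  cfg
}

#' Validate a task configuration
#'
#' Collects every violated field into a single error message.
#'
#' @param cfg a list as produced by [task_config()].
#' @return The config, invisibly, if valid.
#' @export
validate_task_config <- function(cfg) {
  problems <- character(0)
  if (!is.numeric(cfg$evs) || length(cfg$evs) != 2 || any(cfg$evs <= 0) ||
      any(cfg$evs >= 100))
    problems <- c(problems, "evs: need two expected values inside (0, 100)")
  if (!is.numeric(cfg$sds) || length(cfg$sds) != 3 || any(cfg$sds <= 1))
    problems <- c(problems, "sds: need three standard deviations, all > 1")
  if (!is.numeric(cfg$trials_per_dist) || cfg$trials_per_dist < 4)
    problems <- c(problems, "trials_per_dist: need >= 4")
  if (length(cfg$block_range) != 2 || cfg$block_range[1] < 1 ||
      cfg$block_range[2] < cfg$block_range[1])
    problems <- c(problems, "block_range: need increasing pair of positive integers")
  if (!is.numeric(cfg$control_fraction) || cfg$control_fraction < 0 ||
      cfg$control_fraction >= 1)
    problems <- c(problems, "control_fraction: need value in [0, 1)")
  if (!is.numeric(cfg$miss_prob) || cfg$miss_prob < 0 || cfg$miss_prob > 1)
    problems <- c(problems, "miss_prob: need probability in [0, 1]")
  if (length(problems))
    stop("invalid task config:\n  ", paste(problems, collapse = "\n  "))
  invisible(cfg)
}

#' Generate one experiment's design (trial table without predictions)
#'
#' Produces the full three-session design: sessions pair distributions that
#' differ in both EV and SD, each distribution receives exactly
#' `trials_per_dist` trials presented in alternating blocks of 4-6 trials,
#' rewards are moment-matched pseudo-Gaussian draws, and 20% of each
#' session's trials are control trials. Prediction-dependent columns
#' (`prediction`, `pe`, `payoff`) are left `NA` for an agent or participant
#' to fill in.
#'
#' @param config task configuration from [task_config()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param agent_id label written to the `agent_id` column.
#' @return A trial-table data frame, one row per trial, with columns
#'   `agent_id, session, block, trial, dist_id, ev, sd, cue_level,
#'   is_control, reward, prediction, missed, pe, payoff`.
#' @export
generate_experiment <- function(config = task_config(), seed = 1L,
                                agent_id = "agent01") {
  validate_task_config(config)
  set.seed(derive_seed(seed, "task"))
  dists <- make_distribution_set(config$evs, config$sds)
  sessions <- pair_sessions(dists)

  rewards_left <- lapply(setNames(dists$dist_id, dists$dist_id), function(id) {
    row <- dists[dists$dist_id == id, ]
    sample_rewards(row$ev, row$sd, config$trials_per_dist)
  })

  out <- vector("list", length(sessions))
  for (s in seq_along(sessions)) {
    pair <- sessions[[s]]
    blocks <- lapply(pair, function(id)
      block_lengths_for(config$trials_per_dist, config$block_range))
    # strict block-by-block alternation between the two "pots"
    order_ids <- character(0)
    block_no <- integer(0)
    i <- c(1L, 1L); b <- 0L; turn <- 1L
    while (i[1] <= length(blocks[[1]]) || i[2] <= length(blocks[[2]])) {
      if (i[turn] > length(blocks[[turn]])) turn <- 3L - turn
      b <- b + 1L
      len <- blocks[[turn]][i[turn]]
      order_ids <- c(order_ids, rep(pair[turn], len))
      block_no <- c(block_no, rep(b, len))
      i[turn] <- i[turn] + 1L
      turn <- 3L - turn
    }
    n <- length(order_ids)
    df <- data.frame(
      agent_id = agent_id, session = s, block = block_no, trial = seq_len(n),
      dist_id = order_ids, stringsAsFactors = FALSE
    )
    df$ev <- dists$ev[match(df$dist_id, dists$dist_id)]
    df$sd <- dists$sd[match(df$dist_id, dists$dist_id)]
    df$cue_level <- as.character(dists$cue_level[match(df$dist_id, dists$dist_id)])
    df$is_control <- assign_control_trials(n, config$control_fraction)
    df$reward <- NA_real_
    for (id in pair) {
      rows <- which(df$dist_id == id)
      df$reward[rows] <- rewards_left[[id]][seq_along(rows)]
    }
    df$prediction <- NA_real_
    df$missed <- FALSE
    df$pe <- NA_real_
    df$payoff <- NA_real_
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Running-mean benchmark predictions
#'
#' A model-free benchmark agent that predicts, for each distribution, the
#' mean of the rewards observed so far from that distribution (scale
#' midpoint 50 before the first observation). Its absolute prediction
#' errors scale with the SD of the distribution, which is the task's
#' manipulation check.
#'
#' @param trials a trial-table data frame with rewards.
#' @param initial prediction used before any reward has been seen.
#' @return The trial table with `prediction` and `pe` filled in.
#' @export
running_mean_predictions <- function(trials, initial = 50) {
  trials <- trials[order(trials$session, trials$trial), ]
  for (id in unique(trials$dist_id)) {
    rows <- which(trials$dist_id == id)
    r <- trials$reward[rows]
    cm <- cumsum(r) / seq_along(r)
    trials$prediction[rows] <- c(initial, cm[-length(cm)])
  }
  trials$pe <- trials$reward - trials$prediction
  trials
}
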