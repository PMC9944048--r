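#' Simulate a cohort of epsilon-greedy digital twins
#'
#' Runs one independent bandit episode per (agent, replicate): the
#' rewarding arm is redrawn uniformly for every episode and held fixed
#' within it, and the agent plays `n_trials` epsilon-greedy trials with its
#' own exploration probability. Each episode consumes a seed derived from
#' `seed` and the episode index, so results are bit-reproducible and
#' independent of evaluation order.
#'
#' @param epsilons Per-agent exploration probabilities in \[0, 1\] (the
#'   normalized cortisol values when simulating a fish cohort).
#' @param n_trials Trials per episode (21 for the maze protocol, 400 for
#'   long-horizon runs).
#' @param replicates Independent episodes per agent; default 1, one
#'   digital twin per fish.
#' @param tie_break Greedy tie-breaking policy, see [select_arm()].
#' @param seed Integer base seed.
#' @param n_arms Number of arms; default 4.
#' @return An object of class `"simulation_run"`: list with `rewards`, an
#'   integer array of dimension (agents, replicates, trials), plus the
#'   call parameters.
#' @export
#' @examples
#' run <- simulate_cohort(c(0.03, 0.41, 0.93), n_trials = 21, seed = 7)
#' dim(run$rewards)
simulate_cohort <- function(epsilons, n_trials = 21L, replicates = 1L,
                            tie_break = c("first_index", "uniform_random"),
                            seed = 1L, n_arms = 4L) {
  if (length(epsilons) == 0L)
    stop_fb("epsilons must be non-empty", class = "fb_invalid_parameter")
  check_prob(epsilons, "epsilons")
  tie_break <- match.arg(tie_break)
  n_trials <- as.integer(n_trials)
  replicates <- as.integer(replicates)
  if (is.na(n_trials) || n_trials < 1L || is.na(replicates) || replicates < 1L)
    stop_fb("n_trials and replicates must be >= 1",
            class = "fb_invalid_parameter")
  n_arms <- as.integer(n_arms)
  n_agents <- length(epsilons)
  rewards <- array(0L, dim = c(n_agents, replicates, n_trials))
  for (i in seq_len(n_agents)) {
    for (j in seq_len(replicates)) {
      s <- derive_seed(seed, (i - 1) * replicates + j, offset = 4L)
      rewards[i, j, ] <- with_seed(s,
        .episode_rewards(epsilons[i], n_trials, n_arms, tie_break))
    }
  }
  structure(list(rewards = rewards, epsilons = as.numeric(epsilons),
                 n_trials = n_trials, replicates = replicates,
                 tie_break = tie_break, seed = as.integer(seed),
                 n_arms = n_arms),
            class = "simulation_run")
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf("Bandit simulation run: %d agents x %d replicate(s) x %d trials (%s tie-break, seed %d)\n",
              dim(x$rewards)[1], dim(x$rewards)[2], dim(x$rewards)[3],
              x$tie_break, x$seed))
  invisible(x)
}

#' Per-episode average rewards of a simulation run
#'
#' @param run A [simulate_cohort()] result.
#' @return Matrix (agents x replicates) of per-episode average rewards.
#' @export
run_average_rewards <- function(run) {
  stopifnot(inherits(run, "simulation_run"))
  apply(run$rewards, c(1, 2), mean)
}

#' Group-wise mean and standard error summary
#'
#' Summarizes a per-individual quantity (typically the average reward) by
#' group: arithmetic mean and standard error (sample standard deviation
#' over the square root of the group size). A group of one individual has
#' an undefined standard error, reported as `NA` rather than zero.
#'
#' @param values One value per individual.
#' @param groups One group label per individual.
#' @param epsilons Optional per-individual exploration probabilities
#'   (normalized cortisol); when given, the group means are included.
#' @return Data frame with columns `group`, `n`, `mean_epsilon`,
#'   `mean_avg_reward`, `se`, one row per group in ascending label order.
#' @export
#' @examples
#' group_summary(c(0, 1, 0.5), c(1, 1, 2))
group_summary <- function(values, groups, epsilons = NULL) {
  if (length(values) != length(groups))
    stop_fb("values and groups must have one entry per individual",
            class = "fb_invalid_parameter")
  if (!is.null(epsilons) && length(epsilons) != length(values))
    stop_fb("epsilons must match values in length",
            class = "fb_invalid_parameter")
  g <- factor(groups, levels = sort(unique(groups)))
  out <- data.frame(
    group = as.integer(levels(g)),
    n = as.integer(table(g)),
    mean_epsilon = if (is.null(epsilons)) NA_real_ else
      as.numeric(tapply(epsilons, g, mean)),
    mean_avg_reward = as.numeric(tapply(values, g, mean)),
    se = as.numeric(tapply(values, g, se))
  )
  rownames(out) <- NULL
  out
}

#' Cumulative-reward trajectories by group
#'
#' For each group and trial `t`, the mean and standard error over episodes
#' of the cumulative reward up to `t` — the learning-curve surface of the
#' foraging experiment. With `replicates > 1` every (agent, replicate)
#' episode contributes.
#'
#' @param run A [simulate_cohort()] result, or a binary outcomes matrix
#'   with one row per individual (e.g. the fish trial columns).
#' @param groups One group label per agent (per row for matrix input).
#' @return Data frame of class `"trajectory_set"` with columns `group`,
#'   `trial`, `mean_cum_reward`, `se`.
#' @export
cumulative_trajectories <- function(run, groups) {
  if (inherits(run, "simulation_run")) {
    d <- dim(run$rewards)
    if (length(groups) != d[1])
      stop_fb("need one group label per agent", class = "fb_invalid_parameter")
    # flatten (agent, replicate) episodes into rows
    mat <- matrix(aperm(run$rewards, c(2, 1, 3)), d[1] * d[2], d[3])
    groups <- rep(groups, each = d[2])
  } else {
    mat <- as.matrix(run)
    if (length(groups) != nrow(mat))
      stop_fb("need one group label per row", class = "fb_invalid_parameter")
  }
  check_binary(as.vector(mat), "rewards")
  cum <- t(apply(mat, 1, cumsum))
  if (ncol(mat) == 1L) cum <- matrix(cum, ncol = 1L)  # apply drops dims
  g <- factor(groups, levels = sort(unique(groups)))
  res <- do.call(rbind, lapply(levels(g), function(lev) {
    block <- cum[g == lev, , drop = FALSE]
    data.frame(group = as.integer(lev), trial = seq_len(ncol(block)),
               mean_cum_reward = colMeans(block),
               se = apply(block, 2, se))
  }))
  rownames(res) <- NULL
  class(res) <- c("trajectory_set", "data.frame")
  res
}
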