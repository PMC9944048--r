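#' k-armed bandit task with a single rewarding arm
#'
#' The foraging environment: `n_arms` arms labelled `1..k`, exactly one of
#' which pays a binary reward of 1 when chosen; all other arms pay 0. This
#' mirrors a four-arm cross-maze in which one arm holds the food plate.
#'
#' @param n_arms Number of arms (k), at least 2. Default 4.
#' @param reward_arm Label of the rewarding arm in `1..n_arms`.
#' @param reward_value Payoff on the rewarding arm. Only the binary value 1
#'   is supported (the exact oracle and the learner assume 0/1 rewards).
#' @return An object of class `"bandit_task"`.
#' @export
#' @examples
#' bandit_task(4, reward_arm = 2)
bandit_task <- function(n_arms = 4L, reward_arm, reward_value = 1) {
  n_arms <- as.integer(n_arms)
  if (is.na(n_arms) || n_arms < 2L)
    stop_fb("n_arms must be an integer >= 2", class = "fb_invalid_parameter")
  reward_arm <- as.integer(reward_arm)
  if (is.na(reward_arm) || reward_arm < 1L || reward_arm > n_arms)
    stop_fb("reward_arm must lie in 1..n_arms", class = "fb_invalid_parameter")
  if (!identical(as.numeric(reward_value), 1))
    stop_fb("only binary rewards (reward_value = 1) are supported",
            class = "fb_unsupported_reward")
  structure(list(n_arms = n_arms, reward_arm = reward_arm, reward_value = 1),
            class = "bandit_task")
}

#' @export
print.bandit_task <- function(x, ...) {
  cat(sprintf("%d-armed bandit task: arm %d pays 1, all others pay 0\n",
              x$n_arms, x$reward_arm))
  invisible(x)
}

#' Initial state of an epsilon-greedy learner
#'
#' Action values `Q(A)` start at zero for every arm (no optimistic
#' initialization) and visit counts `N(A)` at zero.
#'
#' @param epsilon Exploration probability in \[0, 1\].
#' @param n_arms Number of arms.
#' @return An object of class `"agent_state"` with fields `epsilon`,
#'   `q_values` and `visit_counts`.
#' @export
agent_state <- function(epsilon, n_arms = 4L) {
  check_prob(epsilon, "epsilon")
  n_arms <- as.integer(n_arms)
  if (is.na(n_arms) || n_arms < 2L)
    stop_fb("n_arms must be an integer >= 2", class = "fb_invalid_parameter")
  structure(list(epsilon = as.numeric(epsilon),
                 q_values = numeric(n_arms),
                 visit_counts = integer(n_arms)),
            class = "agent_state")
}

#' Sample-average action-value update
#'
#' Incremental update `Q(A) <- Q(A) + (R - Q(A)) / N(A)`, where `N(A)` is the
#' visit count *including* the current visit. Applied after every trial, it
#' keeps `Q(A)` equal to the arithmetic mean of the rewards received on arm
#' `A` so far; the first visit therefore sets `Q = R`.
#'
#' @param q Current action value in \[0, 1\].
#' @param n Visit count including the current visit (`>= 1`).
#' @param r Reward received, 0 or 1.
#' @return The updated action value, guaranteed to stay in \[0, 1\].
#' @export
#' @examples
#' update_action_value(0, 1, 1)    # 1   (first visit forces Q = R)
#' update_action_value(1, 2, 0)    # 0.5
#' update_action_value(0.5, 4, 1)  # 0.625
update_action_value <- function(q, n, r) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_fb("visit count n must be >= 1 (increment N(A) before updating Q)",
            class = "fb_invalid_count")
  if (!is.numeric(r) || length(r) != 1L || !(r %in% c(0, 1)))
    stop_fb("reward r must be 0 or 1", class = "fb_invalid_outcomes")
  check_prob(q, "q")
  q + (r - q) / n
}

#' Epsilon-greedy arm selection
#'
#' With probability `epsilon` a uniformly random arm is drawn over *all* k
#' arms (exploration, which may re-pick the greedy arm); otherwise an arm
#' maximizing `Q` is chosen (exploitation). Ties among maximal arms are
#' resolved by `tie_break`: `"first_index"` takes the lowest-index maximal
#' arm, `"uniform_random"` samples uniformly among them.
#'
#' @param state An [agent_state()].
#' @param tie_break `"first_index"` (default) or `"uniform_random"`.
#' @return A list with `arm` (integer label) and `explored` (logical flag,
#'   `TRUE` when the arm came from the exploration branch).
#' @seealso [run_episode()] for full episodes; RNG state is used as-is, so
#'   wrap calls in `set.seed()` for reproducibility.
#' @export
select_arm <- function(state, tie_break = c("first_index", "uniform_random")) {
  if (!inherits(state, "agent_state"))
    stop_fb("state must be an agent_state", class = "fb_invalid_parameter")
  tie_break <- match.arg(tie_break)
  k <- length(state$q_values)
  if (stats::runif(1) < state$epsilon) {
    arm <- floor(stats::runif(1) * k) + 1L
    return(list(arm = as.integer(arm), explored = TRUE))
  }
  q <- state$q_values
  if (tie_break == "first_index") {
    arm <- which.max(q)
  } else {
    best <- which(q == max(q))
    arm <- if (length(best) == 1L) best else
      best[floor(stats::runif(1) * length(best)) + 1L]
  }
  list(arm = as.integer(arm), explored = FALSE)
}

#' Run one epsilon-greedy episode on a bandit task
#'
#' Plays `n_trials` trials: select an arm (see [select_arm()]), collect the
#' binary reward, increment the arm's visit count, then apply the
#' sample-average update [update_action_value()].
#'
#' @param epsilon Exploration probability in \[0, 1\].
#' @param n_trials Number of trials (`>= 1`), e.g. 21 for the maze protocol.
#' @param task A [bandit_task()].
#' @param seed Optional integer seed; when given, the episode is
#'   reproducible and the caller's RNG state is left untouched.
#' @param tie_break Greedy tie-breaking policy, see [select_arm()].
#' @return A data frame of class `"bandit_episode"` with one row per trial:
#'   `trial_index`, `chosen_arm`, `reward`, `explored`. The final learner
#'   state is attached as attribute `"state"` and the task as `"task"`.
#' @export
#' @examples
#' ep <- run_episode(0.1, 21, bandit_task(4, reward_arm = 2), seed = 1)
#' mean(ep$reward)
run_episode <- function(epsilon, n_trials, task, seed = NULL,
                        tie_break = c("first_index", "uniform_random")) {
  check_prob(epsilon, "epsilon")
  tie_break <- match.arg(tie_break)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L)
    stop_fb("n_trials must be >= 1", class = "fb_invalid_parameter")
  if (!inherits(task, "bandit_task"))
    stop_fb("task must be a bandit_task", class = "fb_invalid_parameter")
  run <- function() .run_episode_impl(epsilon, n_trials, task, tie_break)
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out
}

# Inner loop, assumes validated arguments and a seeded RNG.
.run_episode_impl <- function(epsilon, n_trials, task, tie_break) {
  k <- task$n_arms
  reward_arm <- task$reward_arm
  q <- numeric(k)
  n <- integer(k)
  chosen <- integer(n_trials)
  reward <- integer(n_trials)
  explored <- logical(n_trials)
  first_index <- tie_break == "first_index"
  for (t in seq_len(n_trials)) {
    if (stats::runif(1) < epsilon) {
      arm <- floor(stats::runif(1) * k) + 1L
      exp_t <- TRUE
    } else {
      if (first_index) {
        arm <- which.max(q)
      } else {
        best <- which(q == max(q))
        arm <- if (length(best) == 1L) best else
          best[floor(stats::runif(1) * length(best)) + 1L]
      }
      exp_t <- FALSE
    }
    r <- if (arm == reward_arm) 1L else 0L
    n[arm] <- n[arm] + 1L
    q[arm] <- q[arm] + (r - q[arm]) / n[arm]
    chosen[t] <- arm
    reward[t] <- r
    explored[t] <- exp_t
  }
  out <- data.frame(trial_index = seq_len(n_trials), chosen_arm = chosen,
                    reward = reward, explored = explored)
  state <- structure(list(epsilon = epsilon, q_values = q, visit_counts = n),
                     class = "agent_state")
  structure(out, state = state, task = task,
            class = c("bandit_episode", "data.frame"))
}

# Reward-only episode for batch simulation: same algorithm and per-trial
# RNG consumption pattern as .run_episode_impl, minus the trace bookkeeping.
# The rewarding arm is drawn uniformly first (one draw), matching the
# batch simulators' episode protocol.
.episode_rewards <- function(epsilon, n_trials, k, tie_break) {
  reward_arm <- floor(stats::runif(1) * k) + 1L
  q <- numeric(k)
  n <- integer(k)
  reward <- integer(n_trials)
  first_index <- tie_break == "first_index"
  for (t in seq_len(n_trials)) {
    if (stats::runif(1) < epsilon) {
      arm <- floor(stats::runif(1) * k) + 1L
    } else if (first_index) {
      arm <- which.max(q)
    } else {
      best <- which(q == max(q))
      arm <- if (length(best) == 1L) best else
        best[floor(stats::runif(1) * length(best)) + 1L]
    }
    r <- if (arm == reward_arm) 1L else 0L
    n[arm] <- n[arm] + 1L
    q[arm] <- q[arm] + (r - q[arm]) / n[arm]
    reward[t] <- r
  }
  reward
}
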