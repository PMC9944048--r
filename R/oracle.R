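#' Exact expected rewards for the epsilon-greedy forager
#'
#' Closed-form dynamic-programming oracle for the Monte Carlo simulator.
#' With zero-initialized action values and a binary reward on a single arm,
#' an episode's reachable belief states collapse to two: the rewarding arm
#' has not yet been found (all `Q = 0`, greedy choice falls back on the
#' tie-break rule) or it has (its `Q` is positive forever after, greedy
#' choice locks onto it). The per-trial success probabilities are
#'
#' * discovered: `h = 1 - epsilon * (k - 1) / k`;
#' * undiscovered: the probability `d` of picking the rewarding arm, which
#'   depends on the tie-break — under `"first_index"` the greedy branch
#'   always plays arm 1, so `d = h` when arm 1 is the rewarding arm and
#'   `d = epsilon / k` otherwise; under `"uniform_random"` every arm is
#'   equally likely, so `d = 1 / k`.
#'
#' Picking the rewarding arm while undiscovered both scores and reveals it,
#' so the chain stays undiscovered at trial `t` with probability
#' `(1 - d)^(t-1)` and `E[R_t] = (1 - d)^(t-1) d + (1 - (1 - d)^(t-1)) h`.
#' `expected_reward_per_trial()` returns this vector, mixing over the
#' rewarding arm's distribution; `expected_average_reward()` is its mean,
#' the exact expectation of (total reward) / `n_trials`.
#'
#' @param epsilon Exploration probability in \[0, 1\].
#' @param n_trials Number of trials.
#' @param n_arms Number of arms k (default 4).
#' @param tie_break Greedy tie-breaking policy, see [select_arm()].
#' @param reward_arm `"uniform"` (the rewarding arm is drawn uniformly per
#'   episode, the simulator's default) or a fixed arm label in `1..n_arms`.
#' @return `expected_reward_per_trial()`: numeric vector of length
#'   `n_trials` with the expected reward of each trial.
#'   `expected_average_reward()`: scalar expected average reward.
#' @export
#' @examples
#' expected_average_reward(1, 21)                               # 0.25
#' expected_average_reward(0, 21)                               # 0.25
#' expected_average_reward(0, 21, tie_break = "uniform_random")
#' # 1 - (3/21) * (1 - 0.75^21)
expected_reward_per_trial <- function(epsilon, n_trials, n_arms = 4L,
                                      tie_break = c("first_index",
                                                    "uniform_random"),
                                      reward_arm = "uniform") {
  check_prob(epsilon, "epsilon")
  tie_break <- match.arg(tie_break)
  n_arms <- as.integer(n_arms)
  n_trials <- as.integer(n_trials)
  if (is.na(n_arms) || n_arms < 2L || is.na(n_trials) || n_trials < 1L)
    stop_fb("n_arms must be >= 2 and n_trials >= 1",
            class = "fb_invalid_parameter")
  k <- n_arms
  h <- 1 - epsilon * (k - 1) / k

  per_trial_fixed_d <- function(d) {
    u <- (1 - d)^(seq_len(n_trials) - 1)   # P(still undiscovered at trial t)
    u * d + (1 - u) * h
  }

  if (tie_break == "uniform_random") {
    # symmetric in the arm label, so the reward_arm distribution is moot
    if (!identical(reward_arm, "uniform")) .check_arm(reward_arm, k)
    return(per_trial_fixed_d(1 / k))
  }
  if (identical(reward_arm, "uniform")) {
    (per_trial_fixed_d(h) + (k - 1) * per_trial_fixed_d(epsilon / k)) / k
  } else {
    .check_arm(reward_arm, k)
    if (as.integer(reward_arm) == 1L) per_trial_fixed_d(h)
    else per_trial_fixed_d(epsilon / k)
  }
}

.check_arm <- function(arm, k) {
  arm <- suppressWarnings(as.integer(arm))
  if (length(arm) != 1L || is.na(arm) || arm < 1L || arm > k)
    stop_fb("reward_arm must be \"uniform\" or an arm label in 1..n_arms",
            class = "fb_invalid_parameter")
  invisible(arm)
}

#' @rdname expected_reward_per_trial
#' @export
expected_average_reward <- function(epsilon, n_trials, n_arms = 4L,
                                    tie_break = c("first_index",
                                                  "uniform_random"),
                                    reward_arm = "uniform") {
  mean(expected_reward_per_trial(epsilon, n_trials, n_arms, tie_break,
                                 reward_arm))
}
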