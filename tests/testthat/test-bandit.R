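test_that("sample-average update follows Q + (R - Q)/N", {
  expect_equal(update_action_value(0, 1, 1), 1)      # first visit sets Q = R
  expect_equal(update_action_value(1, 2, 0), 0.5)
  expect_equal(update_action_value(0.5, 4, 1), 0.625)
  expect_error(update_action_value(0.5, 0, 1), class = "fb_invalid_count")
  expect_error(update_action_value(0.5, 2, 0.3),
               class = "fb_invalid_outcomes")
  expect_error(update_action_value(1.2, 2, 1),
               class = "fb_invalid_parameter")
})

test_that("greedy selection exploits the maximal arm and breaks ties by policy", {
  st <- agent_state(0, 4)
  st$q_values <- c(0, 1, 0, 0)
  for (tb in c("first_index", "uniform_random")) {
    sel <- select_arm(st, tie_break = tb)
    expect_identical(sel$arm, 2L)
    expect_false(sel$explored)
  }
  st$q_values <- c(0, 0, 0, 0)
  expect_identical(select_arm(st, "first_index")$arm, 1L)
  expect_error(select_arm(st, "nearest"))   # unknown policy name
})

test_that("pure exploration draws each arm uniformly", {
  # one long episode at epsilon = 1: every trial is an exploration draw
  ep <- run_episode(1, 1e5, bandit_task(4, 2), seed = 99)
  expect_true(all(ep$explored))
  counts <- tabulate(ep$chosen_arm, nbins = 4)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("greedy episodes lock onto the default arm", {
  ep1 <- run_episode(0, 21, bandit_task(4, 1), seed = 5)
  expect_equal(ep1$reward, rep(1L, 21))
  ep3 <- run_episode(0, 21, bandit_task(4, 3), seed = 5)
  expect_equal(ep3$reward, rep(0L, 21))     # Q stays zero, greedy stays on arm 1
  expect_equal(ep3$chosen_arm, rep(1L, 21))
})

test_that("episode state satisfies the sample-average and conservation invariants", {
  set.seed(42)
  for (i in 1:25) {
    eps <- runif(1)
    T <- sample(1:40, 1)
    arm <- sample(4, 1)
    tb <- sample(c("first_index", "uniform_random"), 1)
    ep <- run_episode(eps, T, bandit_task(4, arm), seed = 1000 + i,
                      tie_break = tb)
    st <- attr(ep, "state")
    expect_identical(sum(st$visit_counts), T)
    expect_true(all(ep$reward %in% c(0L, 1L)))
    expect_equal(ep$reward, as.integer(ep$chosen_arm == arm))
    # Q(A) is the running mean of rewards received on A
    for (a in which(st$visit_counts > 0)) {
      expect_equal(st$q_values[a], mean(ep$reward[ep$chosen_arm == a]))
    }
    expect_true(all(st$q_values >= 0 & st$q_values <= 1))
    expect_true(all(diff(cumsum(ep$reward)) >= 0))
  }
})

test_that("episodes are reproducible under a seed and leave global RNG intact", {
  set.seed(7); before <- runif(1)
  set.seed(7)
  invisible(run_episode(0.5, 21, bandit_task(4, 2), seed = 123))
  expect_identical(runif(1), before)
  a <- run_episode(0.5, 50, bandit_task(4, 2), seed = 123)
  b <- run_episode(0.5, 50, bandit_task(4, 2), seed = 123)
  expect_identical(a, b)
})

test_that("task construction validates arms and binary payoff", {
  expect_error(bandit_task(1, 1), class = "fb_invalid_parameter")
  expect_error(bandit_task(4, 5), class = "fb_invalid_parameter")
  expect_error(bandit_task(4, 2, reward_value = 2),
               class = "fb_unsupported_reward")
})
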