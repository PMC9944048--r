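#' Fit the epsilon-greedy digital-twin model to a fish cohort
#'
#' The central modelling interface. Each fish's min-max-normalized basal
#' cortisol is taken as the exploration probability of an epsilon-greedy
#' agent on a 4-armed bandit with one rewarding arm, and the cohort is
#' simulated trial-for-trial ("digital twins"). The fitted object holds
#' the observed and simulated group summaries (mean and standard error of
#' the average reward per cortisol group), the cumulative-reward
#' trajectories of both, and the fish-versus-simulation correlation
#' report.
#'
#' @param cohort A cohort data frame in the [read_cohort()] schema, a file
#'   path to such a CSV, or an already prepared `"fish_cohort"`.
#' @param group_sizes Ordered cortisol-group sizes; see [assign_groups()].
#' @param replicates Simulated episodes per fish; default 1 (one twin per
#'   fish, the study design). Larger values shrink Monte Carlo noise in
#'   the simulated column.
#' @param tie_break Greedy tie-breaking policy, see [select_arm()].
#' @param seed Integer seed for the simulation.
#' @param quiet Suppress progress messages.
#' @return An object of class `"bandit_twin"` with components `cohort`,
#'   `fish_table`, `sim_table`, `fish_trajectories`, `sim_trajectories`,
#'   `comparison` ([compare_groups()] report), `zero_rewards` (fish and
#'   simulated per-group censuses), `config` and `call`.
#' @seealso [predict.bandit_twin()] for exact expected rewards,
#'   [simulate.bandit_twin()] for fresh simulated cohorts,
#'   [plot.bandit_twin()] for the inverted-U and trajectory figures.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_spec(seed = 11))
#' fit <- bandit_twin(cohort, seed = 11, quiet = TRUE)
#' fit
#' summary(fit)
bandit_twin <- function(cohort, group_sizes = c(16L, 17L, 16L, 16L, 17L),
                        replicates = 1L,
                        tie_break = c("first_index", "uniform_random"),
                        seed = 1L, quiet = FALSE) {
  tie_break <- match.arg(tie_break)
  if (is.character(cohort) && length(cohort) == 1L)
    cohort <- read_cohort(cohort)
  if (!inherits(cohort, "fish_cohort"))
    cohort <- prepare_cohort(cohort, group_sizes = group_sizes,
                             quiet = quiet)
  n_trials <- length(trial_cols(cohort))
  eps <- cohort$normalized_cortisol
  groups <- cohort$group

  fish_table <- group_summary(cohort$avg_reward, groups, epsilons = eps)
  fish_traj <- cumulative_trajectories(as.matrix(cohort[trial_cols(cohort)]),
                                       groups)

  run <- simulate_cohort(eps, n_trials = n_trials, replicates = replicates,
                         tie_break = tie_break, seed = seed)
  avg <- run_average_rewards(run)                  # agents x replicates
  sim_table <- group_summary(as.vector(t(avg)), rep(groups, each = replicates),
                             epsilons = rep(eps, each = replicates))
  sim_traj <- cumulative_trajectories(run, groups)

  comparison <- compare_groups(fish_table, sim_table)
  zero <- list(fish = zero_reward_census(cohort$avg_reward, groups),
               sim = zero_reward_census(as.vector(t(avg)),
                                        rep(groups, each = replicates)))

  structure(list(cohort = cohort, fish_table = fish_table,
                 sim_table = sim_table, fish_trajectories = fish_traj,
                 sim_trajectories = sim_traj, comparison = comparison,
                 zero_rewards = zero, run = run,
                 config = list(n_trials = n_trials, replicates = replicates,
                               tie_break = tie_break, seed = as.integer(seed),
                               group_sizes = group_sizes),
                 call = match.call()),
            class = "bandit_twin")
}

#' @export
print.bandit_twin <- function(x, ...) {
  cat("Epsilon-greedy digital-twin model of cohort foraging\n")
  cat(sprintf("  %d fish, %d trials, %d replicate(s), %s tie-break, seed %d\n",
              nrow(x$cohort), x$config$n_trials, x$config$replicates,
              x$config$tie_break, x$config$seed))
  cat(sprintf("  Pearson r (fish vs. simulation group means): %.2f\n",
              round_half_up(x$comparison$r_all, 2)))
  cat("Use summary() for the group tables and correlation scenarios.\n")
  invisible(x)
}

#' Summarize a fitted digital-twin model
#'
#' @param object A [bandit_twin()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.bandit_twin"` carrying the
#'   group comparison, the correlation scenarios and the zero-reward
#'   censuses; its print method renders the report.
#' @export
summary.bandit_twin <- function(object, ...) {
  structure(list(comparison = object$comparison,
                 fish_table = object$fish_table,
                 sim_table = object$sim_table,
                 zero_rewards = object$zero_rewards,
                 config = object$config),
            class = "summary.bandit_twin")
}

#' @export
print.summary.bandit_twin <- function(x, ...) {
  print(x$comparison)
  cat("\nGroup mean epsilon (normalized cortisol):",
      sprintf("%.4f", x$fish_table$mean_epsilon), "\n")
  cat("Zero-reward individuals per group (fish):     ",
      paste(x$zero_rewards$fish, collapse = " "), "\n")
  cat("Zero-reward individuals per group (simulated):",
      paste(x$zero_rewards$sim, collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.bandit_twin <- function(object, ...) {
  stats::setNames(object$fish_table$mean_epsilon,
                  paste0("epsilon_group", object$fish_table$group))
}

#' Exact expected average rewards from a fitted model
#'
#' Evaluates the dynamic-programming oracle
#' ([expected_average_reward()]) at new exploration probabilities under
#' the fitted configuration — the noiseless prediction the Monte Carlo
#' simulation fluctuates around.
#'
#' @param object A [bandit_twin()] fit.
#' @param newdata Epsilon values; defaults to the fitted group mean
#'   epsilons.
#' @param n_trials Horizon; defaults to the fitted trial count.
#' @param ... Unused.
#' @return Named numeric vector of expected average rewards.
#' @export
predict.bandit_twin <- function(object, newdata = NULL,
                                n_trials = object$config$n_trials, ...) {
  eps <- if (is.null(newdata)) stats::setNames(
    object$fish_table$mean_epsilon,
    paste0("group", object$fish_table$group)) else newdata
  vapply(eps, expected_average_reward, numeric(1), n_trials = n_trials,
         tie_break = object$config$tie_break)
}

#' @export
residuals.bandit_twin <- function(object, ...) {
  stats::setNames(
    object$comparison$comparison$fish_mean -
      object$comparison$comparison$sim_mean,
    paste0("group", object$comparison$comparison$group))
}

#' Simulate fresh cohorts from a fitted model
#'
#' Re-runs the digital twins of the fitted cohort under new seeds and
#' returns the per-fish average rewards, one column per simulation.
#'
#' @param object A [bandit_twin()] fit.
#' @param nsim Number of simulated cohorts.
#' @param seed Base seed; simulation `s` uses `seed + s - 1`.
#' @param ... Unused.
#' @return Data frame (fish x nsim) of average rewards, with the fish ids
#'   as row names.
#' @export
simulate.bandit_twin <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$config$seed + 1L
  eps <- object$cohort$normalized_cortisol
  out <- sapply(seq_len(nsim), function(s) {
    run <- simulate_cohort(eps, n_trials = object$config$n_trials,
                           tie_break = object$config$tie_break,
                           seed = seed + s - 1L)
    as.vector(run_average_rewards(run))
  })
  out <- as.data.frame(matrix(out, nrow = length(eps)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$cohort$fish_id
  out
}

#' Plot a fitted digital-twin model
#'
#' `which = 1`: the inverted-U figure — group mean average reward (with
#' standard-error bars) against group mean epsilon, fish and simulation
#' side by side, with the exact expected-reward curve overlaid.
#' `which = 2`: cumulative-reward trajectories per group, fish (solid)
#' versus simulation (dashed).
#'
#' @param x A [bandit_twin()] fit.
#' @param which Which plots to draw, subset of `1:2`.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.bandit_twin <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    ft <- x$fish_table; st <- x$sim_table
    grid <- seq(0, 1, length.out = 101)
    curve_y <- vapply(grid, expected_average_reward, numeric(1),
                      n_trials = x$config$n_trials,
                      tie_break = x$config$tie_break)
    ylim <- range(0, ft$mean_avg_reward + ft$se, st$mean_avg_reward + st$se,
                  curve_y, na.rm = TRUE)
    graphics::plot(grid, curve_y, type = "l", col = "grey50", lty = 3,
                   xlab = "mean epsilon (normalized cortisol)",
                   ylab = "average reward", ylim = ylim,
                   main = "Foraging performance by cortisol group", ...)
    graphics::arrows(ft$mean_epsilon, ft$mean_avg_reward - ft$se,
                     ft$mean_epsilon, ft$mean_avg_reward + ft$se,
                     angle = 90, code = 3, length = 0.03, col = "black")
    graphics::points(ft$mean_epsilon, ft$mean_avg_reward, pch = 19)
    graphics::arrows(st$mean_epsilon, st$mean_avg_reward - st$se,
                     st$mean_epsilon, st$mean_avg_reward + st$se,
                     angle = 90, code = 3, length = 0.03, col = "red")
    graphics::points(st$mean_epsilon, st$mean_avg_reward, pch = 17,
                     col = "red")
    graphics::legend("topright", c("fish", "simulation", "exact expectation"),
                     pch = c(19, 17, NA), lty = c(NA, NA, 3),
                     col = c("black", "red", "grey50"), bty = "n")
  }
  if (2 %in% which) {
    ftr <- x$fish_trajectories; str_ <- x$sim_trajectories
    gs <- sort(unique(ftr$group))
    cols <- grDevices::hcl.colors(length(gs), "Dark 2")
    graphics::plot(NULL, xlim = c(1, max(ftr$trial)),
                   ylim = c(0, max(ftr$mean_cum_reward + ftr$se,
                                   str_$mean_cum_reward + str_$se)),
                   xlab = "trial", ylab = "mean cumulative reward",
                   main = "Cumulative reward by group", ...)
    for (i in seq_along(gs)) {
      f <- ftr[ftr$group == gs[i], ]
      s <- str_[str_$group == gs[i], ]
      graphics::lines(f$trial, f$mean_cum_reward, col = cols[i])
      graphics::lines(s$trial, s$mean_cum_reward, col = cols[i], lty = 2)
    }
    graphics::legend("topleft", paste("group", gs), col = cols, lty = 1,
                     bty = "n")
  }
  invisible(x)
}
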