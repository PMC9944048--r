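test_that("default synthetic cohort mirrors the study bookkeeping", {
  spec <- synthetic_cohort_spec(seed = 21)
  cohort <- generate_cohort(spec)
  expect_identical(nrow(cohort), 86L)
  expect_identical(sum(cohort$cortisol_flag == "valid"), 82L)
  expect_identical(sum(cohort$cortisol_flag == "assay_failed"), 3L)
  expect_identical(sum(cohort$cortisol_flag == "outlier"), 1L)
  # valid cortisol values fall inside their group's published range
  valid <- cohort[cohort$cortisol_flag == "valid", ]
  idx <- rep(seq_len(5), spec$group_sizes)
  expect_true(all(valid$cortisol_ng_ml >= spec$group_ranges[idx, 1] &
                    valid$cortisol_ng_ml <= spec$group_ranges[idx, 2]))
})

test_that("generation is deterministic under the spec seed", {
  a <- generate_cohort(synthetic_cohort_spec(seed = 5))
  b <- generate_cohort(synthetic_cohort_spec(seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(synthetic_cohort_spec(seed = 6))
  expect_false(identical(a, c))
})

test_that("generated cohorts pass the reader validation end to end", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(synthetic_cohort_spec(seed = 3)), path)
  back <- read_cohort(path)
  prep <- prepare_cohort(back, quiet = TRUE)
  expect_identical(nrow(prep), 82L)
  expect_equal(range(prep$normalized_cortisol), c(0, 1))
})

test_that("single-fish groups and one-trial cohorts are handled", {
  spec <- synthetic_cohort_spec(
    group_ranges = cbind(0:3, 1:4), group_sizes = rep(1L, 4),
    n_assay_failed = 0L, n_outlier = 0L, n_trials = 1L, seed = 9)
  cohort <- generate_cohort(spec)
  expect_identical(nrow(cohort), 4L)
  expect_true(all(cohort$cortisol_ng_ml >= 0:3 &
                    cohort$cortisol_ng_ml <= 1:4))
  expect_true(all(average_reward(cohort[, "trial_01", drop = FALSE]) %in%
                    c(0, 1)))
})

test_that("epsilon-greedy cohorts track the exact expectations by group", {
  # large groups so the Monte Carlo error is small
  spec <- synthetic_cohort_spec(group_sizes = rep(400L, 5),
                                n_assay_failed = 0L, n_outlier = 0L,
                                seed = 12)
  prep <- prepare_cohort(generate_cohort(spec), group_sizes = rep(400L, 5),
                         quiet = TRUE)
  gs <- group_summary(prep$avg_reward, prep$group,
                      epsilons = prep$normalized_cortisol)
  expected <- vapply(gs$mean_epsilon, expected_average_reward, numeric(1),
                     n_trials = 21)
  expect_true(all(abs(gs$mean_avg_reward - expected) < 3 * gs$se))
})

test_that("bernoulli cohorts recover their per-group success rates", {
  p <- c(0.3, 0.4, 0.45, 0.3, 0.27)
  spec <- synthetic_cohort_spec(group_sizes = rep(300L, 5),
                                n_assay_failed = 0L, n_outlier = 0L,
                                behavior_model = "bernoulli",
                                bernoulli_p = p, seed = 8)
  prep <- prepare_cohort(generate_cohort(spec), group_sizes = rep(300L, 5),
                         quiet = TRUE)
  gs <- group_summary(prep$avg_reward, prep$group)
  expect_true(all(abs(gs$mean_avg_reward - p) < 2 * gs$se + 1e-9))
})

test_that("spec validation rejects inconsistent configurations", {
  expect_error(synthetic_cohort_spec(group_ranges = cbind(5, 2)),
               class = "fb_invalid_parameter")
  expect_error(synthetic_cohort_spec(group_ranges = cbind(c(0, 1), c(3, 2))),
               class = "fb_invalid_parameter")
  expect_error(synthetic_cohort_spec(group_sizes = c(16, 17)),
               class = "fb_invalid_parameter")
  expect_error(synthetic_cohort_spec(behavior_model = "bernoulli",
                                     bernoulli_p = c(0.5, 0.5)),
               class = "fb_invalid_parameter")
})
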