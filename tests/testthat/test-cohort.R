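test_that("validity filtering keeps order and counts removals", {
  flags <- c(rep("valid", 82), rep("assay_failed", 3), "outlier")
  cohort <- make_cohort(c(seq(2, 140, length.out = 82), NA, NA, NA, 500),
                        flags = flags)
  kept <- suppressMessages(filter_valid(cohort))
  expect_identical(nrow(kept), 82L)
  expect_identical(kept$fish_id, cohort$fish_id[1:82])
  all_ok <- make_cohort(c(3, 9), flags = "valid")
  expect_identical(suppressMessages(filter_valid(all_ok))$fish_id,
                   all_ok$fish_id)
  mostly_bad <- make_cohort(c(5, NA, NA, NA, 900),
                            flags = c("valid", rep("assay_failed", 3),
                                      "outlier"))
  expect_error(suppressMessages(filter_valid(mostly_bad)),
               class = "fb_insufficient_data")
})

test_that("min-max normalization maps the range onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 5, 8)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(1.68, 135.40)), c(0, 1))
  expect_error(minmax_normalize(c(3, 3, 3)), class = "fb_degenerate_range")
  expect_error(minmax_normalize(3), class = "fb_insufficient_data")
  # idempotence on an already-normalized vector
  set.seed(1)
  v <- minmax_normalize(runif(40, 2, 140))
  expect_equal(minmax_normalize(v), v, tolerance = 1e-12)
})

test_that("ordered grouping forms contiguous ascending blocks", {
  set.seed(2)
  v <- runif(82)
  g <- assign_groups(v)
  expect_identical(as.integer(table(g)), c(16L, 17L, 16L, 16L, 17L))
  # ranges ordered and disjoint
  rng <- t(sapply(1:5, function(k) range(v[g == k])))
  expect_true(all(rng[-1, 1] > rng[-5, 2]))
  expect_identical(assign_groups(c(0.9, 0.1, 0.5), sizes = c(1, 1, 1)),
                   c(3L, 1L, 2L))
  # ties at a block boundary: lower input row goes to the lower group
  expect_identical(assign_groups(c(0.5, 0.5, 0.1), sizes = c(2, 1)),
                   c(1L, 2L, 1L))
  expect_error(assign_groups(runif(10), sizes = c(4, 4)),
               class = "fb_invalid_parameter")
})

test_that("average reward is the fraction of rewarded trials", {
  expect_equal(average_reward(c(rep(1, 7), rep(0, 14))), 1 / 3)
  expect_equal(average_reward(rep(0, 21)), 0)
  expect_equal(average_reward(rep(1, 21)), 1)
  expect_equal(average_reward(rbind(rep(1, 4), c(1, 0, 0, 0))),
               c(1, 0.25))
  expect_error(average_reward(c(0, 2, 1)), class = "fb_invalid_outcomes")
})

test_that("cohort CSV round-trips exactly", {
  cohort <- make_cohort(c(4.2, NA, 77.125, 130.9),
                        flags = c("valid", "assay_failed", "valid", "valid"),
                        outcomes = matrix(rbinom(4 * 21, 1, 0.5), 4, 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_identical(back$fish_id, cohort$fish_id)
  expect_equal(back$cortisol_ng_ml, cohort$cortisol_ng_ml,
               tolerance = 1e-9)
  tc <- grep("^trial_", names(cohort), value = TRUE)
  expect_identical(as.matrix(back[tc]), as.matrix(cohort[tc]))
})

test_that("schema validation rejects malformed cohorts", {
  cohort <- make_cohort(c(3, 9, 27))
  expect_error(validate_cohort(cohort[setdiff(names(cohort), "cortisol_flag")]),
               class = "fb_invalid_cohort")
  bad_flag <- cohort; bad_flag$cortisol_flag[2] <- "dubious"
  expect_error(validate_cohort(bad_flag), class = "fb_invalid_cohort")
  bad_out <- cohort; bad_out$trial_03[1] <- 2L
  expect_error(validate_cohort(bad_out), class = "fb_invalid_outcomes")
  no_cort <- cohort; no_cort$cortisol_ng_ml[1] <- NA
  expect_error(validate_cohort(no_cort), class = "fb_invalid_cohort")
  expect_error(read_cohort("no/such/file.csv"), class = "fb_missing_file")
})

test_that("prepare_cohort adds normalization, groups and rewards", {
  flags <- c(rep("valid", 10), "outlier")
  outcomes <- matrix(0L, 11, 21)
  outcomes[1, 1:7] <- 1L
  cohort <- make_cohort(c(seq(10, 100, length.out = 10), 999),
                        flags = flags, outcomes = outcomes)
  prep <- prepare_cohort(cohort, group_sizes = c(5, 5), quiet = TRUE)
  expect_s3_class(prep, "fish_cohort")
  expect_identical(nrow(prep), 10L)
  expect_equal(range(prep$normalized_cortisol), c(0, 1))
  expect_identical(prep$group, rep(1:2, each = 5))
  expect_equal(prep$avg_reward[1], 1 / 3)
})
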