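#' Specification of a synthetic fish cohort
#'
#' Describes the cohort the generator emulates: per-group basal-cortisol
#' ranges and sizes matching the study's published group structure, a
#' handful of records with invalid cortisol measurements, and 21 binary
#' foraging outcomes per fish produced by a behavioural model.
#'
#' @param group_ranges Two-column matrix (min, max) of cortisol intervals
#'   in ng/mL, one row per group, ordered and non-overlapping. Defaults to
#'   the published per-group ranges (see [betta_reference()]).
#' @param group_sizes Fish per group; default `c(16, 17, 16, 16, 17)`.
#' @param n_assay_failed Records flagged `assay_failed` (empty cortisol);
#'   default 3.
#' @param n_outlier Records flagged `outlier`; default 1. Together with
#'   `n_assay_failed` these are the invalid records appended to the cohort
#'   (default 4, giving 86 records of which 82 are valid).
#' @param n_trials Trials per fish; default 21.
#' @param behavior_model `"epsilon_greedy"`: outcomes generated by
#'   [run_episode()] with each fish's epsilon equal to its normalized
#'   cortisol; `"bernoulli"`: independent Bernoulli outcomes at per-group
#'   rates `bernoulli_p`.
#' @param bernoulli_p Per-group success rates for the Bernoulli model.
#' @param tie_break Greedy tie-breaking for the epsilon-greedy model.
#' @param seed Integer seed; every random draw in the generator flows from
#'   it through per-record derived streams.
#' @return An object of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(group_ranges = NULL,
                                  group_sizes = c(16L, 17L, 16L, 16L, 17L),
                                  n_assay_failed = 3L, n_outlier = 1L,
                                  n_trials = 21L,
                                  behavior_model = c("epsilon_greedy",
                                                     "bernoulli"),
                                  bernoulli_p = c(0.3, 0.4, 0.45, 0.3, 0.27),
                                  tie_break = c("first_index",
                                                "uniform_random"),
                                  seed = 1L) {
  if (is.null(group_ranges)) {
    ref <- betta_reference()
    group_ranges <- cbind(ref$cortisol_min, ref$cortisol_max)
  }
  group_ranges <- as.matrix(group_ranges)
  if (ncol(group_ranges) != 2L || anyNA(group_ranges))
    stop_fb("group_ranges must be a complete (min, max) two-column matrix",
            class = "fb_invalid_parameter")
  if (any(group_ranges[, 2] <= group_ranges[, 1]))
    stop_fb("each cortisol range needs max > min",
            class = "fb_invalid_parameter")
  if (nrow(group_ranges) > 1L &&
      any(diff(as.vector(t(group_ranges))) < 0))
    stop_fb("group cortisol ranges must be ordered and non-overlapping",
            class = "fb_invalid_parameter")
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != nrow(group_ranges) || any(group_sizes < 1L))
    stop_fb("group_sizes must be positive, one per group range",
            class = "fb_invalid_parameter")
  behavior_model <- match.arg(behavior_model)
  if (behavior_model == "bernoulli") {
    check_prob(bernoulli_p, "bernoulli_p")
    if (length(bernoulli_p) != length(group_sizes))
      stop_fb("bernoulli_p needs one rate per group",
              class = "fb_invalid_parameter")
  }
  structure(list(group_ranges = group_ranges, group_sizes = group_sizes,
                 n_assay_failed = as.integer(n_assay_failed),
                 n_outlier = as.integer(n_outlier),
                 n_trials = as.integer(n_trials),
                 behavior_model = behavior_model,
                 bernoulli_p = bernoulli_p,
                 tie_break = match.arg(tie_break),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Sample basal cortisol values for a synthetic cohort
#'
#' Draws `group_sizes[g]` values uniformly from `group_ranges[g, ]` for
#' each group (the published summaries give only ranges and means, and the
#' uniform is the least-informative distribution consistent with a range),
#' then appends the invalid records: `assay_failed` rows carry no cortisol
#' value, the `outlier` rows carry a value far above the measured range.
#' Invalid values are discarded before normalization, so their magnitude
#' is inert.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return Data frame with `fish_id`, `cortisol_ng_ml`, `cortisol_flag`.
#' @export
sample_cortisol <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  vals <- with_seed(derive_seed(spec$seed, 0L, offset = 1L), {
    unlist(lapply(seq_along(spec$group_sizes), function(g)
      stats::runif(spec$group_sizes[g], spec$group_ranges[g, 1],
                   spec$group_ranges[g, 2])))
  })
  flags <- c(rep("valid", length(vals)),
             rep("assay_failed", spec$n_assay_failed),
             rep("outlier", spec$n_outlier))
  cort <- c(vals, rep(NA_real_, spec$n_assay_failed),
            rep(10 * max(spec$group_ranges), spec$n_outlier))
  data.frame(fish_id = sprintf("fish_%03d", seq_along(flags)),
             cortisol_ng_ml = cort, cortisol_flag = flags,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort table
#'
#' Samples cortisol with [sample_cortisol()], min-max normalizes it within
#' the valid subset, and generates each fish's trial outcomes under the
#' chosen behavioural model. Under `"epsilon_greedy"` every fish is an
#' agent on a fresh 4-armed task (rewarding arm drawn uniformly per fish)
#' with epsilon equal to its normalized cortisol — the generative
#' assumption of the cortisol-as-exploration-rate model. Invalid records
#' still get complete outcomes (their exploration rate is drawn uniformly
#' on \[0, 1\], since no cortisol measurement exists for them); they are
#' excluded from every downstream analysis anyway.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A cohort data frame in the [read_cohort()] schema; deterministic
#'   given `spec` (including its seed).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_spec(seed = 42))
#' nrow(cohort)                                  # 86
#' sum(cohort$cortisol_flag == "valid")          # 82
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  base <- sample_cortisol(spec)
  valid <- base$cortisol_flag == "valid"
  eps <- numeric(nrow(base))
  eps[valid] <- minmax_normalize(base$cortisol_ng_ml[valid])
  eps[!valid] <- with_seed(derive_seed(spec$seed, 0L, offset = 2L),
                           stats::runif(sum(!valid)))
  groups <- integer(nrow(base))
  groups[valid] <- assign_groups(eps[valid], sizes = spec$group_sizes)

  out <- matrix(0L, nrow(base), spec$n_trials)
  for (i in seq_len(nrow(base))) {
    s <- derive_seed(spec$seed, i, offset = 3L)
    if (spec$behavior_model == "epsilon_greedy") {
      out[i, ] <- with_seed(s,
        .episode_rewards(eps[i], spec$n_trials, 4L, spec$tie_break))
    } else {
      p <- if (valid[i]) spec$bernoulli_p[groups[i]] else 0.25
      out[i, ] <- with_seed(s,
        as.integer(stats::runif(spec$n_trials) < p))
    }
  }
  colnames(out) <- sprintf("trial_%02d", seq_len(spec$n_trials))
  cohort <- cbind(base, as.data.frame(out))
  validate_cohort(cohort)
  cohort
}
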