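#' Cohort table input and output
#'
#' A cohort is a plain data frame with one row per fish and the columns
#' `fish_id`, `cortisol_ng_ml` (ng/mL; may be empty when the assay failed),
#' `cortisol_flag` (`valid`, `assay_failed` or `outlier`) and binary trial
#' outcomes `trial_01 ... trial_NN` (one column per trial, default 21).
#' Optional columns `normalized_cortisol` and `group` are written by
#' [prepare_cohort()] and round-trip unchanged.
#'
#' @param path Path of a UTF-8 CSV file with the header above.
#' @param records A cohort data frame to write.
#' @return `read_cohort()`: the validated cohort data frame.
#'   `write_cohort()`: `path`, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_fb("cohort file not found: ", path, class = "fb_missing_file")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fish_id = "character"))
  validate_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

trial_cols <- function(df) {
  cols <- grep("^trial_[0-9]+$", names(df), value = TRUE)
  cols[order(as.integer(sub("^trial_", "", cols)))]
}

#' Validate a cohort data frame
#'
#' Checks the schema described in [read_cohort()]: required columns, known
#' flags, complete binary trial outcomes, and nonnegative cortisol wherever
#' the flag is `valid`.
#'
#' @param records Cohort data frame.
#' @return The records, invisibly coerced (flags as character, outcomes as
#'   integer), for chaining.
#' @export
validate_cohort <- function(records) {
  if (!is.data.frame(records))
    stop_fb("cohort must be a data frame", class = "fb_invalid_cohort")
  need <- c("fish_id", "cortisol_ng_ml", "cortisol_flag")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_fb("cohort is missing columns: ", paste(miss, collapse = ", "),
            class = "fb_invalid_cohort")
  tc <- trial_cols(records)
  if (length(tc) < 1L)
    stop_fb("cohort has no trial_NN outcome columns",
            class = "fb_invalid_cohort")
  records$cortisol_flag <- as.character(records$cortisol_flag)
  bad <- setdiff(unique(records$cortisol_flag),
                 c("valid", "assay_failed", "outlier"))
  if (length(bad))
    stop_fb("unknown cortisol_flag value(s): ", paste(bad, collapse = ", "),
            class = "fb_invalid_cohort")
  out <- as.matrix(records[tc])
  if (anyNA(out) || !all(out %in% c(0, 1)))
    stop_fb("trial outcomes must be complete and binary (0/1)",
            class = "fb_invalid_outcomes")
  records[tc] <- lapply(records[tc], as.integer)
  cort <- suppressWarnings(as.numeric(records$cortisol_ng_ml))
  v <- records$cortisol_flag == "valid"
  if (any(v & (is.na(cort) | cort < 0)))
    stop_fb("valid records need a nonnegative cortisol_ng_ml value",
            class = "fb_invalid_cohort")
  records$cortisol_ng_ml <- cort
  invisible(records)
}

#' Keep only records with a valid cortisol measurement
#'
#' Drops rows flagged `assay_failed` or `outlier`, preserving order.
#' Normalization is undefined on fewer than two values, so at least two
#' valid records are required.
#'
#' @param records Cohort data frame.
#' @param quiet Suppress the per-flag removal counts message.
#' @return The valid records.
#' @export
filter_valid <- function(records, quiet = FALSE) {
  records <- validate_cohort(records)
  flags <- records$cortisol_flag
  kept <- records[flags == "valid", , drop = FALSE]
  if (!quiet) {
    rem <- table(factor(flags[flags != "valid"],
                        levels = c("assay_failed", "outlier")))
    message(sprintf("filter_valid: kept %d of %d records (removed %d assay_failed, %d outlier)",
                    nrow(kept), nrow(records), rem[["assay_failed"]],
                    rem[["outlier"]]))
  }
  if (nrow(kept) < 2L)
    stop_fb("fewer than 2 valid cortisol records; normalization undefined",
            class = "fb_insufficient_data")
  rownames(kept) <- NULL
  kept
}

#' Min-max normalization to the unit interval
#'
#' Rescales `values` so the minimum maps to 0 and the maximum to 1:
#' `(v - min) / (max - min)`. Applied to basal cortisol so the normalized
#' level can serve directly as an exploration probability.
#'
#' @param values Numeric vector, at least two values with `max > min`.
#' @return Numeric vector in \[0, 1\], order preserved.
#' @export
#' @examples
#' minmax_normalize(c(2, 5, 8))  # 0.0 0.5 1.0
minmax_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop_fb("need >= 2 non-missing numeric values",
            class = "fb_insufficient_data")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop_fb("all values identical; min-max normalization is degenerate",
            class = "fb_degenerate_range")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Ordered grouping by cortisol level
#'
#' Sorts fish by ascending value and assigns label 1 to the first
#' `sizes[1]` fish, label 2 to the next `sizes[2]`, and so on — contiguous
#' blocks whose value ranges cannot overlap. Ties at a block boundary go to
#' the lower group in input-row order (stable sort).
#'
#' @param normalized Per-fish numeric values (normalized cortisol).
#' @param sizes Integer block sizes summing to `length(normalized)`.
#'   Default `c(16, 17, 16, 16, 17)`, the study's five-group split of 82
#'   fish.
#' @return Integer group labels `1..length(sizes)`, one per fish, in input
#'   order.
#' @export
#' @examples
#' assign_groups(c(0.9, 0.1, 0.5), sizes = c(1, 1, 1))  # 3 1 2
assign_groups <- function(normalized, sizes = c(16L, 17L, 16L, 16L, 17L)) {
  sizes <- as.integer(sizes)
  if (anyNA(sizes) || any(sizes < 1L))
    stop_fb("group sizes must be positive integers",
            class = "fb_invalid_parameter")
  n <- length(normalized)
  if (sum(sizes) != n)
    stop_fb("group sizes sum to ", sum(sizes), " but there are ", n, " fish",
            class = "fb_invalid_parameter")
  ord <- order(normalized)              # radix sort: stable in input order
  labels <- integer(n)
  labels[ord] <- rep.int(seq_along(sizes), sizes)
  labels
}

#' Average reward of an outcome sequence
#'
#' Sum of the binary payoffs divided by the number of trials — the fraction
#' of trials on which the individual entered the rewarding arm first.
#'
#' @param outcomes Binary vector (one individual), or a matrix / data frame
#'   of binary outcomes with one row per individual.
#' @return A scalar in \[0, 1\], or one value per row for matrix input.
#' @export
#' @examples
#' average_reward(c(rep(1, 7), rep(0, 14)))  # 1/3
average_reward <- function(outcomes) {
  if (is.data.frame(outcomes)) outcomes <- as.matrix(outcomes)
  if (is.matrix(outcomes)) {
    check_binary(as.vector(outcomes), "outcomes")
    return(rowMeans(outcomes))
  }
  check_binary(outcomes, "outcomes")
  mean(outcomes)
}

#' Filter, normalize and group a cohort
#'
#' The full cohort preparation used throughout: keep valid records
#' ([filter_valid()]), min-max normalize their cortisol over the valid
#' subset ([minmax_normalize()]), assign ordered groups
#' ([assign_groups()]) and compute each fish's average reward.
#'
#' @param records Cohort data frame (e.g. from [read_cohort()]).
#' @param group_sizes Ordered group sizes; see [assign_groups()].
#' @param quiet Suppress progress messages.
#' @return The valid records with columns `normalized_cortisol`, `group`
#'   and `avg_reward` added; class `"fish_cohort"`. The number of records
#'   removed per flag is attached as attribute `"removed"`.
#' @export
prepare_cohort <- function(records, group_sizes = c(16L, 17L, 16L, 16L, 17L),
                           quiet = FALSE) {
  records <- validate_cohort(records)
  n_in <- nrow(records)
  kept <- filter_valid(records, quiet = quiet)
  kept$normalized_cortisol <- minmax_normalize(kept$cortisol_ng_ml)
  kept$group <- assign_groups(kept$normalized_cortisol, sizes = group_sizes)
  kept$avg_reward <- average_reward(kept[trial_cols(kept)])
  removed <- table(factor(records$cortisol_flag,
                          levels = c("assay_failed", "outlier")))[
    c("assay_failed", "outlier")]
  structure(kept, removed = removed, n_input = n_in,
            class = c("fish_cohort", "data.frame"))
}

#' @export
print.fish_cohort <- function(x, ...) {
  cat(sprintf("Fish cohort: %d valid records (of %d read), %d trials, %d groups\n",
              nrow(x), attr(x, "n_input"), length(trial_cols(x)),
              length(unique(x$group))))
  print(as.data.frame(x)[, c("fish_id", "cortisol_ng_ml",
                             "normalized_cortisol", "group", "avg_reward")],
        ...)
  invisible(x)
}
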