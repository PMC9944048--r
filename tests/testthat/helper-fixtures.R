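# Build a small cohort data frame in code (no stored fixtures).
# `outcomes` is a matrix with one row per fish; recycled rows allowed.
make_cohort <- function(cortisol, flags = "valid", outcomes = NULL,
                        n_trials = 21L) {
  n <- length(cortisol)
  flags <- rep_len(flags, n)
  if (is.null(outcomes))
    outcomes <- matrix(rep_len(c(1L, 0L), n * n_trials), n, n_trials)
  colnames(outcomes) <- sprintf("trial_%02d", seq_len(ncol(outcomes)))
  cbind(data.frame(fish_id = sprintf("f%02d", seq_len(n)),
                   cortisol_ng_ml = cortisol, cortisol_flag = flags,
                   stringsAsFactors = FALSE),
        as.data.frame(outcomes))
}

# Published group reference used across tests (verified external values).
ref_tab <- forageBandit::betta_reference()
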