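#' Published group-level reference values
#'
#' The measured group summaries of the original *Betta splendens* study,
#' provided as a built-in fixture: per cortisol group, the sample size, the
#' measured basal-cortisol range (ng/mL), the mean and standard error of
#' the normalized cortisol (the group's mean epsilon), and the mean and
#' standard error of the average reward after 21 trials for the fish and
#' for their simulated counterparts. The fish-side numbers are measured
#' data — they are inputs to comparisons, never recomputed.
#'
#' @return A data frame with one row per group and columns `group`, `n`,
#'   `cortisol_min`, `cortisol_max`, `epsilon_mean`, `epsilon_se`,
#'   `fish_mean`, `fish_se`, `sim_mean`, `sim_se`.
#' @export
#' @examples
#' betta_reference()
betta_reference <- function() {
  data.frame(
    group        = 1:5,
    n            = c(16L, 17L, 16L, 16L, 17L),
    cortisol_min = c(1.68, 12.78, 32.18, 90.50, 117.44),
    cortisol_max = c(10.69, 28.55, 87.35, 117.33, 135.40),
    epsilon_mean = c(0.0289, 0.1413, 0.4103, 0.8137, 0.9251),
    epsilon_se   = c(5.22e-3, 9.85e-3, 4.32e-2, 1.53e-2, 9.74e-3),
    fish_mean    = c(0.2976, 0.4034, 0.3690, 0.2054, 0.3165),
    fish_se      = c(0.0346, 0.0548, 0.0500, 0.0425, 0.0200),
    sim_mean     = c(0.2946, 0.4048, 0.4650, 0.3165, 0.2687),
    sim_se       = c(0.1031, 0.0899, 0.0605, 0.0271, 0.0307)
  )
}
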