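#' Standard error of the mean
#'
#' Sample standard deviation (denominator `n - 1`) divided by the square root
#' of the sample size. For a single observation the standard error is
#' undefined and `NA` is returned rather than zero.
#'
#' @param x Numeric vector.
#' @return Scalar standard error, or `NA_real_` when `length(x) < 2`.
#' @export
#' @examples
#' se(c(0, 1))  # 0.5
se <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit signed range. Distinct (offset, index) pairs give distinct streams
# so cohort runs are bit-reproducible regardless of evaluation order.
derive_seed <- function(seed, index, offset = 0L) {
  m <- 2147483647               # 2^31 - 1
  s <- (as.double(seed) %% m)
  ((s * 48271 + as.double(offset) * 1000003 + as.double(index)) %% m) + 1
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user scripts.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop_fb <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "forageBandit_error")))
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop_fb(name, " must lie in [0, 1]", class = "fb_invalid_parameter")
  invisible(p)
}

check_binary <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || !all(x %in% c(0, 1)))
    stop_fb(name, " must be a non-empty vector of 0/1 values",
            class = "fb_invalid_outcomes")
  invisible(x)
}
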