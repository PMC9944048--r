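---
title: "Modelling cortisol-modulated foraging as an epsilon-greedy bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortisol-modulated foraging as an epsilon-greedy bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageBandit)
```

## The model

The package treats a fish foraging in a four-arm maze as a learning agent
facing a 4-armed bandit: on each of $T$ trials the agent picks an arm
$A \in \{1, \dots, k\}$ and receives a binary reward $R$, which is 1 on
exactly one rewarding arm and 0 elsewhere. The agent follows the
$\varepsilon$-greedy policy: with probability $\varepsilon$ it explores
(a uniformly random arm, the current best included), otherwise it
exploits the arm with the highest action value. Action values are
sample averages, updated after every visit by

$$Q(A) \leftarrow Q(A) + \frac{1}{N(A)}\bigl[R - Q(A)\bigr],$$

where $N(A)$ counts visits to $A$ *including* the current one, so the
first visit sets $Q = R$. All $Q$ start at zero — no optimistic
initialization.

The biological hypothesis embedded in the model is that an individual's
exploration rate is its basal cortisol level: whole-body cortisol
(ng/mL) is min-max normalized over the cohort's valid measurements and
the resulting value in $[0, 1]$ is used directly as that individual's
$\varepsilon$. Performance is summarized by the *average reward*, the
fraction of rewarded trials, and by cumulative-reward trajectories. Both
very low $\varepsilon$ (an exploiter that may never find the rewarding
arm) and very high $\varepsilon$ (a forager that never settles) are
penalized at $T = 21$, producing the characteristic inverted-U between
cortisol and performance with an interior optimum.

## Parameters that matter

* `n_arms` — 4, fixed by the maze geometry.
* `n_trials` — 21 for the behavioural protocol; 400 for long-horizon
  simulations. Inferred from the cohort's `trial_NN` columns.
* `epsilon` — per-individual, in $[0,1]$; the normalized cortisol.
* `tie_break` — how the greedy branch resolves ties among equal-valued
  arms (all arms are tied before the first reward). `"first_index"` is
  the default: only this convention reproduces the published simulated
  group means (at $\varepsilon \approx 0.03$ it yields an expected
  average reward of $\approx 0.30$, matching the published 0.2946,
  whereas uniform-random tie-breaking yields $\approx 0.86$).
  `"uniform_random"` remains available as a configuration option.
* `group_sizes` — the ordered cortisol-group sizes, default
  `c(16, 17, 16, 16, 17)` for the 82-fish cohort. The published group
  table fixes which groups take 17 individuals.
* `replicates` — simulated episodes per fish; default 1 (one digital
  twin per fish, the study design). Large-scale checks raise it to beat
  Monte Carlo noise.
* `seed` — one integer per run; every episode and every generator draw
  uses a stream derived from it (seed plus stream index, reduced modulo
  $2^{31}-1$), so runs are bit-reproducible and independent of
  evaluation order.

The rewarding arm is drawn uniformly once per episode and held fixed.
In the maze the baited arm moved between trials but was marked by a
visible plate, so the learning problem the fish faces is "follow the
cue", a stationary task; re-drawing the arm every simulated trial would
cap the expected reward at $1/k$ for every $\varepsilon$, which the
published group means clearly exceed.

## The exact expectation oracle

With zero-initialized values and a single binary-rewarding arm, an
episode has only two belief states: the rewarding arm is undiscovered
(all $Q = 0$; the greedy branch falls back on the tie-break) or
discovered (its $Q$ is positive forever; the greedy branch locks on).
Once discovered, the per-trial success probability is
$h = 1 - \varepsilon (k-1)/k$. While undiscovered it is the probability
$d$ of stumbling on the rewarding arm: under first-index ties $d = h$
when arm 1 is rewarding and $d = \varepsilon / k$ otherwise; under
uniform-random ties $d = 1/k$. Discovery coincides with scoring, so

$$\mathbb{E}[R_t] = (1-d)^{t-1} d + \bigl(1 - (1-d)^{t-1}\bigr) h,$$

averaged over trials and mixed over the rewarding-arm draw. This is
`expected_average_reward()`, the noiseless value the Monte Carlo
simulator fluctuates around; the test suite holds the simulator to it
within three Monte Carlo standard errors across the whole
$\varepsilon$ range. Special cases give sharp anchors: $\varepsilon = 1$
gives exactly $1/k$; $\varepsilon = 0$ with first-index ties gives
$1/k$ (reward iff arm 1 happens to be rewarding); $\varepsilon = 0$
with uniform-random ties gives $1 - \frac{3}{T}(1 - 0.75^{T})$ at
$k = 4$. Evaluated on a grid at $T = 21$ the expectation peaks at
$\varepsilon = 0.35$ — an interior optimum; at $T = 400$ the optimum
moves toward lower $\varepsilon$, which is the long-run shift of the
best-performing group from group 3 to group 2.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces an 86-record cohort: 82 valid cortisol
measurements drawn uniformly within each group's published range
(uniform is the least-informative choice consistent with a printed
range; group means consequently approximate rather than equal the
published means), plus 3 `assay_failed` records (no cortisol value) and
1 `outlier` (a value far above the measured range). Outliers are never
auto-detected — the original exclusion criterion is unstated — so flags
must arrive with the data. Invalid records are dropped before
normalization, making their cortisol values inert; they still carry
complete trial outcomes (their unobservable $\varepsilon$ is drawn
uniformly) so schema validation never depends on flags. Trial outcomes
for valid fish come from the bandit model itself, or from independent
Bernoulli trials at per-group rates when a model-free cohort is needed.

Features of real data the generator does *not* reproduce: the measured
cortisol distribution within groups (only its range), any within-fish
trial-order effects beyond bandit learning, and the real cohort's
group-4 anomaly in which a quarter of the fish never scored. Passing
tests therefore certify the pipeline and the model's internal
consistency, not the biology.

A consequence of honest noise: a group of 16 fish, each contributing a
single 21-trial episode, has a group-mean standard error of about 0.06
— the same magnitude as the published simulation column's standard
errors. At that noise level the interior-optimum group (expected gap
$\approx 0.07$ over its neighbour) attains the highest observed mean in
only about 71% of generated cohorts, which matches the real data, where
the observed group-3 fish mean was itself not the cohort maximum. The
parameter-recovery check therefore reads the pipeline's simulated group
table at 30 replicates per fish (group-mean standard error
$\approx 0.01$), where the interior optimum is recovered essentially
always; single-episode group means are kept for what they are, a noisy
observable.

## Numerical choices and degenerate inputs

* Standard errors are everywhere the sample standard deviation
  (denominator $n - 1$) over $\sqrt{n}$; a singleton group's standard
  error is reported as `NA`, never 0.
* Min-max normalization requires at least two distinct values; a
  constant vector raises a degenerate-range error rather than dividing
  by zero. Fewer than two valid cortisol records is an error for the
  same reason.
* Grouping ties at a block boundary are resolved stably: the earlier
  input row goes to the lower group.
* Correlations require at least three points and nonzero variance in
  both arguments; leave-one-out correlations are only computed when at
  least three points remain.
* Report rounding is half-away-from-zero to 2 decimal places, matching
  conventional presentation; all stored values remain unrounded.
* Exploration draws use `floor(runif(1) * k) + 1` rather than
  `sample()`, keeping the per-trial RNG consumption pattern fixed.

## Problem sizes

The package's standard check sizes, chosen to pin each quantity well
below its decision threshold: 20,000 agents per $\varepsilon$ for the
headline group-mean reproduction (Monte Carlo standard error
$\approx 0.002$), 10,000 episodes per $\varepsilon$ for
simulator-versus-oracle agreement, 300 cohorts for estimating the
argmax distribution reported above, and 20 seeds at 30 replicates for
parameter recovery.

## Known limitations

The model is deliberately minimal: stationary rewards within an
episode, a single scalar linking physiology to behaviour, no softmax or
upper-confidence-bound alternatives, no between-group inference (none
was published), and no modelling of the cortisol assay itself. The
fish-side group means are measured data and enter only as fixtures for
comparison — nothing in the package can, or tries to, recompute them.
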