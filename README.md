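# forageBandit

Foraging in a multi-arm maze demands a balance between exploring
unfamiliar arms and exploiting the one known to hold food — the classic
exploration–exploitation tradeoff of the multi-armed bandit problem.
`forageBandit` models each individual forager (the motivating system is
Siamese fighting fish in a four-arm cross-maze, 21 trials) as an
ε-greedy learning agent whose exploration probability ε is its
min-max-normalized basal cortisol level. The package is for behavioural
ecologists and computational ethologists who want to simulate such
"digital twin" cohorts, summarize performance by cortisol group, and
quantify the agreement between observed and simulated foraging.

## The model

On each trial the agent picks an arm `A` of a k-armed bandit (k = 4,
one arm pays a binary reward `R`). With probability ε it explores a
uniformly random arm; otherwise it exploits the arm with the highest
action value, ties going to the lowest index. Action values are sample
averages, updated after each visit by

    Q(A) <- Q(A) + (1 / N(A)) * (R - Q(A))

with `N(A)` the visit count including the current visit, so the first
visit sets `Q = R`. Performance is the *average reward* — rewarded
trials divided by trials — summarized per cortisol group as mean ± SE.
Because both tiny ε (may never find the rewarding arm) and huge ε
(never settles on it) lose reward at short horizons, expected
performance traces an inverted-U over ε with an interior optimum.
Alongside the Monte Carlo simulator the package ships an exact
dynamic-programming oracle for the expected average reward, used
throughout the tests to pin the simulator down.

## Worked example

```r
library(forageBandit)

cohort <- generate_cohort(synthetic_cohort_spec(seed = 11))  # 86 records
fit <- bandit_twin(cohort, seed = 11, quiet = TRUE)
summary(fit)
#> Fish vs. simulation group comparison
#>
#>  group fish_mean    fish_se sim_mean     sim_se
#>      1    0.2440 0.10918469   0.1845 0.09250799
#>      2    0.3725 0.09835882   0.3277 0.09184088
#>      3    0.4524 0.07286907   0.4762 0.05976143
#>      4    0.4077 0.03959564   0.3988 0.03220159
#>      5    0.2605 0.02314105   0.2745 0.02328892
#>
#> Pearson r, all groups: 0.96
#> ...
#> Zero-reward individuals per group (fish):      12 7 4 0 0
#> Zero-reward individuals per group (simulated): 12 8 2 0 0
```

The comparison table gives, per ascending-cortisol group of the 82
valid fish, the observed ("fish") and digital-twin ("sim") mean average
reward with standard errors; `r` is the Pearson correlation between the
two columns of group means, with each leave-one-group-out scenario
listed. The zero-reward census counts individuals that never scored —
at ε ≈ 0.03 most agents never find the rewarding arm, hence 12 of 16.

The exact expectations at the fitted group mean ε values show the
inverted-U directly:

```r
round(predict(fit), 4)
#> group1 group2 group3 group4 group5
#> 0.2974 0.4376 0.5057 0.3732 0.2795
```

A cohort observed on disk works the same way: `bandit_twin("my.csv")`
reads the schema `fish_id,cortisol_ng_ml,cortisol_flag,trial_01,...`.
A command-line wrapper (`inst/scripts/forage-bandit`, subcommands
`synth | simulate | analyze | reproduce`) drives the same pipeline from
a shell; see `?fb_cli`.

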