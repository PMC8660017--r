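# wmload

Working-memory load effects and divisive normalization in single-neuron
spike data.

`wmload` is an analysis pipeline for delayed change-localization
experiments: a subject memorizes an array of two to five colored squares
(six screen locations, two possible colors each, one to three items per
visual hemifield), holds them across a memory delay, and reports which
square changed. The package quantifies how much information single neurons
carry about color identity, how that information changes with memory load,
and whether the change follows divisive normalization. A built-in
synthetic generator emulates the task and weighted-normalization Poisson
spiking, so the entire pipeline runs and is tested without any recorded
data.

## What it computes

**Behavior.** Per-session accuracy by ipsilateral (change-side) load,
ipsi-by-contra performance matrices, Cowan's capacity estimate
*K = n·p*, a Friedman test of the load effect with sessions as blocks,
and a linear model of performance on ipsilateral load, contralateral load,
and their interaction, with a reduced-model likelihood comparison.

**Information.** Per neuron and 200-ms bin, the bias-corrected percent
explained variance of spike counts by color identity,

    omega^2 = (SS_effect − df_effect·MS_error) / (SS_total + MS_error),

at the neuron's *favorite location* (highest cumulative sample-phase
omega² among candidate locations), with significance from a 1000-fold
label-permutation test (add-one p-value, ties counted against
significance). Neurons are classified by which loads yield significant
information (groups I–VII, pooled groups per load, sample/delay
populations), and population proportions are tested with an exact
binomial tail.

**Population.** Early/late sample (400 ms) and early/late delay (500 ms)
window statistics, one-way load-effect ANOVAs with Bonferroni post hocs,
one-sample tests of information above zero, correct-versus-error
comparisons with trial-count-matched subsampling (1000 draws, dependent
t-test, Cohen's d), and hierarchical clustering of load-1 timecourses
with a (1 − correlation) distance and average linkage.

**Normalization.** Whole-phase selectivity and sensory-interaction
indices per neuron,

    SE_i = PROBE_j − REF_i        SI_ij = PAIR_ij − REF_i

on max-normalized condition rates (eight index pairs per neuron), and the
pooled ordinary-least-squares regression of SI on SE. A slope of 0.5
means reference and probe items influence the pair response equally; for
weighted-mean normalization the noiseless slope is exactly
`w_probe / (w_ref + w_probe)`.

## Worked example

```r
library(wmload)

cfg     <- generative_config(n_sessions = 4, trials_per_session = 320,
                             rng_seed = 7)
trials  <- gen_behavior(gen_trials(cfg), cfg)
neurons <- neuron_population(8, cfg, seed = 7)
spikes  <- gen_spikes(trials, neurons, cfg, seed = 7)

performance_by_load(trials)$medians
#>      1      2      3
#> 0.9524 0.7750 0.5250

capacity_by_size(trials)
#>   n       p       K
#> 1 2 0.94375 1.88750
#> 2 3 0.84375 2.53125
#> 3 4 0.65625 2.62500
#> 4 5 0.64375 3.21875
```

Median accuracy falls from 95% to 53% as the change-side load grows from
one to three items, while the capacity estimate K saturates around three
items — the behavioral signature of a limited store.

```r
fl  <- favorite_location(spikes, trials, neuron_id = 7)
pev <- pev_timecourse(spikes, trials, 7, as.integer(fl),
                      n_perm = 1000, seed = 7)
aggregate(omega2 ~ load, pev[pev$phase == "sample", ], mean)
#>   load omega2
#> 1    1  0.234
#> 2    2  0.114
#> 3    3  0.041

classify_neurons(pev)[, c("phase", "sig_load1", "sig_load2", "sig_load3",
                          "group")]
#>   phase sig_load1 sig_load2 sig_load3 group
#>  sample      TRUE      TRUE      TRUE   VII
#>   delay     FALSE     FALSE     FALSE  <NA>
```

This sample-tuned neuron carries strong color information at load 1
(omega² ≈ 0.23 of the spike-count variance explained) that is roughly
halved by each added ipsilateral item — the divisive-normalization
signature — and it is significant at all three loads during the sample
phase only (group VII, sample population).

```r
pairs <- simulate_index_population(200, w_ref = 1, w_probe = 1,
                                   noise = "poisson", seed = 7)
fit_se_si_regression(pairs)
#> SI ~ SE: slope 0.497 (95% CI [0.492, 0.503]), n = 1600 pairs
#>   adj R^2 0.952, F(1, 1598) = 31561.51, p = 0
#>   differs from 0.5: FALSE; differs from 0: TRUE
```

An equal-weight population recovers the slope of 0.5: reference and probe
colors influence the simultaneous response evenly.

`run_pipeline(cfg, out_dir, seed)` executes every stage on one generated
dataset and writes the trial, spike, PEV, and classification tables as CSV
plus a JSON report and seed manifest.

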