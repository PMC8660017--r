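---
title: "Load-resolved information and divisive normalization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Load-resolved information and divisive normalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmload)
```

## The scientific problem

Working memory holds only a handful of items. In a delayed
change-localization task, a subject views an array of two to five colored
squares (six possible screen locations, three per visual hemifield, one of
two colors at each location), holds them across a memory delay, and then
reports which square changed color. Behavioral capacity saturates around
three to four items, and the drop in accuracy is driven almost entirely by
the number of items in the hemifield where the change occurs (the
*ipsilateral* load) — the two hemifields behave like largely independent
stores.

At the neuronal level, single cells in associative areas carry information
about the color at one screen position (the neuron's *favorite location*).
`wmload` quantifies that information, tracks how it degrades (or, for a
distinct subpopulation, emerges) as load grows, and tests whether the
degradation follows *divisive normalization*: when several items occupy a
neuron's hemifield, the response approximates a weighted mean of the
single-item responses rather than their sum.

## Information as bias-corrected explained variance

For each neuron, trials are grouped by the color identity (A or B) shown at
the favorite location, and spike counts in a time bin are decomposed by a
one-way ANOVA. Information is reported as the omega-squared percent
explained variance,

$$
\omega^2 \;=\; \frac{SS_\text{effect} - df_\text{effect}\, MS_\text{error}}
                    {SS_\text{total} + MS_\text{error}},
$$

computed exactly from the sums of squares (`omega_squared()`). Unlike
eta-squared, this estimator is bias-corrected, so chance-level data scatter
around zero and negative values are kept (truncating them would inflate
population averages). The `df` in the numerator is the effect degrees of
freedom (number of groups minus one), the standard form of the estimator.
Constant data leave the ratio undefined; such bins are flagged missing
rather than set to zero. Counts enter raw: omega-squared is invariant to
rescaling the counts of a bin, so no firing-rate normalization precedes it.

Timecourses use non-overlapping 200-ms bins, four across the 800-ms sample
phase and five across the 1000-ms delay (the same scheme in both phases,
half-open intervals $[a, b)$, sample onset at 0 s). The favorite location
is the candidate location — by default the three locations contralateral to
the recorded hemisphere — with the highest cumulative omega-squared over
the four sample bins at load 1, with exact ties resolved to the lowest
location index so the selection is deterministic.

### Permutation significance

Each bin's significance comes from a label-permutation test: the color
labels are permuted 1000 times and the information statistic recomputed
(`permutation_pev_test()`). The p-value uses the add-one estimator

$$
p = \frac{1 + \#\{\omega^2_\text{perm} \ge \omega^2_\text{obs}\}}{n_\text{perm} + 1},
$$

which can never return zero, and counts ties against significance. With
fixed data the total sum of squares is permutation-invariant, so comparing
$SS_\text{effect}$ is equivalent to comparing $\omega^2$; the
implementation uses that identity for speed. A bin is significant at
$p < 0.05$. No multiple-comparison correction is applied across bins by
default: correcting would keep only the most strongly tuned neurons and
thereby inflate the apparent information per retained neuron. A stricter
variant (`strict = TRUE` in `classify_neurons()`) instead requires two
consecutive significant bins.

Because spike counts are small integers, permuted statistics tie with the
observed one at an appreciable rate, and counting ties against
significance makes the test mildly conservative: under a color-independent
Poisson null at the scales used here (15 Hz, 200-ms bins, 30 trials per
color) the realized rejection rate at the 5% criterion is about 4%, not
5.0%. This is a property of the deliberately conservative tie convention,
not a fault in the permutation machinery; the continuous-statistic limit
of the same estimator rejects at 4.995%.

### Classification

A neuron is tested once per ipsilateral load condition (1, 2, 3 items in
the favorite hemifield). The three Boolean outcomes map onto seven groups
(I–VII, every non-null triple), and *pooled group g* collects all neurons
significant at load g. Phase-level flags (sample, delay) assign neurons to
the sample and delay populations; a neuron significant in both phases
belongs to both. The proportion of significant neurons is tested against
the 5% chance rate with an exact binomial upper tail
(`binomial_proportion_test()`).

## Population analyses

Window statistics pool counts over the first and second 400 ms of the
sample and the first and second 500 ms of the delay (one ANOVA per window,
`window_pev()`). Load effects on per-neuron window PEV use a one-way F
test with omega-squared effect size from the same decomposition and
Bonferroni-corrected pairwise t-tests (`load_effect_anova()`); information
above zero uses one-sample t-tests (`above_zero_test()`).

Error trials are rarer than correct ones, and omega-squared depends on
sample size, so correct-trial information is re-estimated by drawing —
without replacement, per color, 1000 times — exactly as many correct
trials as there are error trials, and averaging (`subsampled_omega2()`).
The averaged values are compared against error-trial values of the same
neurons with a dependent t-test and Cohen's d. When the target counts
equal the available counts there is a single possible draw and the
full-sample value is returned exactly; the estimator is demonstrably
near-unbiased as the subsample approaches the full sample.

Load-1 timecourses are clustered hierarchically with a
$(1 - \text{Pearson correlation})$ distance and average (UPGMA) linkage
(`cluster_timecourses()`). Traces are z-normalized per neuron first; the
correlation distance makes any per-trace affine normalization inert, which
is exactly why z-normalization is a safe reading of "normalized" here.
Within-cluster sum-of-squares is reported for k = 1..10 so the elbow can
be inspected; the default k = 7 is a reporting choice, not an enforced
elbow criterion, and is exposed as an argument. Constant traces have no
defined correlation and are excluded with a warning. Clusters are numbered
by dendrogram leaf order, so adjacent cluster ids are similar.

## The SE/SI divisive-normalization analysis

For each neuron and phase (the entire 800-ms sample or the entire 1000-ms
delay as one bin), mean rates are computed for the reference colors alone
at the favorite location, each probe color alone at the two other
ipsilateral locations, and each reference–probe pair shown simultaneously
(ipsilateral load 2; contralateral items are ignored throughout, encoding
hemifield independence). All condition means are divided by the
neuron-phase maximum condition mean. "Normalized firing rate" is not
otherwise pinned down by the index definitions; max-normalization was
chosen because it is the weakest transformation that guarantees both
indices lie in $[-1, 1]$ exactly:

$$
SE_i = \mathit{PROBE}_j - \mathit{REF}_i, \qquad
SI_{i,j} = \mathit{PAIR}_{i,j} - \mathit{REF}_i .
$$

Two reference colors times two probe locations times two probe colors give
eight index pairs per neuron-phase; the pair condition must show exactly
the reference and probe items (probe color matched to the probed
single-color condition). The pooled regression of SI on SE across a neuron
group (`fit_se_si_regression()`) is ordinary least squares; pooling
follows from the design, where every stimulus combination is informative
about the normalization. A slope of 0.5 means reference and probe weigh
equally in the pair response; under the weighted-mean rate law
$r = (w_\text{ref} r_\text{ref} + w_\text{probe} r_\text{probe}) /
(w_\text{ref} + w_\text{probe})$ the noiseless slope is exactly
$w_\text{probe} / (w_\text{ref} + w_\text{probe})$, an identity the test
suite checks to machine precision. Comparisons against 0.5 (and 0) use
95% confidence-interval inclusion, the weakest reading consistent with
reporting "not significantly different from 0.5".

Neurons enter this analysis in three disjoint groups per phase, defined by
whole-phase permutation significance: information-carrying (significant at
load 1), information-gaining (significant at load 2 but not load 1), and
non-informative (neither).

## The synthetic generator

The generator (`gen_trials()`, `gen_behavior()`, `gen_spikes()`) emulates
the task so that every analysis stage is testable without recordings:

* **Trials.** Six locations, colors A/B, hemifield loads 1–3 with total
  array size 2–5 (eight valid combinations, balanced exactly up to
  rounding within sessions); displayed locations, colors, and the target
  drawn uniformly. Epochs: 160-ms fixation, 800-ms sample, 1000-ms delay.
* **Behavior.** A trial is correct with a probability depending only on
  the ipsilateral load — defaults (0.9588, 0.7831, 0.5821) are the
  reported median accuracies for loads 1–3 in the crow change-localization
  data this pipeline targets — optionally modulated by an
  ipsi-by-contra interaction term of the form
  $\beta (L_i - 1)(L_c - 1)$, defaulting to zero. The functional form of
  any interaction is not constrained by the behavioral findings, so the
  generator exposes the coefficient and otherwise stays contra-free.
  Errors are uniform over displayed non-target locations, since error
  placement is not modeled by the analyses.
* **Spiking.** Homogeneous Poisson per epoch: baseline rate (default
  10 Hz) during fixation, and during sample/delay the weighted-normalized
  mean of the single-item rates of the items in the favorite hemifield
  (weights `w_ref`, `w_probe`, defaults 1/1 — the equal-influence regime).
  Contralateral items never enter the rate law. Tuning (default 10 Hz
  between colors at the favorite location, probe items at 5 Hz) applies in
  the phases a neuron's type prescribes; "gaining" neurons have equal
  single-color rates but color-matched pair weights, so differentiation
  appears only at load 2. The default type mix
  (sample/delay/both/gaining/untuned = 0.30/0.10/0.10/0.20/0.30) follows
  the reported population proportions of sample-, delay-, and
  dual-significant neurons and the sizeable load-2-gaining fraction.
  No refractoriness or autocorrelation is modeled: the analyses consume
  only bin counts, for which Poisson is the simplest consistent process.

All randomness flows from explicit integer seeds; sub-streams (per neuron,
per load, per bin) are derived arithmetically from the master seed so
results are reproducible and independent of evaluation order.

What the generator deliberately does **not** emulate: real spike-train
autocorrelation and bursting, rate drift and session nonstationarity,
eye/head movements, reaction times, local field potentials, and any
attentional dynamics beyond the static pair weights. Passing tests on
generated data therefore validate the statistical machinery and its
calibration, not the biological claims themselves.

## Numerical choices and degenerate inputs

* Half-open bins $[a, b)$; a spike exactly on an edge belongs to the
  right-hand bin; bin widths must divide epoch durations (no partial
  bins).
* Constant data: omega-squared flagged `NA`; permutation p fixed at 1
  (every permutation ties); constant traces excluded from clustering;
  zero-variance inputs to t-tests flagged degenerate with t of 0 or signed
  infinity.
* Friedman test of the load effect requires complete session blocks and at
  least two sessions; incomplete sessions must be removed listwise.
* The load model is Gaussian-identity least squares on session-level
  proportions (the reported t statistics and adjusted R-squared imply a
  linear model); predictors stay on their raw 1–3 scale by default, with
  centering as an option. The reduced model omits the contralateral main
  effect but keeps the interaction, and model comparison reports the
  absolute log-likelihood difference.
* Contralateral-load timecourses hold the ipsilateral load at one item
  (configurable) while the opposite-hemifield load varies.

## Problem sizes

The test suite and the acceptance script size their simulations for
precision at interactive timescales: 120–250 synthetic neurons (about
1000–2000 index pairs) for slope recovery, 5000–8000 neuron-bins at 1000
permutations each for the null calibration of the permutation test, 600 to
a few thousand trials per generator check, and 1000–2000 subsample
repetitions. At those sizes the Monte Carlo standard error of the
calibration estimate is under 0.3 percentage points and slope estimates
are recovered to well under 0.01.

## Known limitations

* The SE/SI analysis assumes each neuron has well-estimated condition
  means; with very few load-2 trials per exact pair condition, index pairs
  are skipped rather than imputed, which can shrink the design below eight
  pairs per neuron.
* Max-normalization ties all conditions to the single largest response; a
  neuron with one outlying condition mean compresses the remaining
  indices. Min-max and baseline-subtraction variants are reasonable
  alternatives and would change slopes only through this compression.
* The permutation test's tie conservatism (about one percentage point at
  typical count sizes) is inherent to the chosen estimator; analyses that
  need exact 5% size should increase trial counts or bin widths.
* Cluster count selection is visual by design; the within-cluster
  sum-of-squares curve is emitted rather than an automatic elbow rule.
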