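---
title: "Permuted split-half reliability of oculomotor difference scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permuted split-half reliability of oculomotor difference scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In oculomotor visual-search tasks each trial ends when the eyes fixate the
target (or the time limit expires).  Two per-subject measures summarise
distractor processing: the probability that the *first* saccade lands on a
salient distractor (oculomotor capture), and the latency until the target is
fixated (fixation time).  The individual-differences quantity is a
difference score between a critical and a baseline distractor condition —
for instance, capture on low- minus high-probability distractor-location
trials indexes learned suppression of the high-probability location.
Whether such scores are usable for individual-differences research depends
on their internal consistency, which this package estimates.

## The estimator

A single odd/even split is arbitrary and noisy, so the engine uses a
permuted random split.  One permutation:

1. **Stratified split.** Within every subject × condition × run stratum the
   trials are partitioned at random into two halves of exactly equal size.
   Balancing per condition *and* per run keeps both halves representative
   in the presence of time-dependent effects (learning, extinction), which
   is why datasets pooling distinct phases must encode them as separate
   runs.  Halves are then concatenated over runs.
2. **Scoring.** On each half, for each subject, the measure is computed per
   condition and differenced along the declared `(minuend, subtrahend)`
   direction.
3. **Correlation.** The two per-subject difference-score vectors are
   Pearson-correlated.

Repeating `n_perm` times (default 1000) and averaging the coefficients
gives the split-half reliability `r`; the Spearman–Brown correction
`2r / (1 + r)` extrapolates to full test length.  The coefficients are
averaged directly, not through a Fisher-z transform: with the
permutation-to-permutation spread of coefficients small relative to their
level, the two conventions differ negligibly, and the direct mean is the
convention the reported quantity is defined by.

### Confidence intervals

Both `r` and `r_SB` carry Fisher-z intervals: `z = atanh(r)`, standard
error `1 / sqrt(n - 3)` with `n` the number of subjects, normal quantiles,
back-transformed by `tanh`.  The interval for the corrected coefficient is
the Fisher interval of the corrected *point estimate* — not the
Spearman–Brown transform of the uncorrected interval's endpoints, which is
the other defensible convention but produces wider, asymmetric bounds.
Both conventions were checked against the worked interval examples the test
suite encodes; only the adopted one reproduces them.

### Numerical and degenerate-case policy

* **Odd strata.** A stratum with an odd trial count drops one uniformly
  random trial *for that permutation only*, preserving exact equality of
  half sizes.  Deterministic alternation was rejected because it breaks
  exact balance, and carrying the extra trial in one half would bias the
  half sizes the Spearman–Brown step assumes equal.
* **Timeouts.** Trials with no registered eye movement to the target
  (`first_fixation = "none"`) are excluded from the capture denominator by
  default (`timeout_policy = "exclude_none"`).  Counting them as
  non-capture (`"count_none"`) is available but biases rates downward in
  datasets with many timeouts.  For fixation time such trials contribute no
  latency by construction.
* **Insufficient data.** A subject × condition cell with zero scored trials
  yields `NA`; the subject is excluded for that permutation (or, when the
  full dataset is affected, excluded up front and reported).  Permutations
  with fewer than 3 usable subjects, or zero variance in either half's
  scores, record an undefined coefficient, which is excluded from the mean
  and counted in `n_undefined` — substituting 0 would pull the estimate
  toward zero with no justification.
* **Outlier screen.** `outlier_zscores()` standardises the per-subject
  scores and flags `|z| >= 3` (configurable).  It is diagnostic only: the
  engine never removes subjects on this basis.
* **Seeding.** One master seed; each permutation consumes an independent
  sub-seed drawn sequentially from it, so enlarging `n_perm` extends rather
  than reshuffles the coefficient sequence, and every result is
  bit-reproducible.
* **Reporting.** r-type quantities are reported to 3 decimals.

## Comparing reliabilities

`randomization_test()` pools the two measures' per-permutation coefficient
vectors, repeatedly re-assigns them at random to two groups of the original
sizes (without replacement), and recomputes the difference of group means.
The reported `p` is the two-tailed normal tail probability of
`z = (observed - mean(null)) / sd(null)`; two-tailed is the conservative
reading of a z-based rule, and a one-tailed option exists.  An empirical
permutation `p` with +1 smoothing is attached as a robustness check.  Two
degenerate cases return `p = 1` with a warning: a zero-variance null and
pools identical as multisets (self-comparison), where the test is vacuous.

Note the test's sensitivity: the "observations" are permutation
coefficients of the *same* dataset, so their pooled spread reflects
split-to-split noise only.  Small reliability differences can therefore
reach extreme z-scores.  This is a property of the published procedure the
package implements, not of this implementation.

## The synthetic generator

`sim_config()` / `generate_dataset()` produce cohorts with known structure:

* Capture: subject intercept `b_i ~ N(0, sigma_b^2)` and condition effect
  `d_i ~ N(delta, tau^2)` on the log-odds scale; a trial in condition `c`
  is "captured" with probability `plogis(mu + b_i + d_i [c = critical])`.
  A logistic-normal model was preferred to beta-binomial because the
  reliability-controlling heterogeneity enters additively on the logit
  scale, making `tau` directly interpretable.
* First fixations: a captured trial fixates the distractor (or, on
  distractor-absent trials of the `search_mode` preset, a non-target — the
  event the proxy-distractor rate measures); a non-captured trial fixates
  the target with probability 0.7 and a non-target otherwise
  (`nontarget_share = 0.3`, a modelling choice that exercises the proxy
  measure, not an empirical claim).
* Latency: base (`latency_mean_ms`, default 350 ms) + subject offset
  (SD 60 ms) + condition offset on critical trials (preset sign, SD 25 ms)
  + lognormal trial noise (mean fixed at 150 ms, `sdlog` 0.45), truncated
  at the preset time limit; truncated trials become `"none"`/missing.

The presets encode the three paradigm designs the analysis targets: set
size 6 with a 1500 ms limit and a 45%/55% high/low-probability location
split (`statistical_learning`); set size 6, 1000 ms, equal CS+/neutral
counts (`conditioned_distractor`); set size 4, 2000 ms, distractor present
vs absent equally often (`search_mode`).  Default cohort sizes (40
subjects, 2 runs, 30 trials per condition per run) are round numbers of the
magnitude typical for these paradigms — the original designs' exact trial
counts are not published, and the presets are not reproductions of them.

The generator emulates the statistical structure the estimator assumes —
conditionally independent trials given subject effects, heterogeneous
condition effects, right-skewed latencies, timeouts — and deliberately
omits sequential dependence (fatigue, drift within a run), saccade
kinematics and gaze geometry.  Passing recovery tests therefore validates
the estimator under exchangeable trials; it does not certify behaviour on
data with strong serial structure, which is exactly the situation the
per-run stratification is designed to mitigate, not eliminate.

### Ground truth and what "recovery" means

`true_split_reliability()` estimates the expected half-vs-half correlation
by simulating, for many replicate cohorts, two *independent* halves at the
per-half trial counts the stratified split produces (`floor(m/2)` per
condition per run) and correlating their difference scores.  Because trials
are conditionally independent given subject effects, a within-dataset
split and a fresh simulation at half size have the same expected
correlation, which is what makes this an independent oracle for the engine.

Two points matter when interpreting recovery checks:

* `tau = 0` alone does **not** imply zero reliability: with `sigma_b > 0`
  the probability-scale difference still varies across subjects because the
  logistic link is nonlinear.  The no-individual-differences null therefore
  sets `sigma_b = 0` as well.
* A single simulated cohort's `mean_r` scatters around the population value
  with an across-cohort SD of roughly `(1 - r^2)/sqrt(n_subjects)` (about
  0.1 at 40 subjects under the null), so validation compares Monte-Carlo
  *averages* over cohorts (10 null cohorts; 16 mid-range cohorts against an
  oracle of 500 replicates) — sizes at which the Monte-Carlo error is
  comfortably inside the tolerances being enforced.

```{r example}
library(ocureliab)
cfg <- sim_config("statistical_learning", n_subjects = 36, tau = 0.9,
                  seed = 11)
d <- generate_dataset(cfg)
split_half(d, "capture", n_perm = 1000, seed = 2)
true_split_reliability(cfg, "capture", n_mc = 500, seed = 3)
```

## Data interchange

Trials travel as tidy CSV — one scored trial per row, fixed column order,
empty field for a missing latency (never a sentinel number, which would
silently enter means), latencies written to 1 decimal so read/write round
trips are byte-identical — with the paradigm metadata in a JSON sidecar.
Validation reports *all* violating rows, not the first.  `trial_index`
is 0-based within run and preserves presentation order.

## Limitations

* Only within-session internal consistency is estimated; test–retest
  (between-session) stability is out of scope.
* The capture and fixation-time difference scores are the two supported
  measures; accuracy- or kinematics-based measures are not.
* The Fisher-z interval convention and the z-based p-value follow the
  published procedure; bootstrap intervals over subjects and
  dependent-correlation tests (Williams/Steiger) are deliberately not
  offered, as the resampling scheme itself is the contract being
  implemented.
* Event detection is upstream: the package consumes categorical
  first-fixation labels, not raw gaze data.
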