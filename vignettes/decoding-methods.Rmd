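---
title: "Time-resolved MVPA of epoched MEG data: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved MVPA of epoched MEG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

`megmvpa` implements sensor-level multivariate decoding for a
statistical-learning visual-search experiment. On each trial a placeholder
display appears (time 0 s by convention), followed 1.5 s later by a search
display in which a target must be identified while a color-singleton
distractor (present on 66% of trials) is ignored. The distractor appears in
one hemifield on 75% of distractor-present trials, and the high-probability
hemifield swaps between the two sessions. The scientific questions the
pipeline addresses are: (1) is the distractor's hemifield decodable from
sensor activity *before* the search display (proactive spatial prediction)?
(2) does the pre-search spatial code re-emerge after search onset
(temporal/cross-epoch generalization)? (3) does the previous trial's
distractor location linger in current-trial activity and transfer to the
current location (intertrial, N−1 analyses)?

Because the underlying recordings are not publicly archived, the package
ships a first-class synthetic-data generator that emulates the design and
plants controllable spatial codes. Every statistical claim the test-suite
makes is made about this generator.

## Decoding model

For a two-class label y ∈ {left, right} and time center t, the feature
vector concatenates all sensors over a centered window of `window_samples`
samples (default 5, i.e. 25 ms at 200 Hz; with 306 sensors this is the
familiar 306 × 5 = 1530-element vector). Edge centers whose window would
leave the epoch are excluded, not padded.

Per session the discipline is:

1. drop trials whose label is NA or "absent";
2. if classes are unequal and `balance = TRUE`, randomly subsample the
   majority class to the minority count (a single seeded draw);
3. stratified K-fold split of raw trials (K = 5);
4. within each fold, *pseudotrials* are formed separately in the training
   and test partitions: a random partition of each class into groups of
   exactly m = 5 trials (remainder dropped), averaged. Averaging commutes
   with time-windowing, so group-averaged trials are computed once per fold;
5. z-scoring with mean/SD (n−1) estimated on training pseudotrials only;
   features with zero training SD are mapped to zero in both partitions;
6. optional univariate feature selection by one-way ANOVA F, computed on the
   training partition only;
7. a linear classifier — hinge-loss SVM (cost 1) by default, ridge-penalized
   logistic regression for generalization analyses — reduced to explicit
   weights so held-out scoring is a matrix product;
8. held-out performance as ROC AUC (the Mann–Whitney pair statistic, ties
   half-credited).

Sessions are decoded independently and averaged within subject; group
inference operates on the subject-by-time AUC matrix. Weights can be
transformed to encoding (activation) patterns as Cov(X)·w with unit-norm
scaling, the standard interpretation-safe transform for linear decoders.

Decisions taken where the procedure was genuinely open:

* **"Five samples around each time point"** is read as a centered window
  (±2 samples).
* **Pseudotrial draws per fold** default to one; `n_repeats` averages over
  repeated draws if desired.
* **Standardization in generalization analyses** is estimated on training
  pseudotrials at the train time and applied to test features at every test
  time (the convention of sliding-estimator implementations in the MEG
  ecosystem).
* **Label transfer** (train on the previous trial's distractor hemifield,
  test against the current one) restricts trials to those where both labels
  are defined, balances on the train label, and groups train-side
  pseudotrials by the train label and test-side pseudotrials by the test
  label, so each pseudotrial is pure in the label it is scored against.
  With identical train and test labels this reduces exactly to ordinary
  decoding.
* **Previous-trial labels** reset at block boundaries; distractor-absent
  previous trials are labelled "absent" and excluded from N−1 decoding.

## Group statistics

Point-wise two-tailed one-sample t tests against chance (0.5) form clusters
by adjacency — runs on the time axis, 4-connected components on the
train × test lattice — separately by sign; the cluster statistic is the
summed t (mass). The null distribution of the maximum |mass| is obtained by
sign-flipping subject-level deviations. The literature's description of
"randomizing condition labels" at group level is, for a one-sample design,
equivalent to this subject-level sign-flip; we state the adopted scheme
rather than guess at implementation details of others. Monte-Carlo p-values
use the (k+1)/(B+1) convention (B = 1024 by default), so p is never exactly
zero; whenever B ≥ 2^n − 1 all sign patterns are enumerated exactly.

Windowed tests average subject curves over closed 50 ms windows (centers
100 and 200 ms by convention), apply one-sample t tests, and correct with
Benjamini–Hochberg FDR across all windows and curve directions tested in
one call — the family is the call. Each window also gets a JZS Bayes factor:
a Cauchy(0, r = √2/2) prior on the standardized effect, marginal likelihood
by adaptive quadrature. For the t(19) = 2.08 statistic this quadrature gives
BF10 ≈ 1.36.

## The synthetic generator

`generate_design()` realizes the design with *exact counts* — probabilities
are rounded (half-up) to per-session counts and the order shuffled — so a
generated session reproduces the design percentages (66%, 75/25, 50/50)
exactly rather than in expectation. `make_effect_patterns()` constructs five
unit-norm, zero-mean sensor patterns by Gram–Schmidt so that requested
correlations (presearch–late 0.8, presearch–early 0 by default) are
realized exactly; zero-mean makes Pearson correlation coincide with the
inner product. `simulate_epochs()` plants each pattern as
sign(label) × amplitude × envelope(t), with a boxcar envelope and 25 ms
half-Gaussian ramps, on top of Gaussian noise with a seeded random sensor
covariance (mixing weight 0.2 with the identity) and a 10 ms moving-average
temporal smoothing.

Default planted effects, in noise-SD units:

| effect | pattern | window (s) | amplitude | signed by |
|---|---|---|---|---|
| presearch | p_pre | 0.10–0.70 | 0.4 | current distractor hemifield |
| early reactive | p_early | 1.575–1.625 | 0.4 | current distractor hemifield |
| late reactive | p_late | 1.675–1.725 | 0.4 | current distractor hemifield |
| target | p_target | 1.675–1.725 | 0.4 | current target hemifield |
| carryover | p_carryover | 0.10–0.70 | 0.4 | previous distractor hemifield |

Pattern correlations with p_pre default to 0.8 (late), 0 (early), 0
(target, exact orthogonality) and 0.8 (carryover).

A point worth spelling out, because it determines what the intertrial
transfer analysis can show: in this design consecutive distractor locations
share a 75/25 *marginal* but are statistically independent — the bias does
not correlate trial N−1 with trial N. A decoder trained on the
previous-trial label therefore learns only the carryover pattern, and
transfer to the current-trial label is exactly at chance unless the
carryover pattern overlaps the presearch pattern. Above-chance
previous→current transfer is thus evidence that the lingering
previous-location trace and the anticipatory current-location code share
one spatial mechanism; the generator expresses this with
`rho_pre_carryover = 0.8` by default, and setting it to 0 (or the carryover
amplitude to 0) puts transfer at chance.

The empirical effect sizes of real recordings are unknown; 0.4 was chosen
once, at design time, as the smallest round amplitude that a 20-subject
simulated group recovers reliably at the package's scaled working size — it
is deliberately *stronger* than typical empirical MEG decoding (where group
AUC rarely exceeds ~0.6). The generator emulates the design's label
structure and spatially patterned, spatially correlated noise; it does not
emulate 1/f spectra, evoked transients, artifacts, forward-model geometry
or between-subject pattern similarity. Passing recovery tests therefore
demonstrates the *pipeline's* correctness and sensitivity, not what real
data would show.

Distractor-absent trials carry full noise but no distractor signal and stay
in the epoch container; they are filtered at decoding time, since only
left-vs-right is decoded.

## Conventions and numerical choices

* Time axis: 0 s = placeholder onset, 1.5 s = search onset; default epochs
  span [−0.5, 2.5) s at 200 Hz (600 samples) — every analyzed window at 40%
  of the recorded storage.
* All intervals are half-open [t0, t1), making sample counts unambiguous
  (slicing [0, 1.5) at 200 Hz gives exactly 300 samples).
* SD convention: n−1 denominator everywhere; zero-SD features floored and
  mapped to 0.
* Zero-variance t statistics return ±Inf with p = 0 and a warning.
* Degenerate covariance in the activation-pattern transform is ridged with
  1e−10 of the mean feature variance.
* Every random draw flows from a master seed through `derive_seed(seed,
  tag)`, a pure function; re-running any analysis with the same config and
  seed is bit-identical at the result-file level.

## Problem sizes used by the shipped tests

The test-suite exercises the pipeline at a scaled working size chosen for a
single desktop core: 64 sensors and 240 trials per session (the full
306-sensor, 720-trial configuration is available through the same
constructors) with strided decoding grids of 50–100 ms. Two analyses are
sized differently on purpose: the previous→current transfer analysis uses
full 720-trial sessions because the joint previous × current label
filtering plus class balancing leaves too few minority-class trials per
test fold to form 5-trial pseudotrials at 240 trials/session — an
arithmetic constraint of the method, visible in its error message — and the
statistical-calibration suites (family-wise error of the cluster test; the
no-leakage null of the full pipeline) run hundreds of smaller simulations
(20 × 100 null matrices with B = 512; 8-subject groups at 16 sensors).

## Worked example

```r
library(megmvpa)

# one simulated subject, scaled size
tab <- generate_design(design_config(trials_per_block = 40, seed = 1))
pat <- make_effect_patterns(n_sensors = 64, rho_pre_late = 0.8, seed = 1)
ep  <- simulate_epochs(tab, pat, planted_effects(), noise_spec(seed = 1))

# time-resolved distractor decoding over the presearch window
res <- decode_timecourse(ep, "distractor_hemifield",
                         decoding_config(time_step = 10, seed = 1),
                         t_window = c(0, 1.5))
plot(res$times, colMeans(res$auc), type = "l",
     xlab = "time (s)", ylab = "AUC"); abline(h = 0.5, lty = 2)
```

With several subjects (a list of epoch sets), `cluster_permutation_1d()`
tests the group AUC against chance, `temporal_generalization()` and
`cross_epoch_curves()` probe shared representations across time, and
`run_pipeline()` orchestrates everything from one config and seed.

## Known limitations

* Only two-class (hemifield) decoding; no 4-location multinomial decoding,
  searchlight or source-space analysis.
* No raw-MEG import (FIF/BIDS), filtering or artifact handling — the epoch
  container is the entry point for real data.
* The sign-flip permutation scheme is the group-level one-sample standard;
  trial-level label permutation within subject is not implemented.
* The cluster test's spatial variant covers the train × test lattice only;
  sensor-adjacency clustering is out of scope.
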