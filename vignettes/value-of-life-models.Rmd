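---
title: "Value-of-life choice models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-of-life choice models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralchoice)
```

This vignette documents the statistical model behind `moralchoice`, the
conventions and numerical choices that a reader would otherwise have to
reverse-engineer from the code, and what the package's simulation-based
validation does and does not establish.

## The choice model

Each trial presents two distinct obstacles, one per lane, and records
which lane the driver finally drove into (`chosen_lane`; the obstacle on
that lane is hit, the other is spared). All models are binary logistic
models of the probability of choosing the left lane,

$$p(Y = \mathrm{left} \mid X) = \frac{1}{1 + e^{-X}},$$

with three nested-in-spirit predictor families:

* **pairing**: $X = c\,\omega_i + s\,\omega_s + \omega_b$ with one free
  coefficient per unordered pairing. $c = +1$ when the canonically-first
  obstacle of the pair (catalog order) sits in the left lane, $-1$
  otherwise. With 18 obstacles there are 153 pairings and, with both
  bias terms, 155 parameters.
* **obstacle**: $X = \omega_r - \omega_l + s\,\omega_s + \omega_b$, one
  coefficient per obstacle (20 parameters). A larger coefficient means a
  more-spared obstacle — driving into the *other* lane — so the
  coefficients read directly as a value-of-life scale.
* **cluster**: the obstacle model with coefficients tied within obstacle
  clusters; with the five semantic categories (empty, object, animal,
  human, group) this is 7 parameters. Within-cluster pairings contribute
  zero to every cluster column, so those predictions are carried
  entirely by the bias terms.

### Sign conventions

Two conventions are easy to get wrong and are therefore fixed once,
stated in every fit's printout:

* the starting-lane predictor is $s = +1$ for a left start, $-1$ for a
  right start. A **positive** $\omega_s$ therefore raises the
  probability of choosing the starting lane: an *omission bias*
  (reluctance to switch). A negative value would be a panic/evasion
  bias. Verbal descriptions of this coding in the literature are not
  always self-consistent; we fix the convention by its interpretation,
  and it is exercised by the simulator's default $\omega_s = 0.47$.
* the lane-bias column is a constant $+1$, so $\omega_b > 0$ is a
  preference for driving in the left lane. It is the model's only
  intercept.

### Identifiability and the reported scale

Obstacle and cluster coefficients are defined only up to an additive
constant: adding the same number to every value changes no predicted
probability (`value-of-life` is a *difference* scale). The design
deliberately keeps all 18 obstacle columns — matching the conventional
20-parameter accounting — and lets the tiny ridge penalty pin the fitted
gauge near the minimum-norm solution. Reported scales
(`value_of_life_scale()`) are re-centred so the empty lane sits at 0;
this affects presentation only.

The five cluster columns additionally sum to zero in every row (one
$+1$, one $-1$, or all zeros), an exact collinearity with the same
gauge interpretation. Unpenalized maximum-likelihood *coefficients* are
therefore non-unique, while fitted probabilities are unique; tests
against general-purpose fitters compare probabilities, not raw
coefficients.

## Fitting

`fit_logistic()` maximizes the ridge-penalized Bernoulli log-likelihood

$$\ell(\omega) = \sum_t \big[y_t \log \sigma(x_t^\top\omega) +
(1-y_t)\log(1 - \sigma(x_t^\top\omega))\big] - \tfrac{\lambda}{2}\|\omega\|^2$$

by Newton / iteratively reweighted least squares.

* $\lambda = 10^{-9}$ by default: essentially unpenalized maximum
  likelihood, but the optimum stays finite under perfect separation
  (coefficients cap near $|\omega| \approx 20$–$25$ instead of
  diverging) and the additive gauge above is pinned. All columns,
  including the bias terms, are penalized equally.
* step-halving guards every Newton step, so the penalized objective is
  non-decreasing across iterations.
* convergence is declared when the maximum coefficient change drops
  below `tol` ($10^{-8}$) **or** a full Newton step improves the
  objective by less than $10^{-10}(1+|\ell|)$. The second rule matters
  for near-separated columns (rare pairings observed unanimously), whose
  coefficients creep by $\mathcal{O}(e^{-|\omega|})$ per iteration long
  after every likelihood and every prediction has stabilized.
* log-likelihoods are computed through log-sigmoids
  (`plogis(..., log.p = TRUE)`), so saturated fits do not underflow; the
  reported `log_likelihood` is always the *unpenalized* value at the
  optimum, which is what BIC and the likelihood-ratio test consume.

Classification predicts the left lane when the fitted probability
exceeds 0.5. A probability of exactly 0.5 is resolved by predicting the
trial's starting lane — the deterministic "stay put" reading of an
indifferent model. Some rule is required for the cluster family, whose
within-cluster, bias-free predictions are exactly 0.5; the choice is
stated here because accuracy figures depend on it.

## Model comparison

`bic()` is $k\ln n - 2\ln\hat L$ with $k$ the column count and $n$ the
number of trials in the subset being analysed (per-condition tables use
the per-condition $n$). `cross_validate()` shuffles trials uniformly
(unstratified) under a seed into 10 near-equal folds and pools the
held-out accuracy over trials (micro-average), which is invariant to
fold-size remainders; `compare_models()` reuses one fold assignment for
every spec so all rows are computed on identical splits. A fold whose
training part lacks support for some column is not an error — the ridge
leaves that coefficient near 0.

## Clustering of sparing frequencies

The clustering feature is one number per obstacle: the fraction of its
appearances in which it was spared (sat on the unchosen lane). Choices
enter nowhere else, so the feature is deliberately one-dimensional.

`agglomerate()` runs bottom-up clustering on these values via
`stats::hclust`. The default linkage is **Ward** (`ward.D2`): merging
the pair of clusters with the smallest within-variance increase makes
low cuts of the tree coincide with the minimum-within-spread interval
partition of the sorted values. Greedy pairwise linkages (average,
single, complete) can chain three near-neighbours together before
splitting an obviously wide gap — for frequencies
$\{0.10, 0.12, 0.50, 0.90\}$ average linkage yields the 2-cut
$\{0.10, 0.12, 0.50\}\,|\,\{0.90\}$ rather than the within-spread
optimum $\{0.10, 0.12\}\,|\,\{0.50, 0.90\}$ — which is why Ward is the
default; the `linkage` argument exposes the alternatives. In one
dimension every one of these linkages produces interval clusters, a
property the test suite asserts.

`select_cluster_count()` fits a cluster model for every cut from $n$
clusters down to 1 and returns the BIC minimizer. Frequencies are
unweighted by appearance counts (the balanced design makes counts
near-equal anyway). Merge-height ties (e.g. identical frequencies) are
resolved by `hclust`'s deterministic ordering. An externally imposed
clustering — such as forcing the five semantic categories onto a noisy
condition for comparability — is supplied as a `cluster_map` to
`model_spec()`.

## Error rates, condition contrast, exclusions

**Empty-lane error rate.** In trials with one empty lane, driving into
the occupied lane is read as a non-deliberate response (an error);
chance level is 50%. Under the simulator's lapse model — with
probability $\varepsilon$ the response is a uniform coin flip — the
estimator converges to $\varepsilon/2$ *provided deliberate choices
essentially never hit the sole obstacle*, which holds when the empty
lane sits far below every other obstacle on the value scale. Empty-lane
trials stay in all model fits (they inform the scale's lower end and the
bias terms).

**Nested likelihood-ratio test.** `nested_llr_test()` asks whether the
two timing conditions need separate scales. The nested model fits 19
shared predictors (18 obstacles + starting lane; no lane bias, matching
the shared-scale convention — `lane_bias = TRUE` gives df 20) to the
joint data; the nesting model adds a duplicate set of the same columns
active only in slow-condition rows (38 predictors). The statistic
$2\Delta\ln\hat L$ is referred to $\chi^2_{19}$. Which condition carries
the duplicates is a reparametrization and does not change the statistic
(asserted in tests). Two caveats are documented rather than hidden: the
ridge perturbs $\ln\hat L$ by $\mathcal{O}(\lambda\|\omega\|^2)$,
negligible at $\lambda = 10^{-9}$; and the fitted model is misspecified
under lapses (the lapse mixture is not a logistic), which makes the test
slightly *conservative* — the simulated null rejection rate at
$\alpha = 0.05$ comes out near 0.02–0.06 over 200 study-scale
replicates, within the Monte-Carlo band the acceptance suite checks.

**Outlier subjects.** `exclude_outlier_subjects()` fits a reference
model (obstacle family by default) once per condition on the full pooled
data, computes for each subject the fraction of trials whose observed
choice opposes the predicted lane (pooled over conditions,
trial-weighted), and excludes subjects strictly above 0.5. One
fit-then-exclude pass, no iteration: re-running on the retained set is a
no-op in the clean planted-outlier regime, and iterating would invite
convergence-to-consensus artifacts the single pass avoids.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which everything else is validated.

* **Schedules.** A block is 9 trials in which each of the 18 obstacles
  appears exactly once (a perfect matching). `generate_block_schedule()`
  draws a uniformly random matching. `generate_balanced_design()`
  instead uses the round-robin (circle) 1-factorization of the complete
  graph $K_{18}$: 17 rounds of 9 disjoint pairs whose union is all 153
  pairings. Subjects cycle through the rounds, so any 17 consecutive
  subjects realize every pairing exactly once per condition; lane sides
  and the starting-lane phase flip between 17-subject cycles,
  counterbalancing both. Within-block trial order is shuffled per
  subject. The generator enforces *exactly* once-per-block appearance —
  a strictness the balanced construction makes free.
* **Choices.** Deliberate choices follow the obstacle model (single
  value per obstacle), reflecting the package's core premise that a
  one-dimensional scale suffices; with probability
  $\varepsilon_{\mathrm{condition}}$ a lapse replaces the choice by a
  fair coin. `true_choice_probability()` therefore returns
  $(1-\varepsilon)\sigma(X_o) + \varepsilon/2$. A per-condition
  `value_scale` multiplier emulates the compressed coefficient range
  observed under time pressure (e.g. `fast = 0.5`).
* **Seeding.** All randomness flows from one integer seed; per-subject
  streams are derived at fixed offsets, so enlarging a simulation never
  changes earlier subjects' data. Helper RNG use is wrapped so the
  caller's RNG state is untouched.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| values of life | empty $-4$; objects $0.8$–$1.2$; animals $2.4$–$3.6$; humans $4.4$–$5.6$; groups $6.2$–$6.5$ | category ordering empty < object < animal < human < group with a ~6 log-odds span across the non-empty categories and plausible within-category structure (children above adults, dog highest among animals) |
| empty-lane gap | ~4.8 below the cheapest object | a deliberate driver practically never crashes into an obstacle when an empty lane is available; this makes the empty-lane error estimator a clean $\varepsilon/2$ readout |
| $\omega_s$ | 0.47 | a small omission bias, well below between-category differences |
| $\omega_b$ | 0 | no lane preference; lets the comparison battery demonstrate that the lane-bias ablation wins on BIC |
| $\varepsilon$ | slow 0.056, fast 0.24 | calibrated so the *expected* empty-lane error estimates ($\varepsilon/2$) land at 2.8% and 12.0%, the regime the analysis is designed for |
| subjects | 101 | one 9-trial block per condition gives 909 trials per condition |

The parameter-recovery and calibration experiments use their own
prescribed settings (a ~6 log-odds scale *including* the empty lane and
$\varepsilon = 0$ for recovery; equal conditions for null calibration),
because recovery of the empty lane's coefficient requires it not to be
perfectly separated — with $\varepsilon = 0$ and the default detached
empty lane, the empty column is deterministic and its coefficient runs
to the ridge bound.

### What the simulator does not emulate

No reaction times, lane-switch trajectories, or stimulus presentation;
no between-subject heterogeneity (the analysis pools subjects, and so
does the generator); lapses are condition-constant rather than
fatigue-dependent. Passing validation on this generator shows the
pipeline recovers the structure it assumes — it cannot show that human
data satisfy those assumptions.

## Problem sizes used in validation

Unit and acceptance tests simulate at the study scale of 101 subjects ×
9 trials × 2 conditions (909 trials per condition) for recovery,
selection-consistency (50 seeded replicates), and cluster-count
experiments, and 200 study-scale replicates for the null calibration of
the likelihood-ratio test; the fitter-oracle check compares IRLS against
direct BFGS maximization on twenty 50-trial designs to $10^{-6}$
relative log-likelihood. The full suite runs in well under a minute on
one CPU.

## Known limitations

* BIC's trial count treats trials as independent; with pooled subjects
  this ignores any residual within-subject correlation.
* The chi-square reference for the condition contrast is slightly
  conservative under lapse misspecification (see above).
* Ward linkage on frequencies ignores the differing binomial precision
  of each frequency (appearance counts are near-equal by design, so the
  weighting question is moot for balanced schedules, less so for ragged
  imported data).
* The exclusion rule's reference model is fitted with the
  to-be-excluded subjects included; with many strong outliers the
  reference itself degrades. The single-pass design keeps this
  transparent.
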