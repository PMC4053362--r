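---
title: "Conformal region prediction for multi-label symptom data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal region prediction for multi-label symptom data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mlcp)
```

## The problem

In syndrome differentiation, a clinician assigns a patient a *set* of
syndrome factors (for chronic fatigue, typically drawn from 'spleen
deficiency', 'heart deficiency', 'liver depression' and 'qi deficiency')
based on binary symptoms (presence/absence of items such as insomnia or
night sweating). Statistically this is multi-label classification with
q labels over M binary features, and for clinical use the prediction should
come with a *validity guarantee*: a stated confidence level that the output
label set can be trusted at.

mlcp implements a conformal predictor for this setting. A conformal
predictor outputs, for each candidate label, a p-value measuring how well
the test case with that label conforms to the training data under the
exchangeability assumption, and returns the *region* of labels whose
p-values exceed the significance level $\varepsilon = 1 - \text{confidence}$.
In online single-label prediction the long-run error rate of such regions is
provably at most $\varepsilon$. Region prediction is set-valued by nature,
which is exactly what a multi-label task needs.

## From multi-label cases to single-label examples (PT5)

Conformal prediction wraps a single-label learner, so multi-label training
cases are first expanded by the PT5 problem transformation: a case with
label set of size $l$ is replicated $l$ times, once per label, with its
feature vector copied verbatim (`pt5_transform()`). The expansion keeps an
`origin` index so that a case's own replicates can be recognised later. PT5
is lossless (`pt5_collapse()` inverts it) and the expanded size is
$n' = \sum_i |Y_i|$.

At prediction time, each of the q candidate labels is tested in turn: the
test case is scored *as if* it carried that label, its nonconformity score
is ranked among the training scores, and the p-value is the fraction of
scores at least as large,

$$p_y = \frac{\#\{j : \alpha_j \ge \alpha_{\text{test}}(y)\} + 1}{n' + 1}.$$

We use the un-smoothed p-value (ties counted in full, no randomised
tie-splitting), so all outputs are deterministic given the forest seed.
p-values are therefore multiples of $1/(n'+1)$ and at least $1/(n'+1)$ — a
granularity fact that matters below.

The model is fitted **once** per training set, not refitted with the test
example injected under each candidate label. This is the semi-transductive
reading of the usual algorithm: the forest is grown on the expanded
training data, proximities are exported, and the candidate-label loop only
re-scores. A full-transductive variant (q refits per test case) would
multiply the cost by the alphabet size for a second-order change in the
scores; we did not implement it.

## Nonconformity scores

Three scorers are provided (`rf_nonconformity()`, `knn_nonconformity()`,
`nbc_nonconformity()`); large $\alpha$ always means *less* conforming.

**Random-forest proximity ratio (the headline scorer).** A forest of
`ntree` un-pruned classification trees is grown on bootstrap resamples,
sampling `mtry` features per split (defaults: `ntree = 1000`,
`mtry = floor(sqrt(M))`, so 9 when M = 95). The proximity of two examples
is the fraction of trees in which they land in the same terminal node. The
score of an example evaluated under label $y$ with neighbour count $K$ is

$$\alpha = \frac{\sum_{k=1}^{K} \text{k-th largest proximity to rows labelled} \ne y}
               {\sum_{k=1}^{K} \text{k-th largest proximity to rows labelled} = y}.$$

An example deep inside its class has large same-label proximities and small
different-label proximities, hence small $\alpha$. The score is scale-free
in the proximities.

**KNN distance ratio.** Sum of the K smallest Euclidean distances to
same-label rows over the same sum for different-label rows. Euclidean is
the default on the 0/1 features; a Hamming option exists (on binary data
the two orderings agree, but the K-sums differ).

**Naive-Bayes posterior.** $\alpha = 1 -$ the Bernoulli-naive-Bayes
posterior of the evaluated label, with Laplace smoothing so posteriors stay
strictly inside (0, 1) even for labels unseen in training.

### Replicate exclusion — the one non-obvious rule

Under PT5, a case with labels {A, B} contributes two rows with *identical*
features and different labels. When scoring any training row, its same-origin
replicates are excluded from **both** candidate pools. Without this, the
different-label pool of every multi-label row contains a replicate at
proximity 1 (distance 0), which saturates the numerator and destroys the
intended meaning of the ratio. The source literature is silent on the point;
exclusion is the only choice consistent with the score's stated intuition,
and it also makes a training row's situation match a test instance's (whose
origin case is never in the training set). The naive-Bayes scorer applies
the same rule by removing the origin case's rows from the sufficient
statistics before computing a training row's posterior.

### Edge cases and tie-breaks

* Fewer than K rows in a pool: use all of them.
* Empty same-label pool: $\alpha = +\infty$ (maximally nonconforming);
  empty different-label pool: $\alpha = 0$. `Inf >= Inf` counts as a
  p-value tie.
* Both K-sums zero with non-empty pools (possible only with degenerate
  proximities): $\alpha = 1$, a neutral value; this convention is ours.
* Ties when selecting the K largest proximities / smallest distances are
  broken by ascending row index; score ties in label ranking are broken by
  alphabet order. The label alphabet's order is fixed at dataset creation
  precisely so these tie-breaks are reproducible.

## The ML-KNN baseline

`mlknn_fit()` implements the standard multi-label KNN comparator: per-label
Bernoulli priors $(s + \text{count})/(2s + n)$ and neighbour-count
likelihood tables estimated from leave-one-out K-neighbour statistics,
combined by Bayes' rule at prediction time; labels with posterior above a
threshold (canonically 0.5) form the region. Smoothing defaults to $s = 1$.
Unlike the conformal region, this region *shrinks* as the threshold rises.

## Metrics

`ml_metrics()` computes the six standard multi-label quantities: subset
accuracy (exact set match), hamming loss (symmetric difference / q),
one-error, coverage, ranking loss and average precision. The last four are
functions of the label *ranking*. Ranked by raw scores they are
threshold-independent; because published comparisons often show them varying
with the confidence threshold, every report also carries a "region" view in
which region members are ranked first (by score) and non-members last (in
alphabet order). Cases whose true set is the whole alphabet have no false
labels and are skipped by ranking loss, with a note. Empty regions are legal
(they count as wrong for subset accuracy and contribute $|Y_i|/q$ to hamming
loss).

## The synthetic generator

`simulate_cf_dataset()` emulates the shape of a chronic-fatigue
symptom-survey dataset: q = 4 syndrome factors, M = 95 binary symptoms, and
per-case label sets of size 1..q. Each label owns `signature_size = 6`
dedicated features that fire with probability `signal = 0.9` when the label
is present; every feature also fires at `background = 0.05`. Label sets are
drawn *exactly* from a pairwise log-linear model over the $2^q - 1$
non-empty subsets (q is small, so full enumeration is cheap). Defaults for
prevalence are (0.55, 0.35, 0.40, 0.50) — roughly 1.8 labels per case,
echoing a clinic population in which most patients express one to three
factors.

Because every case must carry at least one label, naive conditioning on
non-emptiness would inflate the marginals. The sampler therefore calibrates
its main-effect logits so that the per-label marginals *given non-emptiness*
equal the requested prevalences (this requires `sum(label_prevalence) > 1`,
since labels per case average at least one; the constructor enforces it).

What the generator deliberately does **not** model: feature dependence
within a label set. Symptoms are conditionally independent given the labels,
which is exactly the regime where a naive-Bayes scorer is at its best.
Passing comparative tests on synthetic data therefore demonstrates the
machinery, not the real-data margins between methods: on clinical data with
strongly dependent symptoms the naive-Bayes and plain-distance scorers
deteriorate in ways this generator cannot show. It also makes no attempt to
match any particular per-symptom frequency table.

With `signal = 1, background = 0` the label set is exactly recoverable from
which signatures fire, giving a noiseless regime in which a competent method
should approach perfect subset accuracy — useful as an end-to-end sanity
bound.

## Evaluation harness and calibration diagnostics

`loocv_evaluate()` runs leave-one-out cross-validation: each fold PT5-expands
the n−1 training cases, fits the scorer, scores the held-out case under
every candidate label, and cuts regions at every threshold in the grid
(default 0.50–0.99 in steps of 0.01; thresholds are open at 1 because a
confidence of exactly 1 forces the full alphabet). Fold i uses forest seed
`seed + i`, so the report is a pure function of (data, config, seed) and
independent of execution order. Fold failures are recorded and surfaced,
never silently dropped.

`online_error_curve()` measures empirical validity. In `unit = "row"` mode
the PT5 rows are shuffled into a genuinely exchangeable single-label stream
and processed online (train on everything before step t, predict step t);
the single-label error rate at significance $\varepsilon$ should stay at or
below $\varepsilon$ up to Monte-Carlo noise. In `unit = "case"` mode whole
cases stream by and two events are tallied: the per-label event, and the
multi-label event that the true *set* is not contained in the region.
Whether the single-label guarantee transfers to the multi-label event under
PT5 is not established theoretically; the package measures it and makes no
claim. `autoplot()` on the result draws accuracy against confidence with
the exact-calibration diagonal.

```{r calibration, eval = FALSE}
d <- simulate_cf_dataset(150, seed = 1)
cal <- online_error_curve(d, method = "rf", unit = "row",
                          ntree = 100, seed = 1)
autoplot(cal)
```

## Numerical and design notes

* **p-value granularity.** At confidence 0.99 a label can only be excluded
  if $1/(n'+1) \le 0.01$, i.e. at least 99 expanded training rows. Small
  studies (say 60 cases at ~1.8 labels each) sit near that boundary, and
  folds that dip under it keep the full alphabet in every region. This is
  intrinsic to conformal prediction, not an artefact: at n′ < 99 the method
  honestly refuses to rule anything out at 99% confidence.
* **Problem sizes in the test-suite.** The shipped checks run the online
  validity study on eight independent streams of 150 cases (about 2,000
  scored steps, forest size 100), the noiseless-recovery study at n = 60
  with 200 trees, and the method-comparison sweep at n = 200 with 200
  trees. These sizes give stable Monte-Carlo estimates while keeping a full
  run in the minutes range; the forest default of 1000 trees is intended
  for real analyses.
* **Determinism.** All randomness flows from explicit integer seeds: the
  generator uses one, each forest fit uses one, online steps use
  `seed + step`, LOOCV folds use `seed + fold`. `ranger` is pinned to one
  thread inside the package so thread scheduling cannot perturb results.
* **Degenerate inputs.** One-row training sets, or constant features with
  constant labels, are fit errors; `mtry > M` and out-of-range thresholds
  are parameter errors; empty label sets are rejected at read time unless
  `drop_empty = TRUE` (dropped with a warning).

## Known limitations

* The multi-label calibration event inherits no proof from the single-label
  theory; treat its curves as empirical diagnostics.
* LOOCV with a transductive conformal predictor is batch, not online, so
  even the single-label guarantee is only approximate there; empirically
  the curves track the diagonal well.
* The generator's conditional-independence structure flattens the
  differences between scorers relative to dependent clinical data (see
  above).
* Only PT5 is implemented; binary-relevance-style transformations are out
  of scope.
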