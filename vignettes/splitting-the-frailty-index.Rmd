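---
title: "Splitting the modified frailty index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting the modified frailty index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtynet)
```

## The scientific question

The accumulating-deficits frailty index treats every health deficit as
interchangeable: the 13-item modified frailty index (mFI) is simply the
number of deficits present divided by 13. But the 13 indicators are not
clinically equivalent. Seven of them — ascites, dialysis within 2 weeks,
dependent functional status, history of COPD, history of CHF within 1 month,
renal failure within 24 hours, and ventilator dependence — are strongly tied
to 30-day postoperative mortality and mark depleted physiologic reserve;
the other six (current smoker, diabetes, disseminated cancer, dyspnea,
hypertension, chronic steroid use) are common chronic conditions with a
weaker acute signal.

This package implements the question operationally: does a classifier that
receives the *high-impact* and *low-impact* deficit fractions as two
separate inputs predict the post-surgery discharge destination (a 9-category
outcome from *home* through *death*) better than the same classifier
receiving the single pooled mFI? Three related quantities follow:

* the **split mFI** pair, `(high deficits)/7` and `(low deficits)/6`;
* the single-group **leave-one-out** models (high-only, low-only), which
  rank the two groups' contributions;
* the **weighted single index**
  $\widehat{mFI} = (\beta \sum \text{high} + \sum \text{low})/13$,
  which folds the asymmetry back into one number a clinician can use. With
  $\beta > 1$ it can exceed 1; its maximum is $(7\beta + 6)/13$ (1.359 at
  $\beta = 1.667$). $\beta$ is chosen from the grid
  $\{1.5, 1.667, 1.75, 2.0\}$ by composite-set prediction accuracy, and the
  composite winner is reused for every specialty; a per-specialty $\beta$
  is possible through `model_variant()` but is not the default protocol.

The identity $mFI = (7\,mFI_{high} + 6\,mFI_{low})/13$ ties the three
representations together and is enforced exhaustively in the tests over all
$2^{13}$ indicator vectors.

## The classifier and its protocol

`mfi_net()` is a deliberately classical multilayer perceptron: 1–3 fully
connected sigmoid hidden layers, sigmoid output units, one-hot targets,
squared-error loss, full-batch backpropagation with momentum. Modern
choices (softmax/cross-entropy, adaptive optimizers) would likely train
faster, but the protocol being studied monitors the training-set RMSE, and
the stopping rules are defined in those terms, so the implementation stays
with the classical formulation:

* train at least `min_epochs`, checking RMSE every `epoch_step` epochs up
  to `max_epochs`;
* stop when training RMSE < 0.05, or when it changes by less than `1e-4`
  (configurable) across the plateau window;
* on a non-finite loss, halve the learning rate once and restart from the
  same initial weights; fail with a diagnostic if that also diverges.

Weights initialize uniformly in $[-0.5, 0.5]$ from the model seed, so a fit
is bit-reproducible from its configuration. The activation function,
learning rate (default 0.3), momentum (0.9) and initialization range are
implementation policy, not protocol constants: the protocol fixes only the
epoch schedule, the RMSE target and the architecture-search rule.

The architecture search (`search_architecture()`) grows depth-first: for
each depth, the newest layer sweeps node counts from $\lceil n/3 \rceil$ to
$4n$, where $n$ is the size of the preceding layer, stopping a sweep after
two consecutive candidates that are strictly worse than the best seen, and
keeping earlier layers frozen at their best size. Accuracy ties go to the
smaller network. The sweep bounds follow the standard hidden-layer sizing
heuristic of one-third to four times the preceding layer; candidates are
scored on test-set accuracy, which reproduces the stated (optimistic)
selection protocol — a held-out-validation variant can be had by passing a
different `eval_fn`.

Two scale profiles exist. The published-scale profile
(`net_control()`: epochs 50000–150000 in steps of 10000) preserves the
protocol constants. The desk profile (`desk_control()`: 1500–4000 by 500,
or 2000–6000 for the cohort experiments below) is what this package runs
routinely; on the balanced training sets involved (a few hundred rows, 5–6
features) the loss trajectory flattens well inside that budget, and the
checkpointed RMSE log lets one verify this on any fit via `plot()`.

## The synthetic cohort generator

Real registry data of this kind (NSQIP participant-use files) are
membership-restricted, so the package ships a generator,
`generate_cohort()`, that emulates the *structure* the analysis needs
rather than the full ~300-column registry schema:

* 13 independent Bernoulli indicators whose default prevalences give a
  median mFI of 1/13 ≈ 0.08, median high-impact-only index 0, and median
  low-impact-only index 1/6 ≈ 0.17 — matching the population the analysis
  targets;
* age (truncated normal, median 63), wRVU (lognormal, median 20.7), ASA
  class (mode 3), sex (44% male);
* a latent severity score
  $s = w_h n_{high} + w_l n_{low} + w_{age}\,age' + w_{asa}\,asa' +
  w_{wrvu}\,wrvu' + \varepsilon$, binned by 8 fixed thresholds into the 9
  ordered destinations. Ties on a threshold go to the higher-intensity
  category.

The latent-ordinal form was chosen over a per-class multinomial because the
destination scale is ordered by care intensity and because it reduces
"high-impact indicators matter more" to a single contrast, $w_h$ vs $w_l$.
The default weights are $w_h = 1.5$, $w_l = 0.5$ per deficit with noise SD
0.75: a 3:1 high/low contrast in which the indicators account for roughly a
third of the latent variance. That fraction is the one genuinely free
choice in the generator; it was fixed after verifying with a multinomial-
logit reference that a substantially weaker indicator signal makes the
destination essentially noise-driven, which would defeat the generator's
purpose as a testbed for the split-vs-single comparison. The default
thresholds were calibrated once by simulation (n = 200 000) so that the
destination marginals match the home-heavy population distribution
(≈91% home, death ≈0.3%) and then frozen; `calibrate_thresholds()` exposes
the calibration for other marginal targets.

What the generator does **not** emulate: comorbidity correlations between
indicators, specialty-specific case mix and indicator profiles,
greater-than-additive interaction effects, and informative missingness
(missingness is injected completely at random over the independent
variables only, since the pipeline's only exclusion rule is
record-completeness). Consequently, passing tests on synthetic cohorts show
that the pipeline recovers a planted additive asymmetry; they do not show
that real surgical cohorts carry such a signal — that is what the restricted
registry analysis reported, and its printed tables are replayed separately.

## Preparation pipeline

`filter_records()` applies the one inclusion rule (complete independent
variables and outcome), builds the nine specialty datasets plus the pooled
composite (the composite is split and balanced independently, not as a
union of per-specialty splits), and drops destinations with fewer than two
records — each retained destination must be able to seed both the training
and the test set. A destination with exactly two records keeps them, one
per set, accepting the instability that implies.

`stratified_split()` halves each destination at random; odd counts
alternate the extra record between train and test across destinations, so
the per-destination counts never differ by more than one.
`partial_balance()` caps each destination at the median per-destination
count (ceiling of the median when the count of destinations is even —
the even-count median is otherwise undefined in the protocol), subsampling
uniformly without replacement. Both the training and the test set are
balanced by default, following the stated text order of the protocol;
`balance_test = FALSE` switches to balancing the training set only.

`encode_features()` min-max scales age, wRVU and ASA class to $[0,1]$ with
*training-set* bounds reused verbatim on the test set, encodes sex as 0/1,
and scales $\widehat{mFI}$ by its theoretical maximum so every input is in
$[0,1]$. ASA class enters as one scaled ordinal input, not one-hot. A
constant training covariate maps to 0 rather than dividing by zero.

## Evaluation

Accuracy is exact-match over the test set. The split-vs-single comparison
is summarized as a percent improvement,
$100\,(\text{acc}_{split}/\text{acc}_{single} - 1)$, and tested with a
one-tailed two-proportion Z-test using the **unpooled** (Wald) standard
error. Unpooled is a deliberate choice: on the reconstructed cardiac
counts (16/52 vs 14/52) it reproduces the published p-value 0.3324 exactly,
where the pooled variant gives 0.3326. No multiple-testing correction is
applied, matching the protocol being reproduced. Destination coverage (the
fraction of present destinations the model ever predicts correctly) and
mortality recall (death-class recall) complete the report. Report-time
rounding is two decimals for accuracies (as percent), one for improvements,
four for p-values; everything upstream stays at full precision.

`replay_worked_examples()` re-derives the published arithmetic with no
input data: all ten improvement percentages from the printed accuracy
pairs, the composite Z-test p = 0.0008 on (31.99%, 36.80%) at n = 1935 per
arm, the cardiac Z-test p = 0.3324, and the composite gain of 125/1935 =
6.46%. The cardiac test-set size (52) is reconstructed from the printed
accuracy pair, whose difference of 3.85 points corresponds to exactly two
misclassified patients.

## Problem sizes and reproducibility

The package's own experiments run at a desk scale chosen to keep a full
pipeline cycle in minutes on a single core: cohorts of 20 000 records,
five independent generator seeds per condition, a fixed 5-node single
hidden layer (the architecture search is exercised separately), and a
2000–12000-epoch desk profile. The layer size keeps the parameter count
below the balanced training-set size, and the epoch ceiling is set high
enough that fits reach their RMSE plateau: under-trained networks
systematically penalize the model with the extra (redundant) input, which
distorts the null comparison. At these sizes the home-heavy marginals make
the balanced composite *training* sets small (≈150–200 rows, the
median-cap consequence of rare destinations such as multi-level facility
at 0.02%), which is why conclusions are drawn from means over seeds rather
than single runs; for the same reason the synthetic contrast experiments
score models on the full unbalanced test half (≈8 000 rows) rather than a
median-capped one — the balanced-test option remains the default in
`run_experiment()`, faithful to the protocol being reproduced, but a
~170-row test set adds measurement noise that five seeds cannot average
away. Every random draw — generation, splitting, balancing, weight
initialization — takes an explicit seed, and `run_experiment()` is
bit-reproducible from its configuration.

## Known limitations

* The generator's additive latent model cannot express the interaction
  structure real comorbidity data may carry; a null result on real data
  would not contradict a planted-signal recovery here.
* Balanced test sets change the meaning of "accuracy" relative to the raw
  population mix; the package follows the protocol it reproduces rather
  than advocating it.
* Architecture selection on test accuracy is optimistic by construction;
  use a third split via `eval_fn` when unbiased generalization estimates
  matter.
* The Z-test treats the two compared proportions as independent although
  they are computed on the same test cases; a paired test (McNemar) would
  be more powerful but is intentionally out of scope.
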