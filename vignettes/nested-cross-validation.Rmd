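---
title: "Nested cross-validation with automated hyperparameter optimization on grouped image data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested cross-validation with automated hyperparameter optimization on grouped image data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nachos)
```

## The estimation problem

A classifier's test accuracy from one train/test split is a single draw
from a distribution whose spread nobody measured. On grouped data — images
nested in patients, OCT volumes nested in kidneys, images pooled from
several institutions — a careless split also leaks near-identical images
across the train/test boundary and inflates the estimate. This package
addresses both problems at once:

* **variance**: every fold rotates through the test role, so the report
  carries k test accuracies, their mean $\bar t$, sample SD $\sigma_t$,
  standard error $SE = \sigma_t/\sqrt{k}$ and a Student-$t$ interval with
  $k-1$ degrees of freedom. Averaging k folds shrinks the SE of the
  estimate by $\sqrt k$ relative to a single fold — with $k=4$ the SE is
  half the fold SD, with $k=10$ roughly a third.
* **leakage**: folds are formed at a declared *group level*; every record
  sharing a group identifier at that level is placed in the same fold, and
  the engine additionally asserts per CT iteration that the held-out fold
  never intersects any training or validation set.

## The two workflows

**Benchmarking (`runNachos`).** Three nested loops. The cross-testing (CT)
loop holds out fold $F_i$. The AHPO loop iterates over $n$ hyperparameter
configurations $h_j$ drawn once per study by random search. The inner CV
loop reserves $F_m$ ($m \ne i$) for validation and trains on the remaining
$k-2$ folds, recording the validation accuracy $\upsilon_{mj}$. The
cross-validation accuracy $\bar\upsilon_j$ is the unrounded mean of the
$k-1$ values $\upsilon_{mj}$; $j^\*$ is its argmax. The winner is retrained
on all folds but $F_i$ and scored on $F_i$ as $t_i$. This costs $k(k-1)n$
validation tasks plus $k$ retrain tasks.

**Deployment (`runDachos`).** The CT loop is dropped: each configuration is
scored by plain $k$-fold CV over the full dataset ($kn$ tasks, each
training on $k-1$ folds — one more than the nested engine uses, which is
why deployment validation accuracies tend to sit slightly higher). The
single selected configuration is retrained on every record. The production
model's test performance is *unknown*: no held-out data remains, and the
report states this rather than fabricating a score.

Throughout, the metric is classification accuracy
$(TP+TN)/(TP+TN+FP+FN)$ in the two-class case, i.e. the confusion-matrix
trace over its total; the metric enters only through the confusion matrix,
so other trace-style metrics could be substituted at the evaluation layer.

### Numerical rules that matter

* Selection always compares **unrounded** means; two-decimal values appear
  only in displays. Bundled worked examples include a case where two
  configurations print identically at 0.90 but differ at 0.898 vs 0.896 —
  rounding before selection would pick the wrong model.
* Ties break to the **lowest configuration index** — deterministic and
  easy to reproduce by hand.
* SDs use the $n-1$ denominator everywhere (fold aggregates, confusion
  cells, partition comparisons).
* The confidence interval uses Student's $t$ with $k-1$ degrees of
  freedom.

## Hyperparameter search

The search space is a named list of finite candidate sets; the default
six-dimension space covers batch size {16, 32, 64, 128}, learning rate
{0.01, 0.001, 0.0001}, learning-rate decay {0.01, 0.001, 0.0001}, momentum
{0.5, 0.9, 0.99}, Nesterov {on, off} and an architecture label. Random
search draws each dimension independently and uniformly; $n$ defaults to 9
but is fully configurable. Duplicates are allowed and evaluated
independently — deduplication would distort random-search semantics, and
the marginal-uniformity property test would catch a biased sampler. The
configuration list is drawn **once per study** and shared between the
benchmarking and deployment runs (and across all test folds), which is
what makes their selections comparable.

## Backends

The engine talks to training code only through `trainModel` /
`evaluateModel`, so backends are pluggable:

* **Reference backend** — a multinomial softmax classifier on flattened,
  per-feature-centred pixels, optionally with one tanh hidden layer, trained
  by mini-batch SGD. It honours every hyperparameter dimension: time-based
  decay $lr_t = lr/(1 + decay \cdot t)$ per update step, classical or
  Nesterov momentum, and an architecture label that selects among the
  small topologies (canonical CNN names map onto them so externally
  tabulated configuration lists run unchanged). Epochs default to 10.
  Initialisation is seeded per task and each epoch's mini-batch shuffle is
  seeded by `seed + epoch`, making training bit-reproducible and — because
  the optimizer state (parameters, momentum velocities, update counter) is
  checkpointed — exactly resumable mid-task. Large CNNs are deliberately
  out of scope: every engine property they would exercise is exercised by
  this backend in seconds.
* **Replay backend** — training is a no-op; evaluation looks up the
  accuracy for (test fold, configuration, validation fold) in a table.
  Synthetic confusion matrices use a **fixed denominator of 100**, so
  tabulated two-decimal accuracies are represented exactly; this is the
  one documented exception to the rule that confusion totals equal the
  number of evaluated records, and it is what allows published aggregates
  to be reproduced digit for digit through the full engine.
* **Mock backend** — accuracy is an arbitrary deterministic function of
  (i, j, m), and every training call is traced with the exact record ids
  it received. Tests use it to compare the engine against a straight-line
  brute-force re-implementation and to audit leakage.

Per-task seeds are a fixed integer mix of the global seed and (i, j, m),
so results are independent of execution order and worker assignment.

## Scheduling and fault tolerance

Tasks run through a manager–worker pool: an idle worker slot receives the
next unassigned task (dynamic load balancing), implemented over local
forked processes with a documented request/assign/complete contract so a
cluster transport could be swapped in. Results are keyed by task identity
and are invariant to worker count and completion order.

The checkpoint store keeps, per task, a small atomic JSON metadata record
(identity, attempts, last completed epoch, status) and **at most one**
model checkpoint, replaced each epoch and deleted on completion — disk
usage scales with in-flight tasks, never with epochs. On relaunch,
completed tasks are skipped (stored results reused), partially trained
tasks resume from their checkpointed epoch, and the rest run fresh. For
deterministic backends the resumed run's results are identical to an
uninterrupted run; the tests verify this at both the task level and the
epoch level, with execution counters confirming exactly-once completion.
Failure detection is at relaunch, not mid-job: a crashed worker's task is
recovered when the run is re-dispatched.

## Partition-scheme statistics

`comparePartitionings()` takes per-fold test accuracies from two or more
partitioning schemes and reports a one-way fixed-effects ANOVA, variance
components by the balanced method of moments (treatment component
$(MS_{between}-MS_{within})/n$, truncated at zero and flagged when
truncated; residual $= MS_{within}$), Tukey HSD intervals, and all
pairwise pooled-SD Cohen's $d$. Degenerate inputs are defined rather than
NaN: constant data gives $F = 0$ and $d = 0$; `cohensD()` alone refuses a
zero pooled SD. `sampleWithMoments()` reconstructs a sample with an exact
mean and SD so published group summaries can be fed through the same code
path as raw fold accuracies.

The method-of-moments estimator and the pooled-SD form of $d$ were chosen
because they are the standard balanced-design estimators and they
reproduce the worked-example values (e.g. $d = 1.40$ and $1.35$ for the
image- and patient- vs dataset-level contrasts) from the printed group
summaries.

## The synthetic generator

`generateDataset()` emulates grouped imaging structures. The hierarchy has
class-mixed levels (a source dataset or a kidney contains every class) and
class-pure levels below the class split (an OCT volume images one tissue).
Each image is

> class template + one low-frequency field per ancestor group + pixel noise,

with the template amplitude (`classSignal`) and the per-level field
amplitudes (`groupEffect`) expressed in pixel-noise SD units. Class
templates are fixed smooth geometric patterns; group fields are seeded
sinusoidal surfaces with random phase and offset. Linear backends learn
the template easily but inherit the fields of the groups they trained on,
so holding out whole groups at a coarse level degrades accuracy — exactly
the regime grouped partitioning is designed to expose. Conversely, setting
tiny pixel noise under a dominant finest-group field produces
near-duplicate images whose image-level splits inflate accuracy toward
1.0.

Two full-size structure presets mirror the worked-example studies: 4
datasets × 2 classes × 620 images (4,960 records) and 10 kidneys × 3
tissues × 30 volumes × 20 images (18,000 records, 90 volumes per kidney).
They are generated manifest-only by default; payloads at that scale are
unnecessary for structural checks. What the generator does **not** emulate:
realistic radiograph or OCT texture, nonlinear class boundaries, label
noise, class imbalance, or correlated noise — passing tests demonstrate
engine and estimator correctness under controlled group structure, not
clinical-grade model performance.

## Problem sizes used in the test suite

Tests run the complete engines at desk scale as a deliberate design
choice: 16 × 16 to 12 × 12 pixel images, 4 groups × 2 classes × 6–15
images, $n$ = 1–3 configurations, 4–8 epochs — a full nested run is then a
sub-second affair and the qualitative properties (group-effect ordering
over 5 seeds, null-calibration of the ANOVA over 1,000 replicates,
crash/resume equivalence) remain cheap to verify. The replay fixtures
exercise the engines at the worked examples' true shapes (k = 4 and
k = 10, n = 9).

## Known limitations

* The scheduler's transport is process-local; distributed transports must
  reimplement the documented contract.
* Balancing at fold assignment is by group count, not image count; with
  very unequal group sizes, folds can differ in image count. Group
  integrity was judged to dominate, and the audit reports sizes.
* No stratification by class: the intended datasets balance classes by
  construction, and image-level stratified splitting would change the
  estimand at grouped levels.
* Fold-level accuracies are treated as independent in the ANOVA and
  effect sizes, as is conventional, although cross-validated accuracies
  share training data.
* `comparePartitionings()` accepts unbalanced schemes but flags them; the
  variance-component estimator is exact only for balanced designs.
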