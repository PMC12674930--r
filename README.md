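# nachos

Nested cross-validation with automated hyperparameter optimization,
grouped data partitioning, variance-quantified performance reporting, and
fault-tolerant manager–worker scheduling — for benchmarking and deploying
image classifiers on grouped (hierarchical) medical-imaging data.

## The problem

Benchmarking a classifier on medical images with a single train/test split
reports one number with unknown variance, and — when images are grouped by
patient, imaging volume, or source institution — often an optimistic one,
because near-identical images from the same group leak across the split.
This package implements two complementary workflows:

* **NACHOS** (nested and automated cross-validation and hyperparameter
  optimization): the dataset is split into *k* grouped folds
  F<sub>0</sub>…F<sub>k−1</sub>. An outer cross-testing loop holds out each
  fold F<sub>i</sub> as a test set. Inside it, an AHPO loop scores *n*
  random-search hyperparameter configurations h<sub>j</sub> by inner
  cross-validation: for each validation fold F<sub>m</sub> (m ≠ i) the model
  trains on the remaining k−2 folds and records the validation accuracy
  υ<sub>mj</sub>. The configuration with the highest mean validation
  accuracy ῡ<sub>j</sub> is retrained on all folds except F<sub>i</sub> and
  scored on F<sub>i</sub>, giving t<sub>i</sub>. The k test accuracies are
  aggregated as

  t̄ = (1/k) Σ t<sub>i</sub>,  σ<sub>t</sub> = sample SD of the t<sub>i</sub>,
  SE = σ<sub>t</sub>/√k,  CI = t̄ ± t<sub>1−α/2,k−1</sub>·SE.

* **DACHOS** (deployment): the same AHPO by plain k-fold CV over the full
  dataset (kn tasks, each training on k−1 folds), then the selected
  configuration is retrained on *everything* to produce the production
  model. Its test performance is unknown by construction and the report
  says so.

Fold assignment is grouped at a declared hierarchy level (image, patient,
volume, dataset, kidney…): all records sharing a group identifier at that
level land in the same fold, and `auditAssignment()` verifies it. Training
tasks — k(k−1)n of them for NACHOS, kn for DACHOS — run through a
manager–worker scheduler with dynamic load balancing, per-task metadata and
model checkpoints, and crash resume (`resumeRun()`).

## Worked example

The package bundles the accuracy tables of two worked-example studies (a
four-fold chest X-ray cardiomegaly benchmark and a ten-fold kidney OCT
tissue benchmark) as replay fixtures; the replay backend feeds them through
the *full* engine — enumeration, selection, tie-breaking, aggregation —
without any model training:

```r
library(nachos)
report <- replayStudy("xray_ncv")
report
#> BenchmarkReport: k = 4 folds, n = 9 configurations (level 'group')
#>   per-fold selections:
#>     F0: h2 (cv 0.72) -> test 0.79
#>     F1: h1 (cv 0.79) -> test 0.71
#>     F2: h8 (cv 0.77) -> test 0.69
#>     F3: h5 (cv 0.70) -> test 0.82
#>   test accuracy 0.75 +/- 0.03 (SE); SD 0.06; 95% CI [0.65, 0.85]
```

Each line reads: with F0 held out for testing, configuration h2 won the
inner cross-validation (mean validation accuracy 0.72 over the three
validation folds) and, retrained on F1–F3, scored 0.79 on F0. Averaging the
four per-fold test accuracies gives 0.75 with standard error 0.03 — the
variance-quantified estimate a single train/test split cannot provide.

A fully synthetic run with real (desk-scale) training:

```r
m  <- generateDataset(deskSpec(seed = 1))            # 4 datasets x 2 classes x 15 images
fa <- assignFolds(m, k = 4, level = "dataset", seed = 1)
cfg <- sampleConfigs(defaultSearchSpace(), n = 3, seed = 1)
runNachos(m, fa, cfg, referenceBackend(), seed = 1, epochs = 4)
```

Partition-scheme comparison (one-way ANOVA, variance components, Tukey
HSD, Cohen's d) from per-fold accuracies:

```r
cohensD(0.811, 0.008, 4, 0.750, 0.061, 4)
#> [1] 1.402206
```

A thin command-line wrapper (`exec/nachos`) exposes the same operations as
subcommands: `synth`, `partition`, `audit`, `nachos`, `dachos`, `resume`,
`compare`, `fixtures`.

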