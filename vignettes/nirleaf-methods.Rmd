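---
title: "Methods: maturity discrimination from NIR leaf spectra"
author: "nirleaf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maturity discrimination from NIR leaf spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirleaf)
```

## The problem and the data model

Fresh crop leaves are harvested by maturity grade. `nirleaf` models the
grading task as five-class discrimination over NIR reflectance spectra:
each leaf is scanned at several spots (six by default), the spot spectra
are averaged per wavelength into one working spectrum per leaf, and a
classifier maps that spectrum to one of the ordinal levels `unripe`,
`mature`, `ripe`, `mellow`, `overmature`. Leaves from different stalk
positions (`upper`, `middle`, `lower`) have systematically different
spectra, so each position is modelled independently.

Spectra live on a regular grid described by `(start_nm, step_nm,
n_points)` under a **half-open convention** `[start, end)`: the
acquisition range 900–2500 nm at 3.125 nm spacing yields exactly
`(2500 - 900) / 3.125 = 512` points, with 2500 nm itself not a grid
point. This is the only convention under which that division is exact,
and it makes grid arithmetic a pure integer check. Spectra are dense;
missing values are rejected at construction.

The interchange format is a wide CSV — `sample_id, position, maturity`
followed by one column per wavelength, one row per spot scan. A long
layout was deliberately rejected: with the grid in the header, parsing
is unambiguous and every structural violation (ragged rows, unequal
header spacing, unknown label tokens) can be reported with a row/column
index.

## Pretreatment operators

NIR reflectance of tissue is corrupted by scatter that acts, to first
order, affinely per spectrum: a multiplicative gain and an additive
offset, plus slow baseline drift. The package implements the classical
inverses, all row-wise and stateless except where noted:

* **Savitzky–Golay filtering** (`sg_filter`): local least-squares
  polynomial fit per window. Coefficients come from `signal::sgolay`;
  the filter is exact on polynomials up to the fit order, which the test
  suite exploits as an analytic oracle (the second derivative of
  $\lambda^2$ is the constant 2). Derivatives are divided by
  `step_nm^deriv` so they carry units of reflectance/nm. `valid` mode
  shortens each row by `window - 1`; `same` mode fits shifted windows at
  the edges, matching `signal::sgolayfilt`.
* **SNV** (`snv`): each row centred by its mean and scaled by its own
  standard deviation. The **sample (n−1)** denominator is the default —
  the same convention the reporting tables use for "±" — with the
  population denominator available.
* **MSC** (`msc_fit` / `msc_apply`): each row regressed on a reference
  spectrum by ordinary least squares, $x \approx a + b\,\mathrm{ref}$,
  then corrected as $(x - a)/b$. The reference is the training-set mean
  spectrum (the standard choice), fitted once and **frozen** for test
  rows; slopes below $10^{-12}$ in magnitude are rejected as
  non-correctable.
* **Min–max normalisation** to $[0, 1]$ per spectrum is the default
  reading of "normalization"; per-spectrum unit-vector scaling is
  available under its own name (`unit_norm`).

Pipelines are ordered step lists with flat key–value serialisation.
The **default pipeline** is a first-derivative SG filter with window 59,
polynomial order 2, valid mode, followed by min–max normalisation. The
window is a reconstruction, not a measured instrument setting: it is the
unique valid-mode window for which the 512-point acquisition grid yields
the 454-point input width the CNN architecture declares
(512 − (59 − 1) = 454). Both window and order are plain arguments.
Normalisation follows the derivative, matching the phrase order in which
the pretreatments are conventionally listed; replicate spot spectra are
averaged on raw reflectance *before* preprocessing, and because all
operators here are linear or row-wise this ordering only matters for the
nonlinear normalisation step (it, too, is configurable by composing
pipelines differently).

PCA scores (`pca_scores`) centre but do not scale columns — all
wavelengths share one physical unit — and are intended for cluster
visualisation, not modelling.

## Kennard–Stone partitioning

Calibration/test splits use the Kennard–Stone max–min procedure: the
first two picks are a globally farthest pair, each later pick maximises
its minimum Euclidean distance to the already-selected set. Two policies
make it bit-reproducible across platforms: distance **ties break to the
lowest row index**, and the train size is `round_half_up(fraction · n)`
— half-up being the only rounding that reproduces all three published
split sizes (790, 760, 799 at 70% of 1128, 1085, 1141), including the
exact half 759.5. The `round_half_up` implementation adds a $10^{-9}$
guard before flooring because `0.7 * 1085` is fractionally *below* 759.5
in binary floating point.

Distances are computed on the preprocessed spectra by default (`split.on
= preprocessed` in run configs): the split should be representative in
the space the model actually sees. KS runs globally per dataset, not per
class; with strongly clustered data this can leave minority test cells
small, which is visible in the worked example's confusion matrix and is
a property of the method, not a bug.

## The five classifiers

All five expose one contract — `fit(x, y, ...)` returning an object with
a `predict` method — and are interchangeable in the harness
(`train_classifier`).

**1D CNN** (`cnn`). Two convolution blocks (conv → batch norm → ReLU →
max pool), flatten, a 100-unit ReLU dense layer, softmax output. The
published parameter table for this architecture family prints kernel
size 13 × 1, but its own output-shape column (450, 225, 221, flatten
14144 = 221 × 64) is arithmetically consistent only with kernel 5 and a
pool stride of 2; the package defaults to the printed shapes (kernel 5)
and exposes kernel 13 as an equal-status configuration — both are
exercised by the shape tests, and which configuration produced any
published accuracy cannot be determined from the table alone. The same
table prints pool stride 1 where only stride 2 yields 450 → 225; the
shapes win again. Training is mini-batch Adam (defaults: batch 64, 300
epochs, learning rate $10^{-3}$, categorical cross-entropy — the
optimiser and loss are unstated upstream, so the community defaults for
this architecture family were chosen and are configurable). Weights are
Xavier-normal initialised; batch normalisation uses per-batch statistics
in training and exponential moving statistics (momentum 0.9) at
prediction. Pooling carries the optional multiplicative/additive biases
of the general pooling formulation, defaulting to the identity (1, 0)
since no values are ever assigned to them. A global-max-pool layer is
implemented but off by default: it appears in prose descriptions of the
architecture but not in its parameter table. The implementation is plain
R over BLAS matrix products (im2col patch matrices), verified against
central-difference numerical gradients; a fixed seed covers
initialisation and batch shuffling, giving bit-identical models.

**ELM** (`elm`). Random frozen input weights and biases, uniform on
(−1, 1), drawn **neuron by neuron** so that for a fixed seed the first
$h$ neurons are identical for every capacity $\geq h$; hidden features
are therefore nested and the least-squares training error is provably
non-increasing in `n_hidden`, which the tests assert exactly. Output
weights are the Moore–Penrose solution `MASS::ginv(H) %*% Y` against
one-hot targets; with `n_hidden >= n_train` on distinct rows the
pseudo-inverse interpolates.

**KNN** (`knn_classifier`). Lazy inverse-distance-weighted voting:
class score $\sum_i 1/(d_i + \varepsilon)$ over the $k$ nearest
neighbours, $\varepsilon = 10^{-12}$ so an exact-match neighbour
dominates. Euclidean or Mahalanobis distances (the latter requiring an
invertible training covariance).

**BPNN** (`bpnn`). One sigmoid hidden layer, sigmoid outputs, squared
error against one-hot targets, full-batch gradient descent — the classic
backpropagation network, kept deliberately plain (its historical claim
to fame, solving XOR, is a test case). The default learning rate is
$10^{-4}$ per the reference configuration; on the 454-dimensional
synthetic benchmark that rate undertrains within any reasonable epoch
budget, so the benchmark tests fit with rate 0.5 — a fitting-parameter
choice, not a change to the contract. `epochs = 0` predicts from the
seeded initial weights, pinning the determinism contract.

**SVM** (`svm_rbf`). One-vs-one RBF C-classification delegated to
libsvm (`e1071`), the same solver family the reference workflow used;
the module's contract is the decision rule, not the optimiser. Penalty
and kernel parameters are accepted as-is, typically powers of two from
the tuning grid ($2^{-10} \ldots 2^{10}$; printed values such as 0.0313
are $2^{-5}$).

## Evaluation and protocols

The accuracy statistic is NER, the diagonal share of the $G \times G$
confusion matrix in percent. Internally full precision is kept;
**reports round half-up to two decimals**, and repeated stochastic runs
aggregate as mean ± sample (n−1) standard deviation. Both conventions
were fixed by recomputing published aggregates: the upper-leaf per-run
testing row aggregates to 96.18 ± 0.26 only under sample sd (population
sd would print 0.25) and half-up rounding. "Increased by" comparisons
are relative percent change, $100(a - b)/b$, confirmed by the published
pairs (96.18 vs 84.02 → 14.47%). Deterministic models (KNN, SVM) are
treated as single-run and reported without a ±.

Three protocols mirror the reference experimental design, with sizes as
arguments:

* `compare_preprocessing`: per repeat, draw `n_subset` (default 450)
  training samples, split 2:1, fit each candidate pipeline on the
  calibration rows only, train each model, tabulate mean internal-test
  NER per (pretreatment, model) cell.
* `tune_cnn`: one-factor-at-a-time sweep in the order kernel size →
  batch size → epochs (grids default to 5/9/13/17/21, 16–256,
  50–1000), each sweep fixing the previous winner; per repeat `n_val`
  (default 150) training samples serve as validation. Returns the
  calibration/validation curves and the selected configuration.
* `tune_baselines`: KNN's $k$ by 10-fold cross-validation; SVM cost and
  gamma by power-of-two grid search under the same CV; ELM and BPNN
  hidden widths by a seeded held-out validation split (no selection rule
  is stated upstream for the latter two; validation selection over a
  grid is the design choice here, with the BPNN grid defaulting to
  1–30).

## The synthetic generator

Field spectra for this task are not publicly deposited, so the package
ships a generator whose output has exactly the structure the pipeline
assumes. A class's noise-free spectrum is a sum of Gaussian bands; each
band's centre may drift and its amplitude scale with maturity level.
Each spot scan is then

$$x(\lambda) = b\,\mathrm{pure}(\lambda) + a + c\,s(\lambda) + \varepsilon(\lambda)$$

with per-spot gain $b \sim U(0.8, 1.2)$, offset $a \sim N(0,
\sigma_a)$, baseline slope $c \sim N(0, \sigma_c)$ against the
$[0,1]$-rescaled wavelength $s$, and i.i.d. point noise $\varepsilon$.
This scatter model is chosen *precisely* so that the classical
pretreatments are its correct inverses — SNV removes $a$ and $b$
exactly at zero noise, MSC recovers the pure spectrum given it as
reference, derivatives kill the constant and linear terms — making the
pretreatment-ranking direction testable. The default band library puts
broad features near the classic water/C–H regions (970, 1200, 1450,
1720, 1940, 2310 nm) on a wide continuum; amplitudes are plausible
reflectance magnitudes. No chemical realism is claimed: real leaf
spectra have correlated noise, instrument drift across sessions, and
class overlap that the generator does not emulate, so passing tests
demonstrate the *machinery*, not field-data accuracy. The published
headline accuracies were obtained on embargoed field data and are not
reproduction targets here.

`easy_benchmark(seed)` is the canonical acceptance fixture: one
position, five classes with large band contrasts, high SNR, zero
baseline slope, 56 leaves per class — a roughly four-fold scale-down of
one position's field dataset (280 vs ~1128 leaves), chosen so the full
suite, including training the complete 128/64-filter CNN, runs in
minutes on one CPU. On it, every classifier should exceed 95% testing
NER, and all five do in the acceptance tests (the CNN trains 50 epochs
there; its loss reaches ~0 within 10).

## Numerical choices and degenerate inputs

* Grid construction tolerates $10^{-9}$ steps of divisibility error and
  names the remainder otherwise; CSV headers are validated for strict
  monotone equal spacing at $10^{-3}$ relative tolerance (wavelengths
  print with ≤ 4 decimals).
* Constant spectra are rejected by SNV/min–max with the row index; MSC
  rejects near-zero slopes; Kennard–Stone requires a nonzero farthest
  pair.
* `which.max`-based tie-breaking (lowest index) is used everywhere a
  deterministic argmax is needed: KS picks, KNN votes, classifier
  argmax over class scores, tuning winners.
* The CNN predicts in 256-row chunks to bound the im2col working set;
  batch-norm uses $\varepsilon = 10^{-5}$; cross-entropy clamps
  probabilities at $10^{-12}$.
* All stochastic entry points take explicit integer seeds and restore
  the caller's RNG state (`withr::with_seed`), so the full pipeline —
  simulate → preprocess → split → train → evaluate — is bit-for-bit
  reproducible under a master seed, which `run_experiment` demonstrates
  by writing byte-identical reports.

## Known limitations

* The CNN trains on CPU in R; it is fast enough for the bundled
  problem sizes (~4 s/epoch on the 196 × 454 benchmark) but not for
  field-scale epochs-by-thousands studies.
* Only Euclidean Kennard–Stone is provided (no SPXY/duplex), and only
  the pretreatments listed above (no wavelets, OSC or detrending).
* KS on strongly clustered data can starve test cells of minority
  classes; stratified per-class KS is available
  (`split_dataset(..., stratify = TRUE)`) but not the default, since
  split totals are conventionally reported per dataset.
* The BPNN is intentionally the textbook algorithm (no momentum,
  no adaptive rates); it exists as a comparison baseline.
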