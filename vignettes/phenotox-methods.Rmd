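---
title: "Methods: profiling, prediction and dose-response in phenotox"
author: "phenotox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling, prediction and dose-response in phenotox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and data model

`phenotox` implements the downstream analysis of a plate-based Cell
Painting screen in which a compound panel is profiled across a
concentration series against same-plate vehicle (DMSO) controls, and an
ATP-luminescence assay provides an orthogonal viability readout. The
package consumes the outputs of an image-analysis pipeline — a
single-cell feature table — and never touches images or segmentation.

The central container is the `ProfileSet`, an S4 class extending
`SummarizedExperiment`: the `"profile"` assay stores morphological
features (rows) by profiles (columns), where a profile is a well or,
after aggregation, a compound-by-concentration treatment. `colData`
carries plate-layout metadata (`plate_id`, `well`, `compound`,
`concentration_m`, `vehicle`), per-profile cell counts and, once
attached, vehicle-relative viability; `metadata()` records the
processing state (aggregation level, normalization method, control
wells, feature drop ledger) so that every downstream step can verify
its preconditions.

# Well aggregation and normalization

Single cells are aggregated to one profile per well by the per-feature
**median** over the well's cell population; the number of contributing
cells becomes the well's `cell_count`. Cells with any missing feature
value are dropped first, with a logged count. Wells that lose their
entire population (zero detectable cells) cannot contribute a profile;
they are excluded from the profile columns but retained, with
`cell_count = 0`, in `metadata()$empty_wells`, because a well emptied by
cytotoxicity is a real observation for every count-based analysis
(`wellCountTable()` reassembles the complete well table).

Normalization is **per plate, against that plate's vehicle wells
only** — plate offsets are a dominant nuisance in high-content screens,
and anchoring each plate to its own controls removes them by
construction. Three methods are available; the default is **Robust
MAD**:

$$ z_{f,w} \;=\; \frac{x_{f,w} - \mathrm{median}(x_{f,\mathrm{ctrl}})}
     {1.4826 \cdot \mathrm{MAD}(x_{f,\mathrm{ctrl}})} , \qquad
   \mathrm{MAD}(x) = \mathrm{median}\,\lvert x - \mathrm{median}(x)\rvert $$

The 1.4826 consistency constant calibrates the MAD to the standard
deviation of a normal distribution, following the convention of the
cytominer family of profiling tools; after normalization, each plate's
vehicle wells have per-feature median exactly 0 and
$1.4826\cdot\mathrm{MAD} = 1$ (asserted to $10^{-9}$ in the tests).
`zscore` ($(x-\bar x_\mathrm{ctrl})/s_\mathrm{ctrl}$) and `minmax`
(control range scaling) are provided for comparison. A feature whose
control scale is zero on some plate is invariant in controls and
carries no calibrated deviation scale; it is dropped (with a ledger
entry) rather than epsilon-inflated, which would manufacture huge
pseudo-Z-scores out of numerical noise.

An open choice here is whether to normalize single cells before
aggregation or well profiles after it. `phenotox` normalizes the
aggregated well profiles: the control statistics are then estimated on
the same objects that are later compared (well medians), and the
procedure is invariant to well population size.

# Feature filtering

Two filters prune the normalized feature space, in this order:

1. **Dispersion**: features with SD above `sd_max` (default 2000) are
   discarded. On well-behaved normalized data this filter is inert; its
   purpose is to catch features blown up by a near-degenerate control
   scale.
2. **Correlation**: features are walked in stored column order; a
   feature whose absolute Pearson correlation with any already-kept
   feature exceeds `corr_max` (default 0.9) is dropped. Morphological
   features are notoriously redundant (which is exactly why the
   generator gives its noise a block-correlation structure), and the
   greedy earlier-column-wins rule makes the result deterministic and
   idempotent. The pair choice is otherwise arbitrary and is recorded,
   with the retained partner, in the drop ledger.

For per-compound models the filters are refit within each compound's
own wells, since a feature can be redundant globally but informative
locally (and vice versa).

# Induction and treatment clustering

Well profiles are aggregated to treatment level (median across the
condition's wells over all plates; `cell_count` is the median well
count). Each treatment profile carries its **induction**: the
percentage of features with absolute robust Z-score strictly above 3,

$$ \mathrm{Induction} = 100 \cdot
   \frac{\#\{f : |z_f| > 3\}}{\#\,\mathrm{features}} , $$

a scalar measure of perturbation strength. Profiles with induction at
or below the threshold (default 20%) are screened out before
clustering; both comparisons are strict, so boundary values are
excluded. This removes near-vehicle phenotypes whose noise would
otherwise spoil the dendrogram with meaningless clusters.

Hierarchical clustering uses **average linkage on the Pearson
dissimilarity** $d = 1 - r$ by default. The dissimilarity is $1-r$,
not $1-|r|$: two profiles perturbed in opposite directions are
biologically maximally distant ($d = 2$), not similar. Euclidean
distance is available but discouraged at high dimensionality; complete
and single linkage are available (single linkage with the Pearson
metric is the convention used for clustering feature-importance
matrices). Agglomeration is performed by `stats::hclust`, which is
deterministic for a fixed input order; profiles enter in their stored
column order, so ties break reproducibly. For heatmap export only,
values are clamped to ±8 (robust MADs) — clustering and induction
always see unclipped values.

# Random-forest prediction of viability and cell count

Each regression forest uses 200 trees, bootstrap resampling and
unlimited depth, with a fixed seed (default 42) from which the split
and forest sub-seeds are derived deterministically. Trees are grown
fully (terminal nodes down to one observation), and the number of
features tried per split stays at the `randomForest` regression default
of `p/3`: random feature subsetting decorrelates the trees and spreads
impurity credit across correlated features, which keeps importance
rankings stable — with all features tried at every split, the greedy
splitter picks a single winner among each block of correlated features
and the importance ranking beyond the first few features degenerates
into a near-flat plateau.
Wells are split 80/20 at random — not stratified by concentration —
with the test size `max(1, ceiling(0.2 n))` (so 96 wells give 76/20),
and the test rows never participate in feature filtering refits or
augmentation. Feature importance is mean decrease in impurity,
normalized to sum to 1.

Per-compound models (vehicle wells excluded, one model per target:
`viability_pct` and `cell_count`) are reported alongside a panel-wide
global model. $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ is reported
for train and test partitions with the MSE; when the test target is
constant, $R^2$ is undefined and reported as `NA` rather than a
headline number. Models whose target variance falls below
`low_variance_floor` are flagged as noise-dominated: the default floor
of 200 is calibrated for the viability-percent scale, where the
generator's assay noise alone (≈11% CV at 100% viability) produces a
variance of about 125 — a "good" $R^2$ on such a target would mostly
certify overfitting. For cross-model comparison, `importanceMatrix()`
ranks features within each model, orders them by median rank across
models, keeps the top 30 and clusters both axes (single linkage,
Pearson).

# SMOGN for rare cytotoxic profiles

Screens are imbalanced by design: most conditions barely move
viability, so low-viability morphologies are rare and a global
regressor under-serves exactly the region of interest. `phenotox`
implements SMOGN from scratch for the low-extreme case:

* **Relevance.** A boxplot-based relevance function over the target:
  relevance 1 at the low adjacent value $Q_1 - \mathrm{rel\_coef}\cdot
  IQR$ (clamped to `min(y)` when it falls below the data), 0 at the
  median and above, joined by a monotone piecewise-cubic interpolant
  clamped to $[0,1]$.
* **Bins.** Observations with relevance ≥ `rel_thres` (default 0.8)
  are rare; contiguous runs along the sorted target form bins.
* **Generation.** For each rare seed row, a neighbour among its
  `k_neighbors` (default 5) rare-bin neighbours is chosen at random.
  If that neighbour is closer than half the median seed-to-neighbour
  distance, a SMOTE-style interpolation is drawn
  ($x' = x_s + u\,(x_n - x_s)$, $u\sim U(0,1)$; target by
  inverse-distance weighting of the parents); otherwise Gaussian-noise
  generation perturbs the seed by `noise_sd_frac` (default 0.02) of
  each feature's SD. Synthetic targets are clamped to the observed
  range.
* **Balance.** Under `samp_method = "balance"`, rare bins are
  oversampled and normal bins randomly undersampled until every bin
  reaches the mean original bin size (undersampling can be disabled).

Neighbour distances are Euclidean in the filtered, normalized feature
space. Every synthetic row is flagged, and augmentation is only ever
applied to a training partition — the caller's test rows are never
resampled or synthesized, which the model reports verify by
construction. Where published SMOGN implementations leave behaviour
undocumented, the rules above are authoritative for this package;
bit-identical agreement with any particular implementation is not a
goal.

# Dose-response analysis

Raw luminescence is scaled per plate to the median of the vehicle
wells (100% = healthy vehicle level); the per-plate vehicle median is
exactly 100 after scaling, and a plate whose vehicle median is zero is
rejected.

Each compound-by-concentration condition is compared with the vehicle
wells of the plates it occupies by a two-sided **Welch** t-test,
separately for cell count and viability. Welch's unequal-variance form
is chosen because condition and control groups differ in both size and
variance by design. Tiers follow the screening convention (\* p<0.05,
\*\* p<0.01, \*\*\* p<0.001). No multiple-testing correction is
applied by default — the screen mimics the per-condition testing
convention of high-content screening reports — but Benjamini-Hochberg
adjustment is available behind a flag.

**Decoupling** flags conditions where the count drops significantly
(and by at least `count_drop_floor`, default 20%) while viability does
not: the signature of compounds, like tubulin binders, that abolish
detectable cells (division arrest, drastic morphology change) while
the surviving population's ATP content is maintained.

Potency summaries fit a four-parameter log-logistic curve per compound
to the median response across the concentration series (viability for
IC50; vehicle-relative count for LC50) by Levenberg-Marquardt least
squares, with a Nelder-Mead fallback. Initialization: ceiling = max
response, floor = min response, slope = 1, midpoint = geometric mean
of the dose range; the midpoint is bounded within 100× of the tested
range. A fit is **not determined** when the response span is below 20%
of the top response (flat), or the fit fails; midpoints outside the
tested range are flagged extrapolated. The 4PL choice itself is this
package's: potency summaries in screening papers rarely document their
fitting procedure, and the 4PL is the field's default.

# The synthetic screen generator

Because raw Cell Painting datasets of this design are rarely
redistributable, the package ships a generator that emulates the full
experiment with known ground truth, so that every pipeline stage has a
parameter-recovery test. The default configuration is the screening
design the analysis assumes: 30 compounds in 5 mechanism groups, 8
concentrations log-spaced from 10 nM to 30 µM, 4 technical-replicate
wells per condition on each of 3 plates (96 treated wells per
compound), 35 vehicle wells per plate, 300 features, ~250 cells per
healthy well.

Per compound, Hill curves (`hillEffect`) govern three dose-dependent
effects sharing a Hill coefficient of 1.5:

* **Detectable cell count**: expected count
  $= \mathrm{baseline}\cdot(1-E_\mathrm{count}(c))$, realized as a
  Poisson draw around a per-well lognormal biological factor
  (σ = 0.1).
* **ATP viability**: luminescence $\propto \mathrm{baseline} \cdot
  (1-E_\mathrm{atp}(c))$ with lognormal (σ = 0.1) and multiplicative
  (CV 5%) noise. Luminescence deliberately tracks true viable biomass,
  not detectable cells: that is what makes a colchicine-like compound —
  strong count decline, flat ATP — representable at all.
* **Morphology**: each cell's feature vector shifts by
  $E_\mathrm{morph}(c)\cdot \mathrm{effect\_scale}$ along the
  compound's unit effect direction.

Effect directions combine a **general cytotoxicity component** (shared
by all toxic compounds, supported on 120 features) with a
**mechanism-specific component** (24 features per mechanism, disjoint
supports), jittered per compound (SD 0.15) — so profiles of
same-mechanism compounds correlate strongly while all toxic compounds
share a weaker common signature, as in real screens. Cell-level noise
is multivariate normal with block-diagonal equicorrelation (blocks of
30 features at ρ = 0.6), emulating the channel/compartment redundancy
that motivates the 0.9 correlation filter; small additive plate
(σ = 0.05) and well (σ = 0.05) offsets make per-plate vehicle
normalization load-bearing. The default `effect_scale` of 8 cell-noise
SDs puts high-dose robust Z-scores in the several-MAD range that
motivates ±8 display clipping, and gives strongly toxic conditions
induction well above the 20% filter while weak conditions fall below
it.

The panel spreads maximal effects from 1.0 down to 0.2 across each
mechanism (potencies log-spread around 0.2–15 µM), and reserves two
special compounds: one **decoupled** (count Emax 0.7 at EC50 30 nM,
ATP Emax 0) and one **no-effect** compound (both Emax 0). Identical
configuration and seed give byte-identical outputs; a `null = TRUE`
switch forces every compound inert for type-I-error calibration.
`generateProfiledExperiment()` simulates and aggregates plate by plate
so the full-scale design runs in a couple of GB of memory; it draws the
identical random stream as `generateExperiment()`.

What the generator does **not** emulate: segmentation errors,
cell-cycle or spatial within-well structure, batch drift across days,
edge effects, or any myotube-specific shape biology. Passing the
recovery tests therefore shows that the pipeline's statistics do what
they claim under the stated noise model — not that any particular
biological screen will reach the same accuracies.

# Problem sizes and numerical choices

The test and acceptance workloads use the default full-scale design
(~2,900 wells, ~600k cells, 300 features) once, cached per session;
unit tests use an 8-compound miniature. The null-calibration run pools
nine inert screens (2,160 condition tests) generated with a minimal
feature load, since the count screen does not read features. Degenerate
inputs are handled explicitly rather than by tolerance tricks:
zero-scale features are dropped at normalization, constant profiles are
an error under the Pearson metric, a constant test target yields
`R^2 = NA`, an empty rare bin refuses augmentation loudly, and the 4PL
reports not-determined instead of extrapolating silently (midpoints
outside the tested range are flagged when they do occur).

# Known limitations

* The induction statistic treats features symmetrically and
  independently; correlated feature blocks make its percentage scale
  design-dependent, which is why the filter threshold is a tunable.
* B-score or other spatial plate normalizations are not implemented;
  the per-plate vehicle anchoring assumes no strong within-plate
  gradients.
* SMOGN here is single-target; multi-target regression and
  classification-style SMOTE are out of scope.
* The Welch screen tests each condition marginally; with 240
  conditions per screen, uncorrected p-values are a ranking device,
  and the FDR option should be used when calling individual
  conditions.
* Potency midpoints from 8-point curves are summaries, not
  benchmark-dose estimates; no confidence intervals are reported.
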