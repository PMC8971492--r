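---
title: "Methods: per-cluster empirical Bayes integration of cytometry batches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cluster empirical Bayes integration of cytometry batches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytofuse)
```

## The problem

Single-cell protein cytometry experiments — mass cytometry (CyTOF),
conventional and spectral flow cytometry, CITE-seq antibody panels — are
usually acquired in batches: different days, instruments, reagent lots or
even technologies. Batches introduce systematic per-marker distortions that
swamp downstream co-analysis: cells of the same phenotype land in different
places in expression space depending on when and where they were measured.
cytofuse removes this technical variance while preserving the biological
variance, without requiring technical replicates shared across batches.

The central difficulty is that a global per-marker adjustment is wrong for
cytometry: a marker's batch effect is not uniform across cell types (an
antibody may shift strongly on monocytes and barely on T cells). cytofuse
therefore *overclusters* cells into small, phenotypically homogeneous
partitions with a self-organizing map (SOM) and applies an empirical Bayes
location/scale adjustment independently within each partition.

## The correction model

Let $Y_{ijg}$ be the ArcSinh-scale expression of marker $g$ in cell $j$ of
batch $i$, inside one SOM cluster. The model is the classical location/scale
batch model:

$$Y_{ijg} = \alpha_g + X\beta_g + \gamma_{ig} + \delta_{ig}\,
\varepsilon_{ijg},$$

where $\alpha_g$ is the grand mean (weighted by batch size), $X\beta_g$
optional fixed covariate effects (e.g., a disease condition whose biology
must survive the correction), and $\gamma_{ig}$, $\delta_{ig}$ the additive
and multiplicative batch effects. Estimation follows the standard empirical
Bayes recipe:

1. **Standardization.** Marker-wise least squares on batch indicators plus
   covariate dummies gives $\hat\alpha_g$, $\hat\beta_g$ and the pooled
   residual variance $\hat\sigma_g^2$ (computed with a $1/n$ denominator);
   $Z = (Y - \hat\alpha - X\hat\beta)/\hat\sigma$.
2. **Per-batch effects.** $\hat\gamma_{ig}$ are the batch means of $Z$ and
   $\hat\delta^2_{ig}$ the batch variances ($n-1$ denominator).
3. **Hyperpriors.** Across markers within a batch,
   $\gamma_{ig} \sim N(\bar\gamma_i, \tau_i^2)$ and
   $\delta^2_{ig} \sim \text{InvGamma}(a_i, b_i)$, with all four
   hyperparameters estimated by moment matching
   ($a = (2s^2 + m^2)/s^2$, $b = (m s^2 + m^3)/s^2$ from the across-marker
   mean $m$ and variance $s^2$ of $\hat\delta^2$).
4. **Shrinkage.** The coupled posterior updates — precision-weighted
   location, inverse-gamma scale — are iterated to a relative-change
   tolerance of $10^{-4}$ (the stopping rule of the reference
   implementation of this algorithm; we additionally cap at 500 iterations
   and raise an error past the cap rather than looping indefinitely).
5. **Adjustment.**
   $Y^* = \hat\sigma\,(Z - \gamma^*)/\sqrt{\delta^{2*}} + \hat\alpha +
   X\hat\beta$.

The unit tests pin this chain to the independently maintained reference
implementation (`sva::ComBat`) at $10^{-6}$ on random designs; the package
never calls it at run time.

### Why shrinkage matters here

SOM clusters are deliberately small (overclustering), so a cluster may hold
only tens of cells per batch; raw per-batch variances would be noisy and
adjustments unstable. Borrowing strength across markers through the priors
is what keeps the adjustment defined and well-behaved down to eight cells
total (two batches of four), the documented lower bound of operation.

### Degenerate situations

Design choices for situations the model itself does not define:

* a cluster with a single batch, or any batch with fewer than two cells, is
  returned **unchanged** and logged — we never fabricate adjustments from
  undefined variances;
* a covariate confounded with batch *within a cluster* is dropped for that
  cluster (with a warning); the global design is still required to be
  non-confounded up front (see below);
* markers constant within some batch carry no scale information and are
  passed through unadjusted; if fewer than two adjustable markers remain
  (the across-marker moments need spread), the cluster is left unchanged;
* zero spread of $\hat\delta^2$ across markers makes the inverse-gamma
  moments undefined; scale shrinkage is then skipped
  ($\delta^{2*} = \hat\delta^2$) instead of dividing by zero.

## The pipeline around the model

1. **Ingestion** (`read_fcs()`, `assemble_dataset()`): FCS 3.0/3.1 files or
   delimited tables, optional count de-randomization (ceiling — it exactly
   inverts the uniform$(-1,0)$ noise CyTOF software adds to integer
   counts), then ArcSinh with a cofactor of 5 (CyTOF), 150 (flow) or 6000
   (spectral flow). De-randomization precedes the transform, so integers
   are transformed. Pre-gating is assumed done upstream.
2. **Design check** (`check_design()`): at least two batches; with a
   covariate, at least one condition of every batch must also occur in some
   other batch — otherwise batch and condition are inseparable and the run
   aborts naming the offending batches.
3. **Normalization for clustering only** (`normalize_batches()`): per
   batch, each marker is either Z-scored (low-variance batches, same
   platform) or rank-transformed with average ties (high-variance or
   cross-platform batches; ranks are invariant to any monotone distortion).
   Ranks are scaled by the batch's cell count into $(0,1]$ so SOM inputs
   are bounded and batch-size independent; this scaling is our choice —
   feeding raw ranks would make the SOM geometry depend on batch size.
   The normalized matrix is used **only** to train the SOM; corrected
   output is always computed from the original ArcSinh values.
4. **SOM partition** (`train_som()`, default $8\times8 = 64$ nodes):
   online training on a rectangular grid with a Gaussian neighborhood, 10
   passes over the data, learning rate decaying linearly 0.05 → 0.01 and
   radius $\max(g_x,g_y)/2$ → 0.5, codebook initialized from seeded data
   rows. Only the grid size is canonical for the method; the schedule is a
   conventional SOM default and is recorded here because it affects
   partitions. Everything is deterministic given (data, grid, seed). Err on
   the side of overclustering: a partition that splits a population is
   harmless, one that merges distinct populations lets correction blur
   biology.
5. **Per-cluster adjustment and capping** (`batch_correct()`): the model
   above per node (ascending node index; clusters are independent so order
   cannot matter), then each marker is capped to its global input min/max
   — "range of the input" is read as the whole input matrix, not per batch
   — so correction never extrapolates beyond observed expression. Capping
   after reassembly is mathematically identical to capping per cluster
   under a global range.

Two panels measured on split samples are co-corrected by relabeling
(batch := panel, covariate := condition); no special code path exists.

## Evaluation metrics

Labels for evaluation come from a fresh SOM trained on the **corrected**
expression (raw corrected values, not re-normalized), transferred to the
uncorrected data, so each cell carries one label in both datasets.

* **EMD reduction.** Per node × marker × batch pair, marker distributions
  are binned at width 0.1 over that marker's global range and compared by
  1-D earth mover's distance with ground distance = bins apart (equal to
  the L1 distance between the histograms' CDFs; verified in tests against
  a linear-programming transport solution). Records where both the
  uncorrected and corrected EMD are below 2 are dropped as uninformative,
  and
  $\text{reduction} = \sum_i (\text{EMD}^{before}_i -
  \text{EMD}^{after}_i) / \sum_i \text{EMD}^{before}_i$.
  1 means complete elimination of cross-batch distance. The filter
  threshold is interpreted in **bin units** (2 bins ≈ 0.2 ArcSinh units);
  a threshold of 2 raw ArcSinh units would discard essentially everything.
  If no record survives the filter the statistic is flagged undefined
  rather than reported as 0.
* **MAD score.** Per node × marker × **batch** (not pair), the median
  absolute deviation (consistency constant 1.4826) before and after;
  the score is $\text{median}_i\,|\text{MAD}^{before}_i -
  \text{MAD}^{after}_i|$. 0 means within-batch — i.e., biological —
  variability is untouched. EMD reduction measures inter-batch effects,
  the MAD score intra-batch side effects; they are read together.

## Panel merging by kernel-density donor draws

To merge two panels, one SOM is trained on the pooled overlap-marker
expression (the panels must be co-corrected on those markers first). Every
cell's missing markers are then filled from a **single** donor cell drawn
uniformly with replacement from the other panel's cells in the same node,
plus Normal(0, bandwidth) noise per marker — a draw from a per-node
multi-dimensional kernel density estimate. The single-donor rule is what
preserves co-expression between imputed markers; drawing markers
independently would destroy it. Bandwidths use Silverman's rule,
$0.9\,\min(\hat\sigma, \text{IQR}/1.34)\,n^{-1/5}$, computed on the node's
donor cells (the node is the "training population"; a panel-level variant
is a documented alternative). We implement the formula directly rather
than using `bw.nrd0()` because the latter substitutes a positive fallback
when the data have zero spread, whereas constant donors should impute
their shared value exactly. Nodes with fewer than 50 donors yield `NA` —
imputation from so few cells is unreliable — and an `is_imputed` mask
accompanies the merged data. Measured values are never modified, so
subtype frequencies are maintained. Imputed values are for visualization
and joint clustering; do not run differential-expression tests on imputed
markers. `salvage_channel()` applies the same mechanism within one
dataset, using good batches as donors for a mis-stained channel.
Sampling with replacement is deliberate: recipients may outnumber donors.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the structure the model assumes:
Gaussian populations on the ArcSinh scale (bimodal positive/negative
phenotypes near 3.5/0.5, within-population sd 0.3), per-batch per-marker
distortions `value * exp(N(0, 0.1)) + N(0, 0.3)` by default, optional
zero-inflation to stress the Gaussian assumption, and condition effects as
abundance shifts so covariate preservation is testable at the composition
level. Defaults (4 populations, 15 markers, 2 batches × 20,000 cells)
are the validation conditions; tests that need smaller or larger inputs
configure them explicitly. What the generator does **not** emulate — and
what passing tests therefore do not demonstrate — includes spillover,
acquisition drift within a run, doublets, heavy-tailed marker noise and
batch effects that vary *within* a phenotype cluster in ways other than
location/scale. Conclusions about real data rest on the model's
robustness, not on these tests.

Validation thresholds used by the test suite (fixed once, from the model's
expected behavior at these sample sizes, and not revisited): on effect-free
data (distortion sds 0), correction at 2 × 20,000 cells must leave the MAD
score below 0.05 and every marker mean within 0.02; under the default
distortions it must reach an EMD reduction of at least 0.5, a MAD score of
at most 0.05, and per-population per-marker batch means agreeing within
0.05.

## Numerical and interface choices

* ArcSinh cofactors: 5 / 150 / 6000 for CyTOF / flow / spectral flow.
* The de-randomization/transform order (ceiling first) is a documented
  choice; the alternative order differs only at sub-count magnitudes.
* FCS: reads 3.0/3.1 (float, double and integer list mode); writes 3.1
  float little-endian. Writing refuses non-finite values so `NA`
  imputation sentinels can never silently reach disk.
* Channel identity is the short parameter name (`$PnN`), case-sensitive;
  stain names (`$PnS`) are display aliases only.
* Seeds: every stochastic step (SOM init/order, donor draws, simulation)
  is driven by an explicit seed argument and restores the caller's RNG
  state; the CLI echoes all seeds into its JSON run report.
* The per-batch Z-score uses the $n-1$ denominator; single-cell batches
  normalize to zero rather than dividing by zero.

## Known limitations

* Batch effects that are not location/scale within a cluster (e.g.,
  bimodality appearing in one batch only) are outside the model family and
  will be only partially removed.
* The confounding requirement is structural: designs whose batches share
  no condition cannot be corrected, full stop.
* Batch correction operates on markers present in all batches; panel
  merging imputes the rest but cannot restore per-cell truth.
* SOM partitions, and hence results, depend on the documented training
  schedule and seed; different seeds give slightly different partitions
  (the evaluation protocol itself trains a SOM and inherits this).
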