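---
title: "Quantifying cross-age transcriptomic dynamics: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-age transcriptomic dynamics: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldyn)
```

# The question and the statistic

A developmental single-cell atlas samples the same tissue at several ages.
Clustering each age yields subtype labels, but the labels alone do not say
*how much* a class of cells rewires its expression programs between ages:
an immature subtype may persist under a new name, split into several mature
subtypes, or vanish into a converged adult identity. `celldyn` measures
this with a supervised transfer design:

* Train a classifier on age $t$: features are log-normalized expression of
  the highly variable genes of age $t$; labels are the age-$t$ subtypes.
* Predict a source-age label for every cell of age $t{+}1$.
* For each class $c$ (e.g. all IT subtypes), restrict to age-$t{+}1$ cells
  whose *true* class is $c$ and compare two partitions of them: true
  subtype labels vs transferred labels, with the plain Rand index

  $$\mathrm{RI} = \frac{a + b}{\binom{n}{2}},$$

  where $a$ is the number of cell pairs grouped together in both
  partitions and $b$ the number separated in both. The **dynamic score**
  is $1 - \mathrm{RI} \in [0, 1]$: 0 when subtype structure is preserved
  across the age pair, large when the classifier's view of the earlier age
  no longer matches the later age's structure.

Three properties make this usable on real atlases. It is label-name
invariant, so immature→mature renaming does not inflate scores. It is
partition-based, so classes with different subtype counts are comparable.
And the per-class restriction conditions on the target cell's *true* class,
so one class's score is unaffected by other classes' cells.

Per class, scores are summarized as the mean and standard deviation across
consecutive-age pairs, mirroring how such bar charts are usually drawn.

## Choices that were genuinely open

**Plain vs adjusted Rand index.** The unadjusted index is used, by design:
the score is a descriptive similarity, not a chance-corrected test
statistic, and the adjusted variant can be negative, breaking the $[0,1]$
interpretation.

**Pooled partitions per class.** A class's score is computed on the pooled
partition of all its subtypes, not as an average of per-subtype scores.
Pooling is what makes between-subtype reorganization (an immature subtype
feeding two mature ones) visible; per-subtype averaging would hide it.

**Class comparison test.** Classes are compared on their per-pair scores
with a two-sided Welch $t$-test by default. With only a handful of
consecutive-age pairs this is an approximation and is flagged as such; an
exact permutation test over pair assignments is available
(`comparison = "permutation"`). No specific published p-value is treated
as a reproduction target.

**Classifier.** Gradient-boosted trees (xgboost) are the default; the
number of boosting rounds is chosen by 5-fold cross-validation with early
stopping, and all randomness (fold assignment, tree building) is tied to
the `classifier_spec` seed, making training deterministic. A
ridge-penalized multinomial model and a nearest-centroid rule are provided
as deterministic alternatives; the score is defined for any classifier
meeting the determinism contract. Highly variable genes are computed on
the source (earlier) age, per the training design, and intersected with
the target's genes.

# Quality control and normalization

Defaults follow the common UMI recipe: cells with fewer than 1000 total
counts, fewer than 1000 detected genes, or more than 15% mitochondrial
content are removed; genes detected in fewer than 3 cells, and all
mitochondrial (`mt-` prefix) and ribosomal (`Rps`/`Rpl`) genes, are
removed. Boundary convention: "more than 15%" is strict, so a cell at
exactly 15% is kept. Filters are idempotent and preserve input order.

Normalization is per-cell scaling to `scale_factor` (default 10,000)
followed by $\ln(1+x)$, so `sum(expm1(values))` per cell equals the scale
factor exactly; natural log is used throughout except for reported fold
changes, which are log2. Highly variable genes are ranked by the classic
binned-dispersion recipe — per-gene dispersion (variance/mean of the
de-logged values), z-scored within 20 equal-width bins of mean expression —
which is deterministic and has no tuning beyond the bin count; ties break
by gene identifier so the ranking is stable under gene reordering.

# Differential expression and proportions

Marker detection uses the two-sided Wilcoxon rank-sum test with normal
approximation, tie correction and continuity correction (the in-package
vectorized implementation is verified gene-by-gene against
`stats::wilcox.test` in the test suite). Fold changes are
$\log_2\!\frac{\bar x_A + 1}{\bar x_B + 1}$ on de-logged normalized means
— the pseudocount-1 convention of the widely used single-cell toolkits —
and genes at or below $|\log_2 \mathrm{FC}| = 0.25$ are skipped rather
than tested. Bonferroni adjustment over tested genes is the default
(configurable); no claim is made that any particular published analysis
adjusted its volcano plots.

Subtype proportions are per-age fractions; each subtype's variability
across ages is its coefficient of variation, population SD over mean.
"Variation of the changes in proportion" is ambiguous between CV of the
fractions and CV of their consecutive-age deltas; the former is the
default and the latter available via `cv_of = "deltas"`.

# Spatial ligand–receptor colocalization

Inputs are segmented-cell centroid tables with per-cell intensities of a
ligand and a receptor gene. For cell $i$ with neighborhood $N_k(i)$ (its
$k = 5$ Euclidean nearest neighbors; distance ties break by cell id), the
pair strength with cell $j$ is

$$s(i,j) = \max(L_i R_j,\; L_j R_i)$$

and the cell's colocalization score is $\max_{j} s(i,j)$ over the
neighborhood. The exact pairwise formula used by published colocalization
routines is not printed anywhere authoritative, so this "strongest
directional product" rule is an explicit, documented assumption of the
package, switchable to the single direction $L_i R_j$
(`rule = "directional"`). Two further choices:

* The cell itself is in its own candidate set by default — a cell
  co-expressing ligand and receptor colocalizes trivially
  (`include_self = FALSE` to disable).
* Intensities are min-max scaled per gene before scoring
  (fluorescence units are arbitrary); with `normalize = FALSE` the score
  is computed on raw values, under which it is exactly scale-equivariant
  (multiplying all ligand values by $c$ multiplies all scores by $c$).
  The normalized and raw variants cannot both have that equivariance, so
  the property is guaranteed, and tested, for the raw rule only.

Fields are compared by a two-sided Wilcoxon rank-sum test on per-cell
scores. Spot annotation of deconvolution abundances is the argmax over
non-excluded subtypes, ties broken by subtype name, all-zero spots labelled
`"unassigned"`.

# The synthetic-data generator

Every stage is exercised against simulated data with known ground truth.
The generator emulates the statistical skeleton of a multi-age UMI atlas:

* **Counts.** Negative binomial around subtype-and-age mean programs,
  `size = 1/dispersion` (default dispersion 0.5, a typical droplet-data
  value), with log-normal per-cell library sizes (default mean 5,000 UMIs,
  `sdlog` 0.3).
* **Programs.** Each subtype draws a start and an end program: a flat
  baseline with ~10% of genes up-weighted about 4-fold (sparse marker
  structure). With drift $d$, the mean program at age index $a$ of $A$ is
  $(1 - d\,a/(A{-}1))P_{\text{start}} + (d\,a/(A{-}1))P_{\text{end}}$ —
  the simplest monotone model of immature→mature program replacement;
  $d = 0$ is a transcriptomically stable subtype.
* **Artifacts.** A small fraction of cells (default 2%) is injected with
  elevated mitochondrial content (35%) and a 0.3× library, giving the QC
  thresholds true positives. Mitochondrial and ribosomal genes carry the
  `mt-`/`Rps`/`Rpl` prefixes the QC module recognizes.
* **Cell allocation.** Subtype counts per age follow the proportion
  schedule by largest-remainder rounding, ties by subtype order, so label
  conservation is exact within rounding.
* **Spatial fields.** Cells uniform on a rectangle; a central disc
  covering `coloc_fraction` of the area expresses ligand and receptor at
  high means, the rest at low means, with log-normal intensity noise.

Both generators are bit-reproducible given their config seed and restore
the caller's RNG state.

What the simulation deliberately omits: batch effects, doublets, ambient
RNA, within-class correlation between subtype programs, spatially varying
cell density. Passing tests therefore demonstrate correctness of the
computations and recoverability of the modelled signal — not robustness to
those real-data pathologies, which upstream tools (integration, doublet
removal) are expected to handle.

A mechanistic note on why drift is detectable: consecutive-age program
shifts are modest relative to between-subtype separation, so a
distance-based classifier tracks them and scores stay near zero. Boosted
trees, whose axis-aligned thresholds are calibrated tightly to the source
age's expression ranges, misroute a fraction of shifted cells — precisely
the covariate-shift sensitivity that makes the transfer design informative.
The test suite verifies the consequence: the default classifier's mean
dynamic score grows monotonically over drift $\in \{0, 0.3, 0.6, 0.9\}$.

# Numerical and degenerate-input conventions

* Rand index is computed in compiled code via the contingency-table
  identity $a + b = \binom{n}{2} + 2\sum_{ij}\binom{n_{ij}}{2} -
  \sum_i\binom{n_{i\cdot}}{2} - \sum_j\binom{n_{\cdot j}}{2}$, exact in
  double precision at these scales; it requires $n \ge 2$.
* A (pair, class) cell set with fewer than 2 cells cannot be scored and is
  flagged missing, excluded from the class mean/SD.
* Sankey edges below similarity 0.05 are dropped by default for
  readability; conservation (per-target-subtype similarities summing to 1)
  holds at floor 0.
* `normalize_counts` refuses zero-total cells; QC must run first.
* Matrix Market files use the format's 1-based indices; symmetric/pattern
  storage optimizations written by the serializer are undone on read, and
  identifier files tolerate CRLF endings and 10x-style extra columns.
* Gene identifiers match case-sensitively (mouse symbols are
  case-meaningful).

# Problem sizes used by the test suite

The suite checks the Rand index against an independent co-membership
oracle exhaustively over all pairs of set partitions up to $n = 8$
(~18 million pairs) and on 1,000 random pairs up to $n = 50$. Drift
recovery uses a four-age course with a drifting ($d = 0.9$) and a stable
class of three subtypes each, 300 cells per age and 500 genes, over 20
simulation seeds, plus a two-age sweep over $d \in \{0, 0.3, 0.6, 0.9\}$
with 10 seeds; these sizes give stable rankings while keeping a full run
in minutes on one CPU, and are the same conditions `scripts/acceptance.R`
reports on. DE calibration uses 2,000 genes and 100 cells per group: ten
null simulations for the type-I error and a 20-gene, 3-fold spike-in for
power — 3-fold being a typical strong-marker effect — with false positives
counted at Bonferroni-adjusted 0.05.

# Known limitations

* The dynamic score conflates genuine biological reorganization with
  classifier failure from any cause; grossly underpowered training data
  will inflate scores. The duplicated-age check (score ≈ 0 when an age is
  its own target) is the control for this.
* With few consecutive-age pairs the per-class SD and the Welch test are
  coarse; treat the p-values as descriptive.
* The ligand–receptor pair-strength rule is an assumption (documented
  above), and min-max normalization makes scores relative within a field —
  comparisons across fields assume comparable intensity distributions.
* The simulator's drift is linear in age index; staged or pulsatile
  maturation is not modelled.
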