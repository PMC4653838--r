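---
title: "Methods: correlation-based feature extraction for multi-omics subtype discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-based feature extraction for multi-omics subtype discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iBFE)
```

## The problem

Disease subtyping from multi-omics data starts from $K$ numeric matrices
$T^{(1)}, \dots, T^{(K)}$, one per datatype (methylation, mRNA, miRNA, ...),
each with the same $M$ patients in rows but different features in columns.
The naive integration — concatenating the matrices column-wise and clustering
the result — fails whenever the datatypes disagree in scale, noise
distribution, or noise size: the datatype with the largest numeric range
dominates every distance computation, and signal in the other datatypes is
drowned out.

## The two-stage correlation mapping

`ibfe()` sidesteps the heterogeneity by never comparing raw features across
datatypes. It works in three steps:

1. **Per-datatype patient similarity.** For each datatype $k$, compute the
   $M \times M$ Pearson correlation matrix $P^{(k)}$ and Spearman correlation
   matrix $S^{(k)}$ between patient rows. Correlation is scale- and
   location-free, so each datatype is mapped onto the common $[-1, 1]$ scale
   regardless of its units. The Spearman half is additionally invariant to
   any strictly increasing per-feature transform.
2. **Stacking.** Concatenate the similarity matrices row-wise into
   $Y = [P^{(1)}\, S^{(1)}\, \cdots\, P^{(K)}\, S^{(K)}]$, an
   $M \times 2MK$ matrix. Because every block lives on the same scale,
   this concatenation is safe where the raw one was not.
3. **Second-stage correlation.** The integrated similarity is the Pearson
   correlation of the rows of $Y$:
   $Z_{ij} = \mathrm{cor}(Y_{i\cdot}, Y_{j\cdot})$. Two patients are
   similar when they relate to the *whole cohort* in the same way across all
   datatypes.

The method has no tuning parameters. Three variants select the first-stage
correlation kinds: `ibfe1` (Pearson + Spearman, default), `ibfe2` (Pearson
only), `ibfe3` (Spearman only; fully invariant to monotone transforms).
`directConcatenate()` provides the naive baseline for comparison.

Numerical conventions, chosen once and used everywhere:

- A patient row with zero variance has undefined correlations; we set its
  similarities to 0, keep the unit diagonal, and warn.
- All correlations are clipped to $[-1, 1]$ to absorb floating-point
  excursions; symmetry is enforced to $10^{-8}$ by the
  `SimilarityMatrix` validity check.
- Spearman uses midranks for ties.

## The simulation benchmark

`simulateScenario()` generates five two-datatype scenarios, each isolating
one failure mode of naive integration. All are built from a block prototype:
an $2n \times 2v$ matrix whose upper-left and lower-right $n \times v$ blocks
are 1 and the rest 0 (defaults $n = 50$, $v = 50$, giving $100 \times 100$
datasets with two planted classes of 50).

- **sd1 — scale conflict.** A single noisy prototype
  $D_0 = \text{blocks} + N(0,1)$ is drawn, then transformed two ways:
  $T_1 = D_0^{\,q}$ and $T_2 = q^{D_0}$ (default study value $q = 20$). The
  noise is added *before* the transforms, so both datasets carry the same
  underlying sample but on wildly different scales ($T_1$ spans
  $\pm 10^{13}$, $T_2$ spans $[10^{-5}, 10^{6}]$). At $q = 1$ the two
  datasets coincide and the generator warns. Note the even default power
  makes $T_1$ non-monotone in $D_0$ (ranks of $x^{20}$ are ranks of $|x|$);
  this is part of the scenario, not a defect.
- **sd2 — noise-type conflict.** Clean prototypes plus $N(0, q)$ noise in
  dataset 1 and $U(0, q)$ noise in dataset 2.
- **sd3 — noise-size conflict.** Pure noise scale mismatch:
  $N(0, \sigma_1)$ vs $N(0, \sigma_2)$ added to the prototypes, with
  $\sigma_1 \ne \sigma_2$ enforced (default pair 0.5 and 2.0).
- **sd4 — incomplete relationships.** Each dataset defines only half of the
  class structure (complementary half-defined prototypes); only their union
  recovers both classes. This is the scenario where concatenation is
  expected to do well.
- **sd5 — conflicting relationships.** The two datasets carry *crossing*
  bipartitions; the joint truth is the 4-class refinement with sizes
  30/20/20/30.

What the generator emulates: heterogeneity of scale and noise across omics
platforms, partial and conflicting views of the same cohort. What it does
not: feature-feature dependence structure, count distributions, batch
effects, or missingness within a matrix — real omics preprocessing is out of
scope.

**Realistic augmentation** (`realistic = TRUE`, or `realisticAugment()` on
an existing output) makes the cohort harder: the second class is doubled
(for sd5, class 2 of the 4-class truth), 50 *unclassified* patients are
appended, and $10 \times v$ pure-$N(0,1)$ feature columns are added to every
dataset (a 200-patient, 1100-column design at the defaults). Unclassified
patients have `NA` labels and are excluded from every label-dependent
metric. One deliberate design choice: unclassified patients are generated
from a zero prototype passed through the *scenario's own* noise and
transform, not from unit-variance noise. Giving them literal $N(0,1)$
features would let clustering isolate them purely by a noise-scale mismatch
whenever the scenario noise scale differs from 1, an artifact the
augmentation is not meant to introduce.

## The evaluation suite

- `intraInterPCC()` — mean Pearson correlation between feature rows of
  same-class vs different-class patient pairs.
- `gaussianKernelSimilarity()` — the same contrast under a Gaussian kernel
  $\exp(-d^2/2\sigma^2)$; the default bandwidth is the median off-diagonal
  Euclidean distance, a standard heuristic that adapts to the feature scale.
- `bestKmeans()` — k-means with `nRestarts` random initializations (default
  1000), keeping the solution with minimum total within-cluster sum of
  squares. Restarts make the non-convex optimization reproducible in
  practice.
- `nmi()` — normalized mutual information with the symmetric
  $\sqrt{H(A)H(B)}$ normalization. Conventions for degenerate partitions: if
  either labeling has zero entropy, NMI is 1 when the two labelings are
  identical up to renaming and 0 otherwise.
- `looRFAccuracy()` — leave-one-out random-forest accuracy (500 trees,
  `mtry = floor(sqrt(p))`, single-threaded with a per-fold seed for exact
  reproducibility). This measures how *learnable* the planted classes are
  from a representation, complementing the unsupervised NMI.
- `stableK()` — choice of the number of clusters by resampling stability.
  Each batch clusters a random 80% patient subsample; the score of a
  candidate $k$ is the mean pairwise NMI between batch partitions restricted
  to their shared patients, and ties go to the smaller $k$. The naive
  alternative — re-running k-means on the full data and scoring agreement —
  is degenerate: with enough restarts every run finds the same optimum, all
  $k$ score 1, and the tie rule always returns the smallest candidate.
  Subsampling is what makes instability visible.
- `runBenchmark()` — repeats a scenario `nRepeats` times with derived
  per-repeat seeds and reports mean/sd/n per method and metric in an
  `EvaluationReport`.

## Survival stratification

`logrankVsRest()` joins cluster labels with a clinical table
(`patient_id`, `time`, `event`), drops and reports patients missing from
either side, and tests each cluster against the rest of the cohort with the
log-rank test ($\chi^2$ with 1 df). `kmCurve()` returns the Kaplan–Meier
product-limit estimate as a plain data frame. Both delegate the numerics to
the `survival` package; the tests pin them against hand-worked
observed-minus-expected oracles.

## Problem sizes and costs

The intended scale is cohorts of $10^2$–$10^3$ patients. The integration is
$O(K M^2 F + M^3)$ time and $O(M^2 K)$ memory; at $M = 100$, `ibfe()` takes
milliseconds, a full 100-repeat benchmark with clustering a few minutes, and
leave-one-out random forests dominate any run that includes them (about 3–9
seconds per LOO pass at $M = 100$).

## Limitations

- The second-stage correlation needs $M \ge 3$ patients and assumes all
  datasets cover the same patients (`alignPatients()` intersects IDs first).
- Correlation-based similarity ignores feature-level effect sizes: a
  datatype where classes differ in only a few of many features contributes
  weak first-stage similarity.
- The simulation benchmark is a stress test of integration logic, not a
  generative model of any omics platform.

## A minimal session

```{r example, eval = FALSE}
sim <- simulateScenario("sd1", q = 20, seed = 1)
z <- ibfe(simDatasets(sim), variant = "ibfe1")
cl <- bestKmeans(featureValues(z), k = 2, nRestarts = 100, seed = 1)$cluster
nmi(trueLabels(sim), cl)
```
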