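---
title: "Methods: iterative maximum-likelihood assignment of dangling transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative maximum-likelihood assignment of dangling transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Multiplexed FISH images yield a table of mRNA spots and a cell
segmentation that is deliberately conservative: nuclei are easy to
outline, full cell bodies are not, so a large fraction of transcripts
falls outside every boundary and would normally be discarded.
`sparcler` reassigns these dangling transcripts to cells.

The model treats each cluster of cells (a putative cell type) as a
multivariate Gaussian over preprocessed expression space. The Gaussian
is an approximation justified by the large transcript count per cell
(a central-limit argument), not by the counts themselves being
Gaussian — counts are integers and in our simulator are explicitly
Dirichlet-multinomial, so running the pipeline on simulated data tests
exactly this approximation.

One iteration:

1. *Preprocess and cluster.* Cells are depth-normalized to the median
   cell total, log1p-transformed, and z-scored per gene. Clustering
   uses either a kNN/Jaccard graph with Louvain communities
   (`clusterGraph()`) or a Dirichlet process mixture model
   (`clusterDpmm()`); neither takes the number of clusters as input.
2. *Moments.* `estimateMoments()` computes each cluster's mean and
   sample covariance (denominator `n - 1`; singleton clusters borrow
   the pooled within-cluster covariance) and adds a ridge
   `lambda = lambdaFrac * mean(diag(pooled))` so every covariance is
   positive definite with a cached Cholesky factor.
3. *Mock cells.* For a dangling spot, every spot within radius `r`
   (inside, assigned, or still dangling — proximity draws no
   distinction, and including previously assigned spots is what lets
   later iterations see earlier decisions) contributes weight
   `1 / (1 + d / delta)` to its gene. The spot itself sits at `d = 0`
   with weight 1.
4. *MLE call.* The mock vector is rescaled to the median raw cell
   total and pushed through the identical log1p/z-score transform
   (with the training means and sds), then classified by pure maximum
   likelihood over the cluster Gaussians. No mixing-proportion prior
   is used, so cluster sizes do not bias the call; ties break to the
   lower cluster id.
5. *Assign or abstain.* The spot goes to the nearest cell (centroid
   distance, ties to the lower cell id) carrying the called label
   within the cap `D`; if no such cell exists, or the likelihood
   margin between best and second-best cluster falls below
   `minLoglikMargin`, the spot stays dangling. Abstention is the
   conservative outcome: a false negative leaves one transcript
   uncounted, a false positive contaminates a cell's profile.
6. *Batch update.* All accepted assignments are applied at once, in
   spot-id order, then the loop re-clusters and re-estimates moments.
   Batch (synchronous) updates make the iteration order-independent:
   each spot's decision depends only on the state at the start of the
   iteration, which is also what makes per-spot work trivially
   parallelizable.

The loop runs for `maxIterations` (default 3) and stops early when an
iteration assigns nothing.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `r` (mock radius) | 2 x median equivalent-disk radius of segmented cells | coord. units | ties the neighborhood to the observed cell scale, keeping the default unit-free; a cell's transcripts extend well beyond its nucleus |
| `maxAssignDist` D | 4 r | coord. units | a spot should only reach a cell within a couple of cell diameters |
| `delta` | 1 | coord. units | scale of the shifted-inverse weight; `1/d` diverges at the spot itself, `1/(1 + d/delta)` gives the spot weight 1 |
| `minLoglikMargin` | 0 (off) | log-likelihood | explicit conservativeness gate; raising it can only reduce assignments |
| `maxIterations` | 3 | — | the assignment yield decays sharply across iterations; three captures nearly all recoverable spots |
| `lambdaFrac` | 1e-2 | fraction of mean pooled variance | covariance ridge; with ~16 cells per cluster and 140 genes the sample covariances are singular without it |
| `kNeighbors` | 30, capped at n/4 | cells | 30 is common practice at atlas scale; the cap matters for FoV-scale data (see below) |
| DPMM `alpha` | 1 | — | standard weakly-informative DP concentration |
| DPMM prior | m0 = data mean, k0 = 0.01, nu0 = d + 2, S0 = diag(var) | — | weakest proper conjugate NIW centered on the data |

# The synthetic field of view

`simulateFov()` generates the study conditions end to end: K = 5
Dirichlet(0.1) gene programs over 140 genes; 80 cells placed by
rejection sampling with 24-unit minimum spacing in a 512 x 512 field;
per-cell transcript counts NegBin(mean 300, size 10); genes i.i.d.
from the cell's program; positions isotropic Gaussian around the cell
center; segmentation = one nucleus disk per cell (radius 6). All
draws come from one seeded stream in documented order, so a FoV is a
pure function of its seed.

Two generator choices deserve justification:

* **Transcript spread `cellSigma = 5`.** The probability that a
  transcript lands inside its own nucleus disk is
  `1 - exp(-R^2 / (2 sigma^2))`; with R = 6 and sigma = 5 this is
  ~0.51, so the conservative segmentation leaves roughly half of all
  transcripts dangling — the regime these images actually exhibit and
  the regime the pipeline is designed for.
* **Dirichlet-multinomial programs, not Gaussians.** Counts must be
  nonnegative integers; the Gaussian is the *model's* approximation,
  so simulating counts and modeling Gaussians stresses that
  approximation rather than assuming it.

What the simulator deliberately does not emulate: cell morphology
(axons, anisotropy — transcript placement is isotropic, matching the
circular mock-cell assumption), optical noise, spot-decoding errors,
doublets, 3D structure, and spatial correlation between gene identity
and subcellular position (genes are i.i.d. given the cell). Passing
tests therefore demonstrate correctness of the machinery and of the
statistical logic under the model's own assumptions — not robustness
to morphology-driven misassignment, which real tissue adds on top.

Problem sizes in the test suite are FoV-scale by design: one 80-cell
default field for the end-to-end checks, 20-cell fields for
driver-level properties, 100-instance randomized batteries for the
exhaustive-oracle equivalences, and 1000 replicates for the Box's M
calibration.

# Numerical and design choices

* **Containment** uses the half-open pixel rule (pixel (i, j) covers
  `[i, i+1) x [j, j+1)`), with no epsilon tolerance: deterministic and
  exactly testable. Spots outside the image extent dangle with a
  warning rather than failing — real exports contain edge spots.
* **Dilation collisions** resolve to the nearest original label (ties
  to the lower id), so dilating never flips a pixel between original
  cells.
* **Graph clustering at FoV scale.** Two failure modes bracket the
  kNN choice: with k above the size of a minority cluster, the
  community is absorbed (most of its edges leave it); with small k, a
  single Gaussian cloud is parcellated by modularity optimization.
  We cap k at n/4 and then merge any two communities whose centroid
  distance is below twice the sum of their within-community sds
  projected on the discriminant direction — halves of one Gaussian
  score ~1.3 on this index, genuinely distinct clusters score far
  higher. The merge threshold of 2 corresponds to treating Gaussian
  clusters less than ~4 projected sds apart as one population.
* **DPMM details.** Collapsed Gibbs over NIW components with
  posterior-predictive Student-t evaluation; labels come from the
  maximum-a-posteriori sweep (joint CRP + marginal likelihood score) —
  simple, deterministic given the seed, and sufficient for moment
  estimation. Chains initialize with every cell in its own cluster:
  collapsed Gibbs merges clusters readily but splits them poorly, so
  over-initialization mixes better. Dimensions above `maxPcs` (50)
  are first reduced by PCA to keep the NIW posteriors
  well-conditioned. A known limitation of the S0 = diag(var) prior:
  when clusters are few-membered relative to nu0 and the marginal
  variance is dominated by between-cluster separation, the broad
  prior predictive can favor merging; with tens of cells per cluster
  the data dominate and the issue disappears.
* **Profile covariance rank.** Z-scored cluster profiles satisfy an
  exact size-weighted zero-sum constraint across clusters (the
  weighted mean of cluster means is the overall mean, which is 0
  after z-scoring), so the K x K profile covariance has rank K - 1;
  `compareRuns()` therefore runs Box's M on K - 1 cluster
  coordinates.
* **Box's M** uses the classical chi-square approximation with Box's
  correction factor; groups too small for a full-rank covariance
  (n <= p) are shrunk toward the pooled estimate with a warning.
* **Loewner ordering** is decided by eigenvalues with tolerance 1e-8
  (not by Cholesky success), because the eigenvalue spectrum
  distinguishes incomparability from one-sided dominance.
* **Ties** everywhere break toward the lower id (cluster id, cell id),
  making every path deterministic.
* **Degenerate inputs** fail loudly and early: all-zero count
  matrices, empty clusters, zero mock vectors, non-finite values, and
  dimension mismatches raise errors naming the offending object;
  zero-count cells are dropped from clustering with a warning and
  keep their previous cluster label.
* **"Improved cell boundaries"** are exported as convex hulls of each
  cell's member spots — the minimal defensible construction, since no
  boundary algorithm is otherwise implied by the model.

# Known limitations

* Assignment accuracy on real tissue is bounded by morphology the
  model cannot see: transcripts in unsegmented processes of a *distant*
  cell will be attributed to nearer cells of the called type.
* The mock-cell radius is global; fields mixing very small and very
  large cells would benefit from a per-region radius.
* The evaluation statistics compare cluster-level structure; they do
  not detect compensating per-cell errors that leave cluster means
  unchanged.
* Everything is 2D; extending to 3D would replace disks and circles
  with balls and spheres without changing the logic.
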