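# sparcler

Imaging-based spatial transcriptomics (MERFISH, smFISH, pciSeq,
STARmap, ...) detects individual mRNA molecules as spots in multiplexed
images, but turning spots into a cell-by-gene count matrix requires a
cell segmentation — and segmentations derived from nuclear stains are
deliberately conservative. Roughly half of all detected transcripts
fall outside every cell boundary ("dangling" transcripts) and are
normally discarded, biasing per-cell quantification and weakening
cell-type and gene-program analyses.

`sparcler` implements Sparcle-style iterative maximum-likelihood
reassignment of dangling transcripts to cells, for analysts working
with spot tables and label-mask segmentations from any of these
platforms. It also ships a ground-truth synthetic field-of-view (FoV)
generator, so the whole pipeline is testable without any external
download, and the covariance-based statistics used to compare pre- and
post-assignment expression structure.

## The model

Let the segmented cells have expression vectors in a preprocessed
space (median-depth normalization, log1p, per-gene z-score). One
iteration of the model:

1. **Cluster** the current cell-by-gene matrix with a method that does
   not fix the number of clusters: a Phenograph-style kNN/Jaccard
   graph with Louvain community detection, or a Dirichlet process
   mixture model (collapsed Gibbs over conjugate
   Normal–Inverse-Wishart components).
2. **Moments.** For each cluster k estimate the first- and
   second-order moments (mu_k, Sigma_k) of its member cells; Sigma_k
   is ridge-regularized so the multivariate Gaussian
   N(mu_k, Sigma_k) is always well defined.
3. **Mock cells.** For every dangling spot s build a circular "mock
   cell" of radius r centered on s: every spot within r contributes
   weight w(d) = 1 / (1 + d/delta) to its gene's entry, so proximal
   transcripts dominate the pseudo-expression vector.
4. **MLE call.** Map the mock vector into the preprocessed space and
   call its cluster by pure maximum likelihood,
   argmax_k log N(v; mu_k, Sigma_k) — no mixing-proportion prior.
5. **Assign.** Attach the spot to the nearest cell (centroid
   Euclidean distance) carrying the called cluster label, provided it
   lies within a distance cap D and the likelihood margin clears a
   conservativeness gate; otherwise the spot stays dangling.
6. **Update** the count matrix with all accepted assignments at once
   (batch, order-independent) and repeat for a fixed number of
   iterations (default 3), re-clustering and re-estimating moments
   each time.

Outputs are the corrected count matrix (MTX + CSV), per-spot
assignment records with log-likelihood provenance, per-cell cluster
labels, and convex-hull cell-boundary estimates over member spots.

## Worked example

Simulate the default MERFISH-like FoV (80 cells, 140 genes, 5
expression programs, a conservative nucleus-disk segmentation leaving
about half the transcripts dangling), run three iterations, and score
against the generative truth:

```r
library(sparcler)

sim <- simulateFov(simConfig(seed = 0))
bm  <- buildCountMatrix(sim$spots, sim$seg)
danglingFraction(bm$spots)
#> [1] 0.4913304

res <- runSparcle(sim$spots, sim$seg, seed = 0)
res$reports[, c("iteration", "nAssigned", "fractionOfTotal", "K")]
#>   iteration nAssigned fractionOfTotal K
#> 1         1     11750    4.897466e-01 5
#> 2         2        26    1.083695e-03 5
#> 3         3         2    8.336112e-05 5

sc <- scoreAssignments(res$records, sim$truth)
c(cell = sc$cellAccuracy, cluster = sc$clusterAccuracy)
#>      cell   cluster
#> 0.9971133 0.9973680
```

So 49.1% of the 23,992 simulated transcripts start dangling; the model
recovers nearly all of them across three iterations of decreasing
yield, and 99.7% of recovered transcripts land on their true
generating cell. Comparing expression structure before and after
assignment against the ground-truth cluster profiles:

```r
ref   <- clusterProfiles(sim$truth$trueCounts, sim$truth$clusterOfCell)
pp    <- preprocessCounts(res$initialCounts)
clPre <- clusterGraph(pp$X, seed = 1, preprocessing = pp$record)
compareRuns(pre  = list(counts = res$initialCounts, clustering = clPre),
            post = list(counts = res$counts, clustering = res$clustering),
            reference = ref)
#>    run K nMatched frobeniusProfiles frobeniusGramian    boxMP diagDominance
#> 1  pre 5        5         3.1843374      0.204554155 0.965092     0.3913817
#> 2 post 5        5         0.4731747      0.004853015 1.000000     0.4277121
```

The post-assignment cluster profiles sit much closer to the truth
(Frobenius distance 0.47 vs 3.18) and the cross-covariance diagonal is
more dominant — the direction expected when reassignment restores real
expression structure.

A thin CLI wraps the same functions:

```sh
inst/scripts/sparcle simulate --seed 0 --out fov/
inst/scripts/sparcle run --spots fov/spots.csv --mask fov/mask.tif --out out/
inst/scripts/sparcle evaluate --pre out/ --post out/ \
    --reference fov/truth/profiles.csv
```

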