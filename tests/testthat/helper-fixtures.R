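# shared fixtures, all generated in code

# isotropic Gaussian blobs with known labels
makeBlobs <- function(centers, nPer, sd = 1, seed = 1) {
  set.seed(seed)
  X <- NULL; lab <- integer(0)
  for (i in seq_len(nrow(centers))) {
    X <- rbind(X, cbind(stats::rnorm(nPer, centers[i, 1], sd),
                        stats::rnorm(nPer, centers[i, 2], sd)))
    lab <- c(lab, rep(i, nPer))
  }
  list(X = X, lab = lab)
}

# a small, fast FoV for driver-level tests
smallSimConfig <- function(seed = 0, ...) {
  args <- list(nCells = 20, nGenes = 30, nClusters = 3,
               countsMean = 80, fieldSize = c(256L, 256L),
               minCellSpacing = 24, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

# build a SpotTable directly from vectors
spotTableOf <- function(gene, x, y, panel = NULL, id = NULL) {
  if (is.null(id)) id <- sprintf("s%03d", seq_along(gene))
  sparcler:::.newSpotTable(
    data.frame(spot_id = id, gene = gene, x = x, y = y,
               stringsAsFactors = FALSE), panel = panel)
}

# mask with disk cells at given centers (x, y), for containment tests
diskMaskSeg <- function(field, centers, radius) {
  readSegmentation(sparcler:::.diskMask(as.integer(field),
                                        centers, radius))
}
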