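#' @include AllClasses.R io.R clustering.R dpmm.R assignment.R
NULL

.equivDiskRadii <- function(seg) {
  if (is.null(seg@mask)) stop("equivalent-disk radius needs a mask")
  areas <- table(seg@mask[seg@mask > 0L])
  sqrt(as.numeric(areas) / pi)
}

.resolveParams <- function(params, seg) {
  r <- params@r
  if (is.na(r)) r <- 2 * stats::median(.equivDiskRadii(seg))
  D <- params@maxAssignDist
  if (is.na(D)) D <- 4 * r
  list(r = r, D = D, delta = params@delta,
       margin = params@minLoglikMargin,
       maxIter = params@maxIterations)
}

.emptyRecords <- function() {
  data.frame(spot_id = character(0), cell_id = integer(0),
             cluster_id = integer(0), iteration = integer(0),
             loglik = numeric(0), stringsAsFactors = FALSE)
}

#' Run the iterative dangling-transcript assignment model
#'
#' The full loop, for a fixed number of iterations: (1) normalize and
#' cluster the current cell-by-gene matrix (cluster count inferred, not
#' given); (2) learn per-cluster Gaussian moments; (3) for every
#' remaining dangling spot, build its distance-weighted mock cell, map
#' it into model space and call its maximum-likelihood cluster; (4)
#' assign the spot to the nearest cell of that cluster within the
#' distance cap, unless the likelihood margin or distance gate says to
#' stay conservative; (5) apply all accepted assignments synchronously
#' (batch update, in spot-id order) and update the count matrix. The
#' loop stops early when an iteration assigns nothing. Deterministic
#' given the seed.
#'
#' @param spots a [SpotTable-class] (statuses will be recomputed).
#' @param seg a [Segmentation-class] with a label mask.
#' @param params an [AssignParams-class].
#' @param clusterMethod "graph" or "dpmm".
#' @param kNeighbors,resolution graph-clustering knobs.
#' @param dpmm parameters from [dpmmParams()] (dpmm method only).
#' @param lambdaFrac covariance ridge fraction for
#'   [estimateMoments()].
#' @param seed seed for the clusterers (per-iteration seeds are derived
#'   from it).
#' @return list: \code{counts} (final [CellGeneCounts-class]),
#'   \code{clustering} (last iteration's [CellClustering-class]),
#'   \code{records} (assignment provenance data.frame), \code{reports}
#'   (per-iteration data.frame: iteration, nAssigned, fractionOfTotal,
#'   nRemainingDangling, K, wallTime), \code{spots} (final statuses),
#'   \code{initialCounts}, \code{resolved} (the run-time r and D).
#' @export
runSparcle <- function(spots, seg, params = assignParams(),
                       clusterMethod = c("graph", "dpmm"),
                       kNeighbors = 30, resolution = 1.0,
                       dpmm = dpmmParams(), lambdaFrac = 1e-2,
                       seed = 0L) {
  clusterMethod <- match.arg(clusterMethod)
  rp <- .resolveParams(params, seg)
  bm <- buildCountMatrix(spots, seg)
  counts <- bm$counts
  spots <- bm$spots
  initialCounts <- counts
  nTotal <- nrow(spots@spots)
  df <- spots@spots
  grid <- .spotGrid(df$x, df$y, rp$r)
  geneIdx <- match(df$gene, counts@genes)
  records <- .emptyRecords()
  reports <- NULL
  prevLabels <- rep(NA_integer_, length(counts@cellIds))
  clustering <- NULL
  for (it in seq_len(rp$maxIter)) {
    t0 <- proc.time()[["elapsed"]]
    pp <- withCallingHandlers(
      preprocessCounts(counts),
      warning = function(w) invokeRestart("muffleWarning"))
    clustering <- if (clusterMethod == "graph") {
      clusterGraph(pp$X, kNeighbors = kNeighbors,
                   resolution = resolution,
                   seed = seed + it, preprocessing = pp$record)
    } else {
      p <- dpmm; p$seed <- dpmm$seed + seed + it
      clusterDpmm(pp$X, params = p, preprocessing = pp$record)
    }
    moments <- estimateMoments(pp$X, clustering, lambdaFrac = lambdaFrac)
    # label vector over all cells; zero-count cells keep their previous
    # label (they are never re-clustered until they gain counts)
    labels <- rep(NA_integer_, length(counts@cellIds))
    labels[match(clustering@cellIds, counts@cellIds)] <-
      clustering@labels
    labels[is.na(labels)] <- prevLabels[is.na(labels)]
    prevLabels <- labels
    df <- spots@spots
    dang <- which(df$status == "dangling")
    dang <- dang[order(df$spot_id[dang])]
    nAssigned <- 0L
    if (length(dang)) {
      mm <- .mockMatrix(df, dang, counts@genes, rp$r, rp$delta,
                        grid = grid)
      V <- .mockMatrixToModelSpace(mm$W, pp$record)
      ll <- .logdensMatrix(V, moments)
      best <- max.col(ll, ties.method = "first")
      bestLl <- ll[cbind(seq_len(nrow(ll)), best)]
      margin <- if (ncol(ll) == 1L) rep(Inf, nrow(ll)) else {
        second <- vapply(seq_len(nrow(ll)), function(i)
          max(ll[i, -best[i]]), numeric(1))
        bestLl - second
      }
      newCells <- rep(NA_integer_, length(dang))
      for (q in seq_along(dang)) {
        if (margin[q] < rp$margin) next
        newCells[q] <- assignToCell(c(df$x[dang[q]], df$y[dang[q]]),
                                    best[q], counts, labels, rp$D)
      }
      acc <- which(!is.na(newCells))
      if (length(acc)) {
        ci <- match(newCells[acc], counts@cellIds)
        gi <- geneIdx[dang[acc]]
        for (q in seq_along(acc))   # batch: all reads preceded writes
          counts@counts[ci[q], gi[q]] <- counts@counts[ci[q], gi[q]] + 1L
        df$status[dang[acc]] <- "assigned"
        df$cell_id[dang[acc]] <- newCells[acc]
        df$iteration[dang[acc]] <- it
        spots@spots <- df
        records <- rbind(records, data.frame(
          spot_id = df$spot_id[dang[acc]],
          cell_id = newCells[acc],
          cluster_id = best[acc],
          iteration = it,
          loglik = bestLl[acc], stringsAsFactors = FALSE))
        nAssigned <- length(acc)
      }
    }
    nRemaining <- sum(spots@spots$status == "dangling")
    reports <- rbind(reports, data.frame(
      iteration = it, nAssigned = nAssigned,
      fractionOfTotal = nAssigned / nTotal,
      nRemainingDangling = nRemaining, K = clustering@K,
      wallTime = proc.time()[["elapsed"]] - t0))
    if (nAssigned == 0L) break
  }
  list(counts = counts, clustering = clustering, records = records,
       reports = reports, spots = spots,
       initialCounts = initialCounts,
       resolved = list(r = rp$r, maxAssignDist = rp$D))
}
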