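#' @import methods
NULL

.STATUS_LEVELS <- c("inside", "dangling", "assigned")

#' SpotTable: per-transcript records for one field of view
#'
#' One row per detected mRNA spot, with its gene, continuous image
#' coordinates and assignment status. Coordinates are 0-based and
#' continuous; pixel (i, j) covers the half-open unit square
#' [i, i+1) x [j, j+1). The status of a spot is one of \code{"inside"}
#' (fell within a segmented cell), \code{"dangling"} (outside every cell
#' boundary) or \code{"assigned"} (a dangling spot later attached to a
#' cell by the iterative model); dangling spots may only move to
#' assigned, never the reverse.
#'
#' @slot spots data.frame with columns \code{spot_id}, \code{gene},
#'   \code{x}, \code{y}, \code{status}, \code{cell_id}, \code{iteration}.
#' @slot panel ordered character vector of gene symbols; defines the
#'   column order of any count matrix built from the table.
#' @export
setClass("SpotTable", slots = c(spots = "data.frame", panel = "character"))

setValidity("SpotTable", function(object) {
  df <- object@spots
  need <- c("spot_id", "gene", "x", "y", "status", "cell_id", "iteration")
  if (!all(need %in% names(df)))
    return(paste("spots must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$spot_id)) return("spot_id values must be unique")
  if (nrow(df) > 0L) {
    if (!all(df$gene %in% object@panel))
      return("every gene must be in the panel")
    if (!all(df$status %in% .STATUS_LEVELS))
      return("status must be one of inside/dangling/assigned")
    bad <- df$status %in% c("inside", "assigned") & is.na(df$cell_id)
    if (any(bad)) return("inside/assigned spots must carry a cell_id")
  }
  TRUE
})

#' Segmentation: cell boundaries as a label mask or polygons
#'
#' Either an integer label mask (0 = background, k > 0 = cell k; stored
#' as a matrix whose rows index y and columns index x) or a table of
#' closed per-cell polygons. Centroids are the arithmetic mean of member
#' pixel centers (mask) or of polygon vertices.
#'
#' @slot mask integer matrix or NULL.
#' @slot polygons data.frame (cell_id, x, y) or NULL.
#' @slot cellIds integer vector of positive, unique cell labels.
#' @slot centroids numeric matrix (cells x 2, columns x and y), rows
#'   named by cell id.
#' @export
setClass("Segmentation",
         slots = c(mask = "ANY", polygons = "ANY",
                   cellIds = "integer", centroids = "matrix"))

setValidity("Segmentation", function(object) {
  ids <- object@cellIds
  if (length(ids) && (any(ids <= 0L) || anyDuplicated(ids)))
    return("cell ids must be positive and unique")
  if (is.null(object@mask) && is.null(object@polygons))
    return("one of mask or polygons must be present")
  if (nrow(object@centroids) != length(ids))
    return("one centroid per cell required")
  if (!is.null(object@mask) && length(ids)) {
    h <- nrow(object@mask); w <- ncol(object@mask)
    cx <- object@centroids[, 1L]; cy <- object@centroids[, 2L]
    if (any(cx < 0 | cx > w | cy < 0 | cy > h))
      return("centroids must lie inside the image extent")
  }
  TRUE
})

#' CellGeneCounts: the cell-by-gene count matrix
#'
#' Nonnegative integer counts (cells x genes) together with cell
#' centroids. This is the evolving central state of the pipeline: each
#' accepted assignment increments exactly one entry.
#'
#' @slot counts integer matrix, cells x genes; dimnames are cell ids and
#'   gene symbols.
#' @slot cellIds integer vector.
#' @slot genes character vector in SpotTable panel order.
#' @slot centroids cells x 2 numeric matrix (x, y).
#' @export
setClass("CellGeneCounts",
         slots = c(counts = "matrix", cellIds = "integer",
                   genes = "character", centroids = "matrix"))

setValidity("CellGeneCounts", function(object) {
  cm <- object@counts
  if (nrow(cm) != length(object@cellIds)) return("rows must match cellIds")
  if (ncol(cm) != length(object@genes)) return("columns must match genes")
  if (length(cm) && (any(cm < 0) || any(cm != round(cm))))
    return("counts must be nonnegative integers")
  if (nrow(object@centroids) != nrow(cm)) return("one centroid per cell")
  TRUE
})

#' CellClustering: cluster labels for the cells of a count matrix
#'
#' @slot labels integer vector of cluster labels in 1..K (NA for cells
#'   dropped from clustering, e.g. zero-count cells).
#' @slot K number of clusters.
#' @slot method "graph" or "dpmm".
#' @slot preprocessing record of the normalization applied (median
#'   library size, per-gene means/sds), reused to map mock cells into the
#'   same space.
#' @slot cellIds the cells the labels refer to.
#' @export
setClass("CellClustering",
         slots = c(labels = "integer", K = "integer", method = "character",
                   preprocessing = "list", cellIds = "integer"))

setValidity("CellClustering", function(object) {
  lab <- object@labels[!is.na(object@labels)]
  K <- object@K
  if (length(lab)) {
    if (any(lab < 1L | lab > K)) return("labels must lie in 1..K")
    if (!setequal(unique(lab), seq_len(K)))
      return("every label in 1..K must be non-empty")
  }
  if (length(object@labels) != length(object@cellIds))
    return("one label per cell required")
  TRUE
})

#' ClusterMoments: per-cluster Gaussian first and second moments
#'
#' The mean vector and (regularized) covariance matrix of each cluster
#' in preprocessed expression space, defining the multivariate Gaussian
#' likelihood used to classify mock cells. Cholesky factors of the
#' covariances are cached for fast log-density evaluation.
#'
#' @slot means K x G matrix of cluster means.
#' @slot covariances list of K symmetric positive-definite G x G matrices.
#' @slot chols list of K upper-triangular Cholesky factors.
#' @slot n integer member count per cluster.
#' @slot lambda ridge added to each covariance diagonal.
#' @export
setClass("ClusterMoments",
         slots = c(means = "matrix", covariances = "list", chols = "list",
                   n = "integer", lambda = "numeric"))

setValidity("ClusterMoments", function(object) {
  K <- nrow(object@means)
  if (length(object@covariances) != K || length(object@chols) != K ||
      length(object@n) != K)
    return("one covariance/cholesky/count per cluster required")
  if (any(object@n < 1L)) return("every cluster needs at least one member")
  TRUE
})

#' MockCell: distance-weighted pseudo-cell around one dangling spot
#'
#' @slot center length-2 numeric (x, y) of the dangling spot.
#' @slot radius capture radius r.
#' @slot weights length-G nonnegative numeric named by gene; entry g is
#'   the sum over captured neighbors of gene g of 1 / (1 + d / delta).
#' @slot nNeighbors number of spots captured (>= 1: the spot itself).
#' @export
setClass("MockCell",
         slots = c(center = "numeric", radius = "numeric",
                   weights = "numeric", nNeighbors = "integer"))

setValidity("MockCell", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (object@nNeighbors < 1L) return("a mock cell captures at least itself")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  TRUE
})

#' SimConfig: parameters of the synthetic field-of-view generator
#'
#' @slot nCells number of cells placed in the field.
#' @slot nGenes size of the gene panel.
#' @slot nClusters number of expression programs K.
#' @slot clusterProportions simplex vector of cluster frequencies.
#' @slot programConcentration Dirichlet concentration of per-cluster
#'   gene programs (small = sparse, well-separated programs).
#' @slot countsMean,countsDispersion negative-binomial transcript count
#'   per cell (mean and size).
#' @slot cellSigma isotropic Gaussian spread of transcripts around the
#'   cell center, in coordinate units.
#' @slot nucleusRadius radius of the segmented nucleus disk.
#' @slot fieldSize c(width, height).
#' @slot minCellSpacing minimum center-to-center distance.
#' @slot seed RNG seed; the whole FoV is a deterministic function of it.
#' @export
setClass("SimConfig",
         slots = c(nCells = "integer", nGenes = "integer",
                   nClusters = "integer", clusterProportions = "numeric",
                   programConcentration = "numeric", countsMean = "numeric",
                   countsDispersion = "numeric", cellSigma = "numeric",
                   nucleusRadius = "numeric", fieldSize = "integer",
                   minCellSpacing = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (abs(sum(object@clusterProportions) - 1) > 1e-8)
    return("clusterProportions must sum to 1")
  if (length(object@clusterProportions) != object@nClusters)
    return("one proportion per cluster required")
  if (object@nucleusRadius <= 0 || object@cellSigma <= 0)
    return("nucleusRadius and cellSigma must be positive")
  if (object@nClusters > object@nCells)
    return("need at least as many cells as clusters")
  TRUE
})

#' AssignParams: tuning parameters of the assignment engine
#'
#' @slot r mock-cell radius; NA means "2 x median equivalent-disk radius
#'   of the segmented cells", resolved at run time.
#' @slot maxAssignDist cap D on spot-to-centroid distance; NA means 4 r.
#' @slot delta scale of the 1 / (1 + d / delta) neighbor weight, in
#'   coordinate units.
#' @slot minLoglikMargin conservativeness gate: a spot is only assigned
#'   if best minus second-best cluster log-likelihood is at least this.
#' @slot maxIterations fixed iteration budget of the outer loop.
#' @export
setClass("AssignParams",
         slots = c(r = "numeric", maxAssignDist = "numeric",
                   delta = "numeric", minLoglikMargin = "numeric",
                   maxIterations = "integer"))

setValidity("AssignParams", function(object) {
  if (!is.na(object@r) && object@r <= 0) return("r must be positive")
  if (!is.na(object@r) && !is.na(object@maxAssignDist) &&
      object@maxAssignDist < object@r)
    return("maxAssignDist must be >= r")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  TRUE
})

#' ClusterProfileMatrix: per-cluster mean expression on a shared panel
#'
#' @slot profiles K x G numeric matrix (clusters x genes), rows named by
#'   cluster, columns by gene; entries are per-gene z-scores averaged
#'   within cluster.
#' @export
setClass("ClusterProfileMatrix", slots = c(profiles = "matrix"))

setValidity("ClusterProfileMatrix", function(object) {
  if (is.null(colnames(object@profiles)))
    return("profiles must carry gene names")
  TRUE
})
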