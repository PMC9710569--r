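#' @include AllClasses.R
NULL

#' Accessors for sparcler classes
#'
#' Small, read-only views of the S4 containers: spot records, cell ids,
#' gene panel, raw counts, centroids, cluster labels.
#'
#' @param object a sparcler S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spotData", function(object) standardGeneric("spotData"))

#' @rdname accessors
#' @export
setGeneric("genePanel", function(object) standardGeneric("genePanel"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))

#' @rdname accessors
#' @export
setGeneric("cellCentroids", function(object) standardGeneric("cellCentroids"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("spotStatus", function(object) standardGeneric("spotStatus"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))

setMethod("spotData", "SpotTable", function(object) object@spots)
setMethod("genePanel", "SpotTable", function(object) object@panel)
setMethod("spotStatus", "SpotTable", function(object) {
  stats::setNames(object@spots$status, object@spots$spot_id)
})
setMethod("cellIds", "Segmentation", function(object) object@cellIds)
setMethod("cellCentroids", "Segmentation", function(object) object@centroids)
setMethod("cellIds", "CellGeneCounts", function(object) object@cellIds)
setMethod("genePanel", "CellGeneCounts", function(object) object@genes)
setMethod("countsMatrix", "CellGeneCounts", function(object) object@counts)
setMethod("cellCentroids", "CellGeneCounts", function(object) object@centroids)
setMethod("clusterLabels", "CellClustering", function(object) {
  stats::setNames(object@labels, object@cellIds)
})
setMethod("nClusters", "CellClustering", function(object) object@K)
setMethod("profileMatrix", "ClusterProfileMatrix",
          function(object) object@profiles)

setMethod("show", "SpotTable", function(object) {
  s <- table(factor(object@spots$status, levels = .STATUS_LEVELS))
  cat("SpotTable with", nrow(object@spots), "spots,",
      length(object@panel), "genes\n")
  cat("  inside:", s[["inside"]], " dangling:", s[["dangling"]],
      " assigned:", s[["assigned"]], "\n")
})

setMethod("show", "Segmentation", function(object) {
  rep <- if (!is.null(object@mask)) {
    sprintf("label mask %d x %d", nrow(object@mask), ncol(object@mask))
  } else "polygons"
  cat("Segmentation (", rep, ") with ", length(object@cellIds),
      " cells\n", sep = "")
})

setMethod("show", "CellGeneCounts", function(object) {
  cat("CellGeneCounts:", nrow(object@counts), "cells x",
      ncol(object@counts), "genes, total", sum(object@counts),
      "transcripts\n")
})

setMethod("show", "CellClustering", function(object) {
  cat("CellClustering (", object@method, "): ", length(object@labels),
      " cells in ", object@K, " clusters\n", sep = "")
})

setMethod("show", "ClusterMoments", function(object) {
  cat("ClusterMoments:", nrow(object@means), "clusters x",
      ncol(object@means), "genes (lambda =",
      format(object@lambda, digits = 3), ")\n")
})

setMethod("show", "MockCell", function(object) {
  cat("MockCell at (", paste(format(object@center, digits = 4),
      collapse = ", "), "), r = ", object@radius, ", ",
      object@nNeighbors, " neighbors\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCells, "cells,", object@nGenes, "genes,",
      object@nClusters, "clusters, field",
      paste(object@fieldSize, collapse = " x "), "\n")
})

setMethod("show", "AssignParams", function(object) {
  cat("AssignParams: r =", object@r, ", D =", object@maxAssignDist,
      ", delta =", object@delta, ", margin >=", object@minLoglikMargin,
      ",", object@maxIterations, "iterations\n")
})

setMethod("show", "ClusterProfileMatrix", function(object) {
  cat("ClusterProfileMatrix:", nrow(object@profiles), "clusters x",
      ncol(object@profiles), "genes\n")
})
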