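#' @include AllClasses.R
NULL

#' Normalize a cell-by-gene count matrix for clustering
#'
#' Standard single-cell recipe: library-size normalize every cell to the
#' median cell total, then log(1 + x), then z-score each gene across
#' cells. Zero-total cells cannot be normalized and are dropped with a
#' warning (the driver re-attaches them to their previous cluster).
#' The returned record (median total, per-gene means and sds of the
#' log-normalized values) is exactly what [mockToModelSpace()] replays
#' on mock cells, so mock cells and real cells live in the same space.
#'
#' @param counts a [CellGeneCounts-class] or a numeric cells x genes
#'   matrix.
#' @return list: \code{X} (kept-cells x genes z-scored matrix, rownames
#'   = cell ids), \code{record} (list medianTotal, geneMeans, geneSds),
#'   \code{dropped} (cell ids with zero counts).
#' @export
preprocessCounts <- function(counts) {
  cm <- if (methods::is(counts, "CellGeneCounts")) counts@counts else
    as.matrix(counts)
  if (nrow(cm) < 2L) stop("degenerate input: need at least 2 cells")
  if (all(cm == 0)) stop("degenerate input: all-zero count matrix")
  ids <- if (methods::is(counts, "CellGeneCounts")) counts@cellIds else
    seq_len(nrow(cm))
  totals <- rowSums(cm)
  keep <- totals > 0
  if (any(!keep))
    warning(sum(!keep), " zero-count cell(s) dropped from clustering")
  cmk <- cm[keep, , drop = FALSE]
  medTot <- stats::median(totals[keep])
  L <- log1p(cmk * (medTot / totals[keep]))
  mu <- colMeans(L)
  sds <- apply(L, 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  X <- sweep(sweep(L, 2L, mu, "-"), 2L, sds, "/")
  rownames(X) <- ids[keep]
  list(X = X,
       record = list(medianTotal = medTot, geneMeans = mu,
                     geneSds = sds),
       dropped = ids[!keep])
}

.relabelCompact <- function(lab) {
  u <- unique(lab)
  as.integer(match(lab, u))
}

# separation of two labeled groups along their discriminant direction:
# centroid distance over the sum of the projected within-group sds.
# Halves of one Gaussian score ~1.3; Gaussians >= 4 sd apart score >= 2.
.projSeparation <- function(X, lab, a, b) {
  Xa <- X[lab == a, , drop = FALSE]
  Xb <- X[lab == b, , drop = FALSE]
  mua <- colMeans(Xa); mub <- colMeans(Xb)
  v <- mub - mua
  d <- sqrt(sum(v^2))
  if (d == 0) return(0)
  v <- v / d
  sa <- stats::sd(Xa %*% v); sb <- stats::sd(Xb %*% v)
  s <- sum(c(sa, sb), na.rm = TRUE)
  if (s == 0) return(Inf)
  d / s
}

# iteratively merge the least-separated pair of communities until every
# remaining pair is separated by more than `thr` projected spreads;
# undoes the parcellation of single Gaussian clouds that modularity
# optimization produces on kNN graphs
.mergeUnseparated <- function(X, lab, thr) {
  repeat {
    ks <- sort(unique(lab))
    if (length(ks) <= 1L) break
    ratio <- matrix(Inf, length(ks), length(ks))
    for (i in seq_along(ks)[-length(ks)])
      for (j in seq.int(i + 1L, length(ks)))
        ratio[i, j] <- .projSeparation(X, lab, ks[i], ks[j])
    if (min(ratio) >= thr) break
    ij <- which(ratio == min(ratio), arr.ind = TRUE)[1L, ]
    lab[lab == ks[ij[2L]]] <- ks[ij[1L]]
  }
  lab
}

#' Graph-based (Phenograph-style) clustering
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances, weights
#' edges by the Jaccard overlap of the endpoints' neighbor sets, and
#' runs Louvain modularity community detection. Singleton communities
#' are merged into the community with the nearest centroid, and
#' communities that are not separated along their discriminant
#' direction (modularity parcels of a single Gaussian cloud) are merged
#' back. The number of clusters is not specified in advance.
#'
#' @param X preprocessed cells x features matrix (see
#'   [preprocessCounts()]).
#' @param kNeighbors neighbors per cell; shrunk with a warning when the
#'   field has too few cells, and always capped at a quarter of the
#'   cells so minority clusters are not absorbed by the graph.
#' @param resolution Louvain resolution.
#' @param mergeSeparation two communities are kept apart only if their
#'   centroid distance exceeds this many summed projected
#'   within-community sds; 2 corresponds to Gaussian clusters at least
#'   ~4 sd apart.
#' @param seed RNG seed (community detection is seeded, so results are
#'   deterministic).
#' @param preprocessing optional preprocessing record to carry along.
#' @return a [CellClustering-class].
#' @export
clusterGraph <- function(X, kNeighbors = 30, resolution = 1.0, seed = 0L,
                         mergeSeparation = 2.0,
                         preprocessing = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("degenerate input: need at least 3 cells")
  k <- as.integer(kNeighbors)
  if (k > n - 1L) {
    warning("kNeighbors shrunk from ", k, " to ", n - 1L)
    k <- n - 1L
  }
  # small-FoV shrink: a community whose size falls below k is absorbed
  # by the denser graph (most of its edges point outward), so cap k at
  # a quarter of the cells
  k <- min(k, max(3L, n %/% 4L))
  D <- as.matrix(stats::dist(X))
  nbr <- lapply(seq_len(n), function(i) {
    d <- D[i, ]; d[i] <- Inf
    order(d)[seq_len(k)]
  })
  ei <- rep(seq_len(n), each = k)
  ej <- unlist(nbr)
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  key <- paste(lo, hi)
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  w <- vapply(seq_along(lo), function(e) {
    a <- nbr[[lo[e]]]; b <- nbr[[hi[e]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- w > 0
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(lo[keep], hi[keep]))
  igraph::E(g)$weight <- w[keep]
  lab <- withr::with_seed(as.integer(seed), {
    igraph::membership(igraph::cluster_louvain(
      g, weights = igraph::E(g)$weight, resolution = resolution))
  })
  lab <- as.integer(lab)
  # merge singleton communities into the nearest community by centroid
  repeat {
    sizes <- table(lab)
    singles <- as.integer(names(sizes)[sizes == 1L])
    if (!length(singles) || length(sizes) == 1L) break
    s <- singles[1L]
    i <- which(lab == s)
    cents <- vapply(setdiff(unique(lab), s), function(cl) {
      sum((colMeans(X[lab == cl, , drop = FALSE]) - X[i, ])^2)
    }, numeric(1))
    lab[i] <- setdiff(unique(lab), s)[which.min(cents)]
  }
  lab <- .mergeUnseparated(X, lab, thr = mergeSeparation)
  lab <- .relabelCompact(lab)
  methods::new("CellClustering", labels = lab,
               K = max(lab), method = "graph",
               preprocessing = preprocessing,
               cellIds = if (is.null(rownames(X))) seq_len(n) else
                 as.integer(rownames(X)))
}

# exact assignment solver (maximize total weight) by bitmask DP over the
# smaller dimension; exact for K up to ~20, which covers FoV-scale runs
.hungarianMax <- function(W) {
  n1 <- nrow(W); n2 <- ncol(W)
  transposed <- FALSE
  if (n1 > n2) { W <- t(W); tmp <- n1; n1 <- n2; n2 <- tmp
                 transposed <- TRUE }
  if (n2 > 20L) stop("assignment problem too large for exact solver")
  nS <- bitwShiftL(1L, n2)
  f <- matrix(-Inf, n1 + 1L, nS)
  f[1L, 1L] <- 0
  choice <- matrix(NA_integer_, n1 + 1L, nS)
  for (i in seq_len(n1)) {
    for (S in which(f[i, ] > -Inf) - 1L) {
      for (j in seq_len(n2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(S, bit) == 0L) {
          v <- f[i, S + 1L] + W[i, j]
          if (v > f[i + 1L, bitwOr(S, bit) + 1L]) {
            f[i + 1L, bitwOr(S, bit) + 1L] <- v
            choice[i + 1L, bitwOr(S, bit) + 1L] <- j
          }
        }
      }
    }
  }
  best <- which.max(f[n1 + 1L, ])
  S <- best - 1L
  assign <- integer(n1)
  for (i in rev(seq_len(n1))) {
    j <- choice[i + 1L, S + 1L]
    assign[i] <- j
    S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  if (transposed) {
    out <- rep(NA_integer_, ncol(W))
    out[assign] <- seq_len(nrow(W))
    out
  } else assign
}

#' Match two clusterings of the same cells
#'
#' Builds the contingency table, solves the optimal one-to-one cluster
#' correspondence (maximum total overlap), and reports the adjusted Rand
#' index.
#'
#' @param labelsA,labelsB integer label vectors over the same cells; if
#'   named, names must agree (order-insensitive).
#' @return list: \code{mapping} (labelsA cluster -> labelsB cluster, NA
#'   where A has more clusters than B), \code{agreement} (fraction of
#'   cells on the matched diagonal), \code{ari}.
#' @export
matchClusters <- function(labelsA, labelsB) {
  if (!is.null(names(labelsA)) && !is.null(names(labelsB))) {
    if (!setequal(names(labelsA), names(labelsB)))
      stop("consistency error: clusterings cover different cell sets")
    labelsB <- labelsB[names(labelsA)]
  } else if (length(labelsA) != length(labelsB)) {
    stop("consistency error: clusterings cover different cell sets")
  }
  a <- as.integer(factor(labelsA)); b <- as.integer(factor(labelsB))
  tab <- table(a, b)
  W <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  assign <- .hungarianMax(W)
  la <- sort(unique(labelsA)); lb <- sort(unique(labelsB))
  if (nrow(W) <= ncol(W)) {
    mapping <- stats::setNames(lb[assign], la)
    agree <- sum(W[cbind(seq_len(nrow(W)), assign)])
  } else {
    mapping <- stats::setNames(lb[assign], la)
    matched <- which(!is.na(assign))
    agree <- sum(W[cbind(matched, assign[matched])])
  }
  list(mapping = mapping, agreement = agree / length(a),
       ari = mclust::adjustedRandIndex(labelsA, labelsB))
}
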