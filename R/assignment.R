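#' @include AllClasses.R clustering.R
NULL

#' Construct assignment-engine parameters
#'
#' @param r mock-cell capture radius; NA (default) resolves at run time
#'   to twice the median equivalent-disk radius of the segmented cells,
#'   which keeps the default unit-free.
#' @param maxAssignDist cap on the spot-to-centroid distance of an
#'   accepted assignment; NA resolves to 4 r.
#' @param delta scale of the neighbor weight w(d) = 1 / (1 + d / delta),
#'   in coordinate units; the dangling spot itself (d = 0) always
#'   contributes weight 1.
#' @param minLoglikMargin conservativeness gate: minimum lead of the
#'   best cluster log-likelihood over the runner-up; 0 disables it.
#' @param maxIterations outer-loop budget.
#' @return an [AssignParams-class].
#' @export
assignParams <- function(r = NA_real_, maxAssignDist = NA_real_,
                         delta = 1.0, minLoglikMargin = 0.0,
                         maxIterations = 3L) {
  methods::new("AssignParams", r = as.numeric(r),
               maxAssignDist = as.numeric(maxAssignDist),
               delta = delta, minLoglikMargin = minLoglikMargin,
               maxIterations = as.integer(maxIterations))
}

#' Estimate per-cluster Gaussian moments
#'
#' First- and second-order moments (mean and covariance) of every
#' cluster of the preprocessed expression matrix. Covariances use the
#' n-1 denominator; clusters with a single member fall back to the
#' pooled within-cluster covariance. Every covariance is ridge-
#' regularized by lambda = lambdaFrac x mean pooled variance, which
#' guarantees positive definiteness, and the Cholesky factor is cached.
#'
#' @param X preprocessed cells x genes matrix, rows aligned with
#'   \code{clustering}.
#' @param clustering a [CellClustering-class] over the rows of X.
#' @param lambdaFrac ridge fraction.
#' @return a [ClusterMoments-class].
#' @export
estimateMoments <- function(X, clustering, lambdaFrac = 1e-2) {
  X <- as.matrix(X)
  lab <- clustering@labels
  if (length(lab) != nrow(X))
    stop("clustering and matrix cover different cells")
  keep <- !is.na(lab)
  X <- X[keep, , drop = FALSE]; lab <- lab[keep]
  K <- clustering@K
  G <- ncol(X)
  counts <- tabulate(lab, K)
  if (any(counts == 0L))
    stop("consistency error: cluster with 0 members")
  means <- matrix(0, K, G, dimnames = list(seq_len(K), colnames(X)))
  covs <- vector("list", K)
  pooled <- matrix(0, G, G); pooledDf <- 0L
  for (k in seq_len(K)) {
    Xk <- X[lab == k, , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    if (nrow(Xk) >= 2L) {
      covs[[k]] <- stats::cov(Xk)
      pooled <- pooled + (nrow(Xk) - 1L) * covs[[k]]
      pooledDf <- pooledDf + nrow(Xk) - 1L
    }
  }
  pooled <- if (pooledDf > 0L) pooled / pooledDf else
    diag(apply(X, 2L, stats::var), G)
  lambda <- lambdaFrac * mean(diag(pooled))
  if (!is.finite(lambda) || lambda <= 0) lambda <- lambdaFrac
  chols <- vector("list", K)
  for (k in seq_len(K)) {
    S <- if (is.null(covs[[k]])) pooled else covs[[k]]
    S <- S + diag(lambda, G)
    covs[[k]] <- (S + t(S)) / 2
    chols[[k]] <- chol(covs[[k]])
  }
  methods::new("ClusterMoments", means = means, covariances = covs,
               chols = chols, n = as.integer(counts), lambda = lambda)
}

# uniform-bin spatial index over spot coordinates; query returns every
# spot within Euclidean distance r, identical to an exhaustive scan
.spotGrid <- function(x, y, r) {
  keys <- paste(floor(x / r), floor(y / r))
  list(bins = split(seq_along(x), keys), x = x, y = y, r = r)
}

.gridQuery <- function(grid, x0, y0) {
  bx <- floor(x0 / grid$r); by <- floor(y0 / grid$r)
  keys <- as.vector(outer((bx - 1):(bx + 1), (by - 1):(by + 1), paste))
  cand <- unlist(grid$bins[keys], use.names = FALSE)
  if (is.null(cand)) return(integer(0))
  d2 <- (grid$x[cand] - x0)^2 + (grid$y[cand] - y0)^2
  cand[d2 <= grid$r^2]
}

#' Build the mock cell around a dangling spot
#'
#' Captures every spot (inside, assigned or still dangling) within
#' Euclidean distance r of the dangling spot — including the spot
#' itself at d = 0 — and accumulates per-gene weights
#' w(d) = 1 / (1 + d / delta), so nearby transcripts dominate the
#' pseudo-expression vector the way peri-nuclear transcripts dominate a
#' real cell.
#'
#' @param spotId id of a dangling spot in \code{spots}.
#' @param spots the [SpotTable-class].
#' @param r capture radius (> 0).
#' @param delta weight scale.
#' @return a [MockCell-class].
#' @export
buildMockCell <- function(spotId, spots, r, delta = 1.0) {
  if (r <= 0) stop("parameter error: r must be positive")
  df <- spots@spots
  i <- match(spotId, df$spot_id)
  if (is.na(i)) stop("unknown spot ", spotId)
  if (df$status[i] != "dangling")
    stop("mock cells are built around dangling spots only")
  d2 <- (df$x - df$x[i])^2 + (df$y - df$y[i])^2
  nb <- which(d2 <= r^2)
  w <- 1 / (1 + sqrt(d2[nb]) / delta)
  gi <- match(df$gene[nb], spots@panel)
  wv <- numeric(length(spots@panel))
  for (j in seq_along(nb)) wv[gi[j]] <- wv[gi[j]] + w[j]
  names(wv) <- spots@panel
  methods::new("MockCell", center = c(df$x[i], df$y[i]), radius = r,
               weights = wv, nNeighbors = length(nb))
}

# batched mock-cell construction for the driver: one row per requested
# spot, grid-accelerated, equal to buildMockCell row by row
.mockMatrix <- function(df, idx, panel, r, delta, grid = NULL) {
  if (is.null(grid)) grid <- .spotGrid(df$x, df$y, r)
  G <- length(panel)
  gi <- match(df$gene, panel)
  W <- matrix(0, length(idx), G, dimnames = list(df$spot_id[idx], panel))
  nnb <- integer(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    nb <- .gridQuery(grid, df$x[i], df$y[i])
    d <- sqrt((df$x[nb] - df$x[i])^2 + (df$y[nb] - df$y[i])^2)
    w <- 1 / (1 + d / delta)
    a <- rowsum(w, gi[nb])
    W[q, as.integer(rownames(a))] <- a[, 1L]
    nnb[q] <- length(nb)
  }
  list(W = W, nNeighbors = nnb, grid = grid)
}

#' Map a mock cell into the clustered model space
#'
#' Rescales the weighted gene vector to the median raw total of the
#' segmented cells, then replays the identical log1p + per-gene z-score
#' transform (with the training means and sds) that produced the
#' clustered matrix, so mock cells and real cells are directly
#' comparable. Scalar multiples of a weight vector map to the same
#' point.
#'
#' @param mock a [MockCell-class] or a nonnegative weight vector.
#' @param preprocessing the record from [preprocessCounts()].
#' @return length-G numeric vector in model space.
#' @export
mockToModelSpace <- function(mock, preprocessing) {
  v <- if (methods::is(mock, "MockCell")) mock@weights else
    as.numeric(mock)
  if (sum(v) <= 0) stop("degenerate input: zero mock-cell vector")
  t <- log1p(v * (preprocessing$medianTotal / sum(v)))
  (t - preprocessing$geneMeans) / preprocessing$geneSds
}

.mockMatrixToModelSpace <- function(W, preprocessing) {
  tot <- rowSums(W)
  L <- log1p(W * (preprocessing$medianTotal / tot))
  sweep(sweep(L, 2L, preprocessing$geneMeans, "-"),
        2L, preprocessing$geneSds, "/")
}

.logdensMatrix <- function(V, moments) {
  K <- nrow(moments@means)
  G <- ncol(moments@means)
  out <- matrix(NA_real_, nrow(V), K)
  for (k in seq_len(K)) {
    R <- moments@chols[[k]]
    Z <- backsolve(R, t(V) - moments@means[k, ], transpose = TRUE)
    out[, k] <- -(G / 2) * log(2 * pi) - sum(log(diag(R))) -
      0.5 * colSums(Z^2)
  }
  out
}

#' Maximum-likelihood cluster call for one expression vector
#'
#' Evaluates the multivariate Gaussian log-density of \code{v} under
#' every cluster's moments — pure likelihood, no mixing-proportion
#' prior — and returns the argmax. Ties break to the lower cluster id.
#'
#' @param v length-G numeric vector in model space.
#' @param moments a [ClusterMoments-class].
#' @return list: \code{cluster}, \code{loglik}, \code{margin} (best
#'   minus second best; +Inf when there is a single cluster).
#' @export
mleCluster <- function(v, moments) {
  if (length(v) != ncol(moments@means))
    stop("validation error: dimension mismatch")
  ll <- .logdensMatrix(matrix(v, 1L), moments)[1L, ]
  k <- which.max(ll)
  margin <- if (length(ll) == 1L) Inf else
    ll[k] - max(ll[-k])
  list(cluster = as.integer(k), loglik = ll[k], margin = margin)
}

#' Nearest cell of a given cluster within the distance cap
#'
#' Among cells carrying the called cluster label whose centroid lies
#' within \code{D} of the spot, returns the one with minimal centroid
#' distance (ties to the lower cell id); \code{NA} when no such cell
#' exists — absence is a valid, conservative outcome.
#'
#' @param spotXY length-2 numeric (x, y).
#' @param clusterId called cluster.
#' @param counts a [CellGeneCounts-class] (for centroids and cell ids).
#' @param labels integer cluster label per cell of \code{counts} (NA =
#'   unclustered, never a candidate).
#' @param D distance cap.
#' @return cell id (integer) or NA.
#' @export
assignToCell <- function(spotXY, clusterId, counts, labels, D) {
  cand <- which(!is.na(labels) & labels == clusterId)
  if (!length(cand)) return(NA_integer_)
  d2 <- (counts@centroids[cand, 1L] - spotXY[1L])^2 +
    (counts@centroids[cand, 2L] - spotXY[2L])^2
  ok <- d2 <= D^2
  if (!any(ok)) return(NA_integer_)
  cand <- cand[ok]; d2 <- d2[ok]
  ids <- counts@cellIds[cand]
  ids[order(d2, ids)][1L]
}

#' Apply one accepted assignment
#'
#' Increments exactly one count-matrix entry, flips the spot's status
#' from dangling to assigned, and emits the provenance record. A spot
#' can only ever be assigned once.
#'
#' @param spotId dangling spot id.
#' @param cellId receiving cell.
#' @param clusterId called cluster.
#' @param counts a [CellGeneCounts-class].
#' @param spots the [SpotTable-class].
#' @param iteration current iteration (recorded on spot and record).
#' @param loglik log-likelihood of the call.
#' @return list: updated \code{counts}, \code{spots}, one-row
#'   \code{record} data.frame.
#' @export
applyAssignment <- function(spotId, cellId, clusterId, counts, spots,
                            iteration, loglik) {
  df <- spots@spots
  i <- match(spotId, df$spot_id)
  if (is.na(i)) stop("unknown spot ", spotId)
  if (df$status[i] != "dangling")
    stop("consistency error: spot ", spotId, " already assigned")
  ci <- match(cellId, counts@cellIds)
  if (is.na(ci)) stop("unknown cell ", cellId)
  gi <- match(df$gene[i], counts@genes)
  counts@counts[ci, gi] <- counts@counts[ci, gi] + 1L
  df$status[i] <- "assigned"
  df$cell_id[i] <- cellId
  df$iteration[i] <- iteration
  spots@spots <- df
  record <- data.frame(spot_id = spotId, cell_id = cellId,
                       cluster_id = clusterId,
                       iteration = as.integer(iteration),
                       loglik = loglik, stringsAsFactors = FALSE)
  list(counts = counts, spots = spots, record = record)
}
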