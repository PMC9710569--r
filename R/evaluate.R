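#' @include AllClasses.R clustering.R
NULL

.zscoreCols <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  sweep(sweep(X, 2L, mu, "-"), 2L, sds, "/")
}

#' Per-cluster mean expression profiles
#'
#' Z-scores every gene across cells, then averages within cluster,
#' yielding the K x G cluster-profile matrix used by all downstream
#' covariance comparisons.
#'
#' @param counts a [CellGeneCounts-class] or a cells x genes numeric
#'   matrix (with gene column names).
#' @param labels a [CellClustering-class] or an integer label vector
#'   over the rows (NA rows are ignored).
#' @param sharedGenes optional gene subset (must exist in the panel);
#'   profiles are restricted to it, in the given order.
#' @return a [ClusterProfileMatrix-class].
#' @export
clusterProfiles <- function(counts, labels, sharedGenes = NULL) {
  X <- if (methods::is(counts, "CellGeneCounts")) counts@counts else
    as.matrix(counts)
  if (methods::is(labels, "CellClustering")) {
    cl <- labels
    if (methods::is(counts, "CellGeneCounts")) {
      lab <- rep(NA_integer_, nrow(X))
      lab[match(cl@cellIds, counts@cellIds)] <- cl@labels
    } else lab <- cl@labels
  } else lab <- as.integer(labels)
  if (length(lab) != nrow(X)) stop("one label per cell required")
  if (!is.null(sharedGenes)) {
    miss <- setdiff(sharedGenes, colnames(X))
    if (length(miss))
      stop("genes absent from panel: ", paste(miss, collapse = ", "))
    X <- X[, sharedGenes, drop = FALSE]
  }
  keep <- !is.na(lab)
  X <- X[keep, , drop = FALSE]; lab <- lab[keep]
  ks <- sort(unique(lab))
  Z <- .zscoreCols(X)
  P <- t(vapply(ks, function(k) colMeans(Z[lab == k, , drop = FALSE]),
                numeric(ncol(Z))))
  dimnames(P) <- list(ks, colnames(X))
  methods::new("ClusterProfileMatrix", profiles = P)
}

.asProfiles <- function(P) {
  if (methods::is(P, "ClusterProfileMatrix")) P@profiles else
    as.matrix(P)
}

#' Gramian (cluster-cluster) covariance of cluster profiles
#'
#' The K x K covariance across genes of the K cluster-profile rows:
#' (P - rowmeans)(P - rowmeans)' / (G - 1). Symmetric positive
#' semidefinite by construction; comparing these between modalities
#' asks whether cell types covary the same way.
#'
#' @param P a [ClusterProfileMatrix-class] or K x G matrix.
#' @return K x K numeric matrix.
#' @export
gramianCovariance <- function(P) {
  P <- .asProfiles(P)
  if (nrow(P) < 1L) stop("validation error: need at least one cluster")
  if (ncol(P) < 2L) stop("need at least 2 genes")
  C <- P - rowMeans(P)
  tcrossprod(C) / (ncol(P) - 1L)
}

#' Cross-covariance between two sets of cluster profiles
#'
#' Entry (i, j) is the covariance across genes of row i of \code{Pa}
#' and row j of \code{Pb}; a dominant diagonal means matched cell types
#' agree across modalities.
#'
#' @param Pa,Pb profile matrices on the identical ordered gene panel.
#' @return Ka x Kb numeric matrix.
#' @export
crossCovariance <- function(Pa, Pb) {
  Pa <- .asProfiles(Pa); Pb <- .asProfiles(Pb)
  if (ncol(Pa) != ncol(Pb) ||
      !identical(colnames(Pa), colnames(Pb)))
    stop("validation error: gene order mismatch")
  Ca <- Pa - rowMeans(Pa)
  Cb <- Pb - rowMeans(Pb)
  tcrossprod(Ca, Cb) / (ncol(Pa) - 1L)
}

#' Diagonal dominance of a square matrix
#'
#' mean(|diagonal|) - mean(|off-diagonal|); larger values mean the
#' within-cluster entries dominate the between-cluster ones.
#'
#' @param M square matrix with at least 2 rows.
#' @return numeric score.
#' @export
diagonalDominanceScore <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("validation error: matrix not square")
  if (nrow(M) < 2L)
    stop("off-diagonal undefined for a 1 x 1 matrix")
  d <- abs(diag(M))
  off <- abs(M[row(M) != col(M)])
  mean(d) - mean(off)
}

#' Frobenius distance between two matrices
#'
#' @param A,B matrices of identical shape.
#' @return sqrt(sum((A - B)^2)).
#' @export
frobeniusDistance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop("validation error: shape mismatch")
  sqrt(sum((A - B)^2))
}

#' Box's M test for homogeneity of covariance matrices
#'
#' Classical chi-square approximation: M = (N - g) ln|S_pooled| -
#' sum (n_i - 1) ln|S_i|, scaled by Box's correction factor, with
#' df = p(p+1)(g-1)/2. Large p-values indicate the group covariances
#' are compatible. Groups too small to estimate a full-rank covariance
#' (n_i <= p) are shrunk toward the pooled covariance with a warning.
#'
#' @param groups list of >= 2 numeric matrices (n_i x p, same p).
#' @return list: \code{M}, \code{chi2}, \code{df}, \code{p}.
#' @export
boxMTest <- function(groups) {
  g <- length(groups)
  if (g < 2L) stop("need at least 2 groups")
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1L]])
  if (any(vapply(groups, ncol, integer(1)) != p))
    stop("validation error: groups must share dimension")
  ns <- vapply(groups, nrow, integer(1))
  N <- sum(ns)
  covs <- lapply(groups, stats::cov)
  pool <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) /
    (N - g)
  small <- ns <= p
  if (any(small)) {
    warning(sum(small), " group(s) with n <= p; covariances shrunk ",
            "toward the pooled estimate")
    for (i in which(small)) {
      w <- p / (ns[i] - 1 + p)
      covs[[i]] <- (1 - w) * covs[[i]] + w * pool
    }
    pool <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) /
      (N - g)
  }
  logdets <- vapply(seq_len(g), function(i) {
    ld <- determinant(covs[[i]], logarithm = TRUE)
    if (ld$sign <= 0)
      stop("numerical error: singular covariance in group ", i)
    as.numeric(ld$modulus)
  }, numeric(1))
  ldPool <- determinant(pool, logarithm = TRUE)
  if (ldPool$sign <= 0) stop("numerical error: singular pooled covariance")
  M <- (N - g) * as.numeric(ldPool$modulus) -
    sum((ns - 1) * logdets)
  c1 <- (sum(1 / (ns - 1)) - 1 / (N - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  chi2 <- M * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  list(M = M, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Loewner (positive-semidefinite) ordering of two symmetric matrices
#'
#' A is above B in the Loewner order iff A - B is positive
#' semidefinite. Both directions are checked by eigenvalue, so the
#' result distinguishes equality, strict one-sided dominance, and
#' incomparability.
#'
#' @param A,B symmetric matrices of identical shape.
#' @param tol eigenvalue tolerance.
#' @return one of "equal", "A>=B", "B>=A", "incomparable".
#' @export
loewnerOrder <- function(A, B, tol = 1e-8) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop("validation error: shape mismatch")
  if (max(abs(A - t(A))) > tol || max(abs(B - t(B))) > tol)
    stop("validation error: inputs must be symmetric")
  ev <- eigen((A - B + t(A - B)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  aGeq <- min(ev) >= -tol
  bGeq <- max(ev) <= tol
  if (aGeq && bGeq) "equal"
  else if (aGeq) "A>=B"
  else if (bGeq) "B>=A"
  else "incomparable"
}

#' Pearson block-correlation matrix between two cell sets
#'
#' Samples (without replacement, seeded) the same number of cells per
#' type from each source, stacks them type by type, and computes the
#' full cells-of-A x cells-of-B Pearson correlation matrix over the
#' shared gene panel. Block structure on the diagonal indicates that
#' matched types correlate across sources.
#'
#' @param cellsA,cellsB cells x genes matrices (gene column names
#'   required).
#' @param typesA,typesB per-cell type labels.
#' @param nPerType cells sampled per type (types smaller than this are
#'   used whole, with a warning).
#' @param seed sampling seed.
#' @return correlation matrix with row/column names "type:index";
#'   attributes \code{rowType}/\code{colType} give the block labels.
#' @export
pearsonBlockMatrix <- function(cellsA, typesA, cellsB, typesB,
                               nPerType = 100L, seed = 0L) {
  shared <- intersect(colnames(cellsA), colnames(cellsB))
  if (length(shared) < 2L) stop("need a shared gene panel")
  sampleBlocks <- function(X, types) {
    out <- NULL; lab <- character(0)
    for (ty in sort(unique(types))) {
      idx <- which(types == ty)
      if (length(idx) < nPerType)
        warning("type ", ty, " has only ", length(idx),
                " cells; using all")
      take <- if (length(idx) <= nPerType) idx else
        sample(idx, nPerType)
      out <- rbind(out, X[take, shared, drop = FALSE])
      lab <- c(lab, rep(as.character(ty), length(take)))
    }
    rownames(out) <- paste0(lab, ":", seq_along(lab))
    list(X = out, lab = lab)
  }
  withr::with_seed(as.integer(seed), {
    a <- sampleBlocks(as.matrix(cellsA), typesA)
    b <- sampleBlocks(as.matrix(cellsB), typesB)
    R <- stats::cor(t(a$X), t(b$X))
    attr(R, "rowType") <- a$lab
    attr(R, "colType") <- b$lab
    R
  })
}

# match run profiles to reference profiles by maximum total correlation
.matchProfilesToReference <- function(P, ref) {
  W <- stats::cor(t(P), t(ref))
  W[!is.finite(W)] <- 0
  assign <- .hungarianMax(W)      # P-row -> ref-row, NA when K_P > K_ref
  out <- matrix(NA_real_, nrow(ref), ncol(ref),
                dimnames = dimnames(ref))
  for (i in seq_len(nrow(P)))
    if (!is.na(assign[i])) out[assign[i], ] <- P[i, ]
  out
}

#' Compare pre- and post-assignment runs against a reference
#'
#' Matches each run's cluster profiles to the reference profiles
#' (maximum-correlation one-to-one matching), then reports, per run:
#' Frobenius distance of matched profiles to the reference, Frobenius
#' distance between Gramian matrices, Box's M p-value comparing the
#' run's and the reference's profile covariance (genes as
#' observations, clusters as variables), and the diagonal dominance of
#' the run-vs-reference cross-covariance. Unmatched reference clusters
#' appear as NA profile rows and are excluded from the statistics.
#'
#' @param pre,post lists with elements \code{counts}
#'   ([CellGeneCounts-class]) and \code{clustering}
#'   ([CellClustering-class]).
#' @param reference a [ClusterProfileMatrix-class] of ground-truth (or
#'   scRNA-seq) cluster profiles.
#' @param outCsv optional path; the report is written as CSV.
#' @return data.frame with one row per run (pre, post).
#' @export
compareRuns <- function(pre, post, reference, outCsv = NULL) {
  ref <- .asProfiles(reference)
  runGenes <- function(run)
    if (methods::is(run$counts, "CellGeneCounts")) run$counts@genes else
      colnames(run$counts)
  shared <- Reduce(intersect, list(colnames(ref), runGenes(pre),
                                   runGenes(post)))
  if (length(shared) < 2L)
    stop("validation error: fewer than 2 shared genes")
  ref <- ref[, shared, drop = FALSE]
  evalRun <- function(run) {
    P <- .asProfiles(clusterProfiles(run$counts, run$clustering,
                                     sharedGenes = shared))
    M <- .matchProfilesToReference(P, ref)
    ok <- stats::complete.cases(M)
    Mok <- M[ok, , drop = FALSE]; refok <- ref[ok, , drop = FALSE]
    # z-scored profiles obey a size-weighted zero-sum constraint across
    # clusters, so the full K x K covariance is rank K-1: run Box's M
    # on the first K-1 cluster coordinates
    boxp <- if (sum(ok) >= 3L)
      boxMTest(list(t(refok)[, -sum(ok), drop = FALSE],
                    t(Mok)[, -sum(ok), drop = FALSE]))$p else NA_real_
    dd <- if (sum(ok) >= 2L)
      diagonalDominanceScore(crossCovariance(Mok, refok)) else NA_real_
    data.frame(
      K = nrow(P), nMatched = sum(ok),
      frobeniusProfiles = frobeniusDistance(Mok, refok),
      frobeniusGramian = frobeniusDistance(gramianCovariance(Mok),
                                           gramianCovariance(refok)),
      boxMP = boxp, diagDominance = dd)
  }
  out <- rbind(cbind(run = "pre", evalRun(pre)),
               cbind(run = "post", evalRun(post)))
  if (!is.null(outCsv)) utils::write.csv(out, outCsv, row.names = FALSE)
  out
}
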