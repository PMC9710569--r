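#' @include AllClasses.R clustering.R
NULL

#' Dirichlet process mixture model parameters
#'
#' Conjugate Normal-Inverse-Wishart component priors: m0 = data mean,
#' small k0 (diffuse mean), nu0 = d + 2 (weakest proper), S0 = diagonal
#' of the empirical per-feature variances.
#'
#' @param alpha DP concentration.
#' @param k0 prior pseudo-count on the mean.
#' @param nu0 Inverse-Wishart degrees of freedom; NULL resolves to d + 2
#'   at fit time.
#' @param nSweeps Gibbs sweeps.
#' @param seed RNG seed.
#' @param maxPcs reduce to this many principal components when the
#'   feature dimension exceeds it (keeps NIW posteriors
#'   well-conditioned).
#' @return a parameter list for [clusterDpmm()].
#' @export
dpmmParams <- function(alpha = 1.0, k0 = 0.01, nu0 = NULL,
                       nSweeps = 200L, seed = 0L, maxPcs = 50L) {
  stopifnot(alpha > 0, k0 > 0, nSweeps >= 1)
  list(alpha = alpha, k0 = k0, nu0 = nu0,
       nSweeps = as.integer(nSweeps), seed = as.integer(seed),
       maxPcs = as.integer(maxPcs))
}

.lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) +
    sum(lgamma(a + (1 - seq_len(d)) / 2))
}

# posterior NIW hyperparameters from sufficient stats (n, s = column sum,
# SS = sum of outer products)
.niwPosterior <- function(pr, n, s, SS) {
  kn <- pr$k0 + n
  nun <- pr$nu0 + n
  mn <- (pr$k0 * pr$m0 + s) / kn
  Sn <- pr$S0 + SS + pr$k0 * tcrossprod(pr$m0) - kn * tcrossprod(mn)
  Sn <- (Sn + t(Sn)) / 2
  list(kn = kn, nun = nun, mn = mn, Sn = Sn)
}

# log posterior-predictive density: multivariate Student-t
.tPredictiveCache <- function(pr, n, s, SS) {
  d <- length(pr$m0)
  po <- .niwPosterior(pr, n, s, SS)
  df <- po$nun - d + 1
  scale <- po$Sn * (po$kn + 1) / (po$kn * df)
  R <- chol(scale)
  list(df = df, m = po$mn, R = R,
       logdet = 2 * sum(log(diag(R))),
       const = lgamma((df + d) / 2) - lgamma(df / 2) -
         (d / 2) * log(df * pi))
}

.tPredictiveLogd <- function(cache, x) {
  z <- backsolve(cache$R, x - cache$m, transpose = TRUE)
  maha <- sum(z^2)
  d <- length(x)
  cache$const - 0.5 * cache$logdet -
    ((cache$df + d) / 2) * log1p(maha / cache$df)
}

# log marginal likelihood of one cluster's data under the NIW prior
.clusterLogMl <- function(pr, n, s, SS) {
  if (n == 0L) return(0)
  d <- length(pr$m0)
  po <- .niwPosterior(pr, n, s, SS)
  -(n * d / 2) * log(pi) +
    .lmvgamma(po$nun / 2, d) - .lmvgamma(pr$nu0 / 2, d) +
    (pr$nu0 / 2) * pr$logdetS0 - (po$nun / 2) *
      as.numeric(determinant(po$Sn, logarithm = TRUE)$modulus) +
    (d / 2) * (log(pr$k0) - log(po$kn))
}

.jointLogPosterior <- function(pr, alpha, clusters, n) {
  K <- length(clusters)
  crp <- K * log(alpha) + lgamma(alpha) - lgamma(alpha + n) +
    sum(vapply(clusters, function(cl) lgamma(cl$n), numeric(1)))
  crp + sum(vapply(clusters,
                   function(cl) .clusterLogMl(pr, cl$n, cl$s, cl$SS),
                   numeric(1)))
}

#' Dirichlet process mixture model clustering (collapsed Gibbs)
#'
#' Fits an infinite Gaussian mixture with conjugate
#' Normal-Inverse-Wishart components by collapsed Gibbs sampling over
#' cluster assignments, so the number of clusters is inferred rather
#' than specified. Labels are taken from the maximum-a-posteriori sweep
#' (highest joint CRP + marginal-likelihood score); empty components are
#' pruned. When the feature dimension exceeds \code{maxPcs}, the data
#' are first projected onto the leading principal components.
#'
#' @param X preprocessed cells x features matrix.
#' @param params from [dpmmParams()].
#' @param preprocessing optional preprocessing record to carry along.
#' @return a [CellClustering-class].
#' @export
clusterDpmm <- function(X, params = dpmmParams(),
                        preprocessing = list()) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("validation error: non-finite values")
  n <- nrow(X)
  if (n < 3L) stop("degenerate input: need at least 3 cells")
  ids <- rownames(X)
  if (ncol(X) > params$maxPcs) {
    r <- min(params$maxPcs, n - 1L)
    X <- stats::prcomp(X, rank. = r, center = TRUE, scale. = FALSE)$x
  }
  d <- ncol(X)
  nu0 <- if (is.null(params$nu0)) d + 2 else params$nu0
  if (nu0 <= d + 1) stop("nu0 must exceed d + 1")
  v0 <- apply(X, 2L, stats::var)
  v0[v0 <= 0] <- 1e-6
  pr <- list(m0 = colMeans(X), k0 = params$k0, nu0 = nu0,
             S0 = diag(v0, d),
             logdetS0 = sum(log(v0)))
  newCluster <- function() list(n = 0L, s = numeric(d),
                                SS = matrix(0, d, d), cache = NULL)
  addTo <- function(cl, x) {
    cl$n <- cl$n + 1L; cl$s <- cl$s + x; cl$SS <- cl$SS + tcrossprod(x)
    cl$cache <- NULL; cl
  }
  removeFrom <- function(cl, x) {
    cl$n <- cl$n - 1L; cl$s <- cl$s - x; cl$SS <- cl$SS - tcrossprod(x)
    cl$cache <- NULL; cl
  }
  priorCache <- .tPredictiveCache(pr, 0L, numeric(d), matrix(0, d, d))
  withr::with_seed(params$seed, {
    # every point starts in its own cluster: collapsed Gibbs merges
    # readily but splits poorly, so over-initialization mixes better
    z <- seq_len(n)
    clusters <- lapply(seq_len(n), function(i)
      addTo(newCluster(), X[i, ]))
    bestScore <- -Inf; bestZ <- z
    for (sweep in seq_len(params$nSweeps)) {
      for (i in seq_len(n)) {
        x <- X[i, ]
        zi <- z[i]
        clusters[[zi]] <- removeFrom(clusters[[zi]], x)
        if (clusters[[zi]]$n == 0L) {
          clusters[[zi]] <- NULL
          z[z > zi] <- z[z > zi] - 1L
          z[i] <- NA_integer_
        }
        K <- length(clusters)
        logw <- numeric(K + 1L)
        for (k in seq_len(K)) {
          cl <- clusters[[k]]
          if (is.null(cl$cache))
            clusters[[k]]$cache <- cl$cache <-
              .tPredictiveCache(pr, cl$n, cl$s, cl$SS)
          logw[k] <- log(cl$n) + .tPredictiveLogd(cl$cache, x)
        }
        logw[K + 1L] <- log(params$alpha) +
          .tPredictiveLogd(priorCache, x)
        w <- exp(logw - max(logw))
        pick <- sample.int(K + 1L, 1L, prob = w)
        if (pick > K) clusters[[pick]] <- newCluster()
        clusters[[pick]] <- addTo(clusters[[pick]], x)
        z[i] <- pick
      }
      score <- .jointLogPosterior(pr, params$alpha, clusters, n)
      if (score > bestScore) { bestScore <- score; bestZ <- z }
    }
    lab <- .relabelCompact(bestZ)
    methods::new("CellClustering", labels = lab, K = max(lab),
                 method = "dpmm", preprocessing = preprocessing,
                 cellIds = if (is.null(ids)) seq_len(n) else
                   as.integer(ids))
  })
}
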