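clusteringOf <- function(labels, cellIds = seq_along(labels),
                         preprocessing = list()) {
  methods::new("CellClustering", labels = as.integer(labels),
               K = max(labels), method = "graph",
               preprocessing = preprocessing,
               cellIds = as.integer(cellIds))
}

test_that("moments match closed-form two-point and degenerate cases", {
  X <- rbind(c(1, 0), c(0, 1))
  mom <- estimateMoments(X, clusteringOf(c(1L, 1L)), lambdaFrac = 1e-2)
  expect_equal(unname(mom@means[1, ]), c(0.5, 0.5))
  lambda <- 1e-2 * 0.5   # pooled = the single cluster covariance
  expect_equal(mom@lambda, lambda)
  expect_equal(unname(mom@covariances[[1]]),
               rbind(c(0.5, -0.5), c(-0.5, 0.5)) + diag(lambda, 2))

  # identical members: covariance collapses to lambda * I exactly
  Xc <- rbind(c(2, 3), c(2, 3), c(2, 3))
  momc <- estimateMoments(Xc, clusteringOf(c(1L, 1L, 1L)))
  expect_equal(unname(momc@covariances[[1]]), diag(momc@lambda, 2))
})

test_that("moments equal brute-force per-cluster mean and covariance", {
  set.seed(12)
  X <- matrix(rnorm(200 * 10), 200, 10)
  lab <- rep(1:2, each = 100)
  mom <- estimateMoments(X, clusteringOf(lab))
  for (k in 1:2) {
    Xk <- X[lab == k, ]
    expect_equal(unname(mom@means[k, ]), unname(colMeans(Xk)))
    expect_equal(mom@covariances[[k]],
                 cov(Xk) + diag(mom@lambda, 10),
                 ignore_attr = TRUE)
  }
  # singleton cluster falls back to the pooled covariance
  lab1 <- c(rep(1L, 199), 2L)
  mom1 <- estimateMoments(X, clusteringOf(lab1))
  pooled <- cov(X[lab1 == 1L, ])
  expect_equal(mom1@covariances[[2]],
               pooled + diag(mom1@lambda, 10), ignore_attr = TRUE)
})

test_that("a mock cell captures neighbors with shifted-inverse weights", {
  st <- spotTableOf(gene = c("A", "B", "B"),
                    x = c(0, 1, 50), y = c(0, 0, 0))
  # radius below the nearest neighbor: only the spot itself
  mc0 <- buildMockCell("s001", st, r = 0.5, delta = 1)
  expect_equal(mc0@nNeighbors, 1L)
  expect_equal(unname(mc0@weights), c(1, 0))
  # one neighbor of gene B at d = delta contributes 1/2
  mc1 <- buildMockCell("s001", st, r = 2, delta = 1)
  expect_equal(mc1@nNeighbors, 2L)
  expect_equal(unname(mc1@weights), c(1, 0.5))
  expect_error(buildMockCell("s001", st, r = 0), "parameter")
})

test_that("grid-accelerated mock cells equal the exhaustive scan", {
  set.seed(13)
  n <- 500
  st <- spotTableOf(gene = sample(c("A", "B", "C", "D"), n, TRUE),
                    x = runif(n, 0, 120), y = runif(n, 0, 120))
  df <- spotData(st)
  idx <- sort(sample.int(n, 120))
  got <- sparcler:::.mockMatrix(df, idx, genePanel(st), r = 25,
                                delta = 2)
  for (q in seq_along(idx)) {
    i <- idx[q]
    d <- sqrt((df$x - df$x[i])^2 + (df$y - df$y[i])^2)
    nb <- which(d <= 25)
    w <- 1 / (1 + d[nb] / 2)
    want <- vapply(genePanel(st), function(g)
      sum(w[df$gene[nb] == g]), numeric(1))
    expect_equal(unname(got$W[q, ]), unname(want))
    expect_equal(got$nNeighbors[q], length(nb))
  }
})

test_that("model-space mapping is scale-invariant and replayable", {
  rec <- list(medianTotal = 200,
              geneMeans = c(1, 2, 0.5), geneSds = c(1, 0.5, 2))
  v <- c(3, 0, 1)
  expect_equal(mockToModelSpace(v, rec), mockToModelSpace(10 * v, rec))
  # manual replay of the stored transform
  scaled <- v * (200 / sum(v))
  want <- (log1p(scaled) - rec$geneMeans) / rec$geneSds
  expect_equal(mockToModelSpace(v, rec), want)
  expect_error(mockToModelSpace(c(0, 0, 0), rec), "degenerate")
})

test_that("mock vectors proportional to a cell profile transform like it", {
  cm <- matrix(c(30L, 10L, 5L, 55L, 20L, 8L, 70L, 2L, 1L), 3, 3,
               byrow = TRUE, dimnames = list(1:3, c("A", "B", "C")))
  pp <- preprocessCounts(cm)
  prof <- cm[2, ] * (pp$record$medianTotal / sum(cm[2, ]))
  direct <- (log1p(prof) - pp$record$geneMeans) / pp$record$geneSds
  expect_equal(mockToModelSpace(0.37 * cm[2, ], pp$record),
               direct, tolerance = 1e-6)
})

test_that("the MLE cluster call matches brute-force density evaluation", {
  # equal spherical covariances: nearest mean wins
  mom <- estimateMoments(rbind(c(1, 0), c(1, 0.1), c(0, 1), c(0.1, 1)),
                         clusteringOf(c(1L, 1L, 2L, 2L)))
  expect_equal(mleCluster(c(1, 0), mom)$cluster, 1L)
  expect_equal(mleCluster(c(0, 1), mom)$cluster, 2L)
  # exact tie: lower cluster id, zero margin
  momT <- methods::new("ClusterMoments",
                       means = rbind(c(1, 0), c(1, 0)),
                       covariances = list(diag(2), diag(2)),
                       chols = list(chol(diag(2)), chol(diag(2))),
                       n = c(2L, 2L), lambda = 0)
  tie <- mleCluster(c(5, 5), momT)
  expect_equal(tie$cluster, 1L)
  expect_equal(tie$margin, 0)
  expect_error(mleCluster(c(1, 2, 3), momT), "dimension")

  set.seed(14)
  G <- 5; K <- 4
  covs <- lapply(seq_len(K), function(k) {
    A <- matrix(rnorm(G * G), G); crossprod(A) + diag(G)
  })
  mom4 <- methods::new("ClusterMoments",
                       means = matrix(rnorm(K * G), K, G),
                       covariances = covs,
                       chols = lapply(covs, chol),
                       n = rep(2L, K), lambda = 0)
  for (t in 1:100) {
    v <- rnorm(G, sd = 2)
    # oracle: direct density via solve() and det(), no Cholesky
    ll <- vapply(seq_len(K), function(k) {
      dv <- v - mom4@means[k, ]
      -G / 2 * log(2 * pi) - 0.5 * log(det(covs[[k]])) -
        0.5 * drop(dv %*% solve(covs[[k]], dv))
    }, numeric(1))
    got <- mleCluster(v, mom4)
    expect_equal(got$cluster, which.max(ll))
    expect_equal(got$loglik, max(ll), tolerance = 1e-8)
  }
})

test_that("nearest-of-cluster assignment honors the cap and ties", {
  counts <- methods::new("CellGeneCounts",
                         counts = matrix(0L, 3, 1,
                                         dimnames = list(1:3, "A")),
                         cellIds = c(2L, 5L, 9L), genes = "A",
                         centroids = rbind(c(5, 0), c(10, 0), c(3, 0)))
  labels <- c(1L, 1L, 2L)
  expect_equal(assignToCell(c(0, 0), 1L, counts, labels, D = 20), 2L)
  expect_true(is.na(assignToCell(c(0, 0), 1L, counts, labels, D = 2)))
  expect_equal(assignToCell(c(0, 0), 2L, counts, labels, D = 20), 9L)
  # tie at equal distance goes to the lower cell id
  countsT <- methods::new("CellGeneCounts",
                          counts = matrix(0L, 2, 1,
                                          dimnames = list(1:2, "A")),
                          cellIds = c(7L, 4L), genes = "A",
                          centroids = rbind(c(5, 0), c(-5, 0)))
  expect_equal(assignToCell(c(0, 0), 1L, countsT, c(1L, 1L), D = 10), 4L)
})

test_that("random nearest-of-cluster instances match exhaustive scans", {
  set.seed(15)
  for (t in 1:100) {
    nc <- sample(3:12, 1)
    counts <- methods::new("CellGeneCounts",
                           counts = matrix(0L, nc, 1,
                                           dimnames = list(seq_len(nc),
                                                           "A")),
                           cellIds = sample.int(50, nc),
                           genes = "A",
                           centroids = cbind(runif(nc, 0, 40),
                                             runif(nc, 0, 40)))
    labels <- sample.int(3, nc, replace = TRUE)
    xy <- runif(2, 0, 40); k <- sample.int(3, 1); D <- runif(1, 5, 30)
    got <- assignToCell(xy, k, counts, labels, D)
    d <- sqrt(colSums((t(counts@centroids) - xy)^2))
    ok <- which(labels == k & d <= D)
    if (!length(ok)) expect_true(is.na(got)) else {
      best <- ok[order(d[ok], counts@cellIds[ok])][1L]
      expect_equal(got, counts@cellIds[best])
    }
  }
})

test_that("applying an assignment moves exactly one count", {
  seg <- diskMaskSeg(c(30L, 30L), rbind(c(8, 8), c(22, 22)), 4)
  st <- spotTableOf(gene = c("A", "B", "A"), x = c(8, 22, 15),
                    y = c(8, 22, 15))
  bm <- buildCountMatrix(st, seg)
  before <- sum(countsMatrix(bm$counts))
  out <- applyAssignment("s003", 2L, 1L, bm$counts, bm$spots,
                         iteration = 1L, loglik = -3.2)
  expect_equal(sum(countsMatrix(out$counts)), before + 1L)
  expect_equal(countsMatrix(out$counts)["2", "A"],
               countsMatrix(bm$counts)["2", "A"] + 1L)
  expect_equal(spotData(out$spots)$status[3], "assigned")
  expect_equal(nrow(out$record), 1L)
  expect_error(applyAssignment("s003", 2L, 1L, out$counts, out$spots,
                               1L, 0), "already assigned")
})

test_that("with one cluster the MLE degenerates to pure proximity", {
  sim <- simulateFov(smallSimConfig(seed = 2, nClusters = 1))
  bm <- buildCountMatrix(sim$spots, sim$seg)
  pp <- preprocessCounts(bm$counts)
  oneCluster <- methods::new("CellClustering",
                             labels = rep(1L, nrow(pp$X)), K = 1L,
                             method = "graph", preprocessing = pp$record,
                             cellIds = as.integer(rownames(pp$X)))
  mom <- estimateMoments(pp$X, oneCluster)
  labels <- rep(NA_integer_, length(cellIds(bm$counts)))
  labels[match(oneCluster@cellIds, cellIds(bm$counts))] <- 1L
  cents <- cellCentroids(bm$counts)
  df <- spotData(bm$spots)
  D <- 30
  for (i in which(df$status == "dangling")[1:40]) {
    mc <- buildMockCell(df$spot_id[i], bm$spots, r = 12)
    v <- mockToModelSpace(mc, pp$record)
    call <- mleCluster(v, mom)
    expect_equal(call$cluster, 1L)
    expect_equal(call$margin, Inf)
    got <- assignToCell(c(df$x[i], df$y[i]), call$cluster, bm$counts,
                        labels, D)
    d <- sqrt((cents[, 1] - df$x[i])^2 + (cents[, 2] - df$y[i])^2)
    d[is.na(labels)] <- Inf
    if (min(d) > D) expect_true(is.na(got)) else
      expect_equal(got, cellIds(bm$counts)[which.min(d)])
  }
})

test_that("raising the likelihood margin never adds assignments", {
  sim <- simulateFov(smallSimConfig(seed = 1))
  ns <- vapply(c(0, 2, 10, 50), function(m) {
    res <- runSparcle(sim$spots, sim$seg,
                      params = assignParams(minLoglikMargin = m),
                      seed = 0)
    nrow(res$records)
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})
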