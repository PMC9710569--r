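test_that("cluster profiles are z-score group means", {
  set.seed(20)
  X <- matrix(rpois(10 * 6, 5), 10, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  # one cluster: z-scores average to zero over all cells
  p1 <- profileMatrix(clusterProfiles(X, rep(1L, 10)))
  expect_equal(unname(p1[1, ]), rep(0, 6), tolerance = 1e-12)

  # disjoint marker genes force the sign pattern
  M <- matrix(1L, 8, 2, dimnames = list(NULL, c("mA", "mB")))
  M[1:4, 1] <- 10L; M[5:8, 2] <- 10L
  pm <- profileMatrix(clusterProfiles(M, rep(1:2, each = 4)))
  expect_true(pm["1", "mA"] > 0 && pm["2", "mA"] < 0)
  expect_true(pm["1", "mB"] < 0 && pm["2", "mB"] > 0)

  # equals manual per-gene z then group mean
  lab <- rep(1:2, 5)
  Z <- scale(X)
  want <- rbind(colMeans(Z[lab == 1, ]), colMeans(Z[lab == 2, ]))
  expect_equal(unname(profileMatrix(clusterProfiles(X, lab))),
               unname(want))
})

test_that("gramian covariance is symmetric PSD and matches cross-covariance", {
  P <- matrix(rnorm(4 * 20), 4, 20,
              dimnames = list(1:4, paste0("g", 1:20)))
  Gm <- gramianCovariance(P)
  expect_equal(Gm, t(Gm))
  expect_gte(min(eigen(Gm, symmetric = TRUE)$values), -1e-10)
  expect_equal(crossCovariance(P, P), Gm, ignore_attr = TRUE)

  # identical rows: every entry equals the common variance
  Pi <- matrix(rep(rnorm(10), each = 3), 3, 10,
               dimnames = list(1:3, paste0("g", 1:10)))
  Gi <- gramianCovariance(Pi)
  expect_equal(max(Gi) - min(Gi), 0)

  # orthogonal centered rows give a diagonal gramian
  Po <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  colnames(Po) <- paste0("g", 1:4)
  Go <- gramianCovariance(Po)
  expect_equal(Go[1, 2], 0)
})

test_that("cross-covariance negates with a negated argument and matches loops", {
  set.seed(21)
  Pa <- matrix(rnorm(3 * 12), 3, 12,
               dimnames = list(1:3, paste0("g", 1:12)))
  Pb <- matrix(rnorm(2 * 12), 2, 12,
               dimnames = list(1:2, paste0("g", 1:12)))
  expect_equal(crossCovariance(Pa, -Pa), -gramianCovariance(Pa),
               ignore_attr = TRUE)
  CC <- crossCovariance(Pa, Pb)
  for (i in 1:3) for (j in 1:2)
    expect_equal(CC[i, j], cov(Pa[i, ], Pb[j, ]))
  Pb2 <- Pb; colnames(Pb2) <- rev(colnames(Pb))
  expect_error(crossCovariance(Pa, Pb2), "gene order")
})

test_that("diagonal dominance scores match direct computation", {
  expect_equal(diagonalDominanceScore(diag(3)), 1)
  expect_equal(diagonalDominanceScore(matrix(1, 3, 3)), 0)
  set.seed(22)
  M <- matrix(rnorm(25), 5, 5)
  want <- mean(abs(diag(M))) - mean(abs(M[row(M) != col(M)]))
  expect_equal(diagonalDominanceScore(M), want)
  expect_error(diagonalDominanceScore(matrix(2, 1, 1)), "1 x 1")
})

test_that("frobenius distance is a metric with known special values", {
  A <- matrix(rnorm(9), 3, 3)
  expect_equal(frobeniusDistance(A, A), 0)
  B <- A; diag(B) <- diag(B) + 1
  expect_equal(frobeniusDistance(A, B), sqrt(3))
  expect_equal(frobeniusDistance(diag(2), matrix(0, 2, 2)), sqrt(2))
  set.seed(23)
  for (t in 1:20) {
    X <- matrix(rnorm(6), 2, 3); Y <- matrix(rnorm(6), 2, 3)
    Z <- matrix(rnorm(6), 2, 3)
    expect_equal(frobeniusDistance(X, Y), sqrt(sum((X - Y)^2)))
    expect_equal(frobeniusDistance(X, Y), frobeniusDistance(Y, X))
    expect_lte(frobeniusDistance(X, Z),
               frobeniusDistance(X, Y) + frobeniusDistance(Y, Z) + 1e-12)
  }
  expect_error(frobeniusDistance(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})

test_that("Box's M is zero for identical groups and matches an independent implementation", {
  set.seed(30)
  A <- matrix(rnorm(60), 20, 3)
  same <- boxMTest(list(A, A, A))
  expect_equal(same$M, 0, tolerance = 1e-10)
  expect_equal(same$p, 1)

  # frozen cross-implementation oracle (independent Python Box's M /
  # pingouin.box_m on this exact fixture)
  set.seed(7)
  G1 <- matrix(round(rnorm(40, 0, 1), 4), 20, 2)
  G2 <- matrix(round(rnorm(50, 0, 1.5), 4), 25, 2)
  got <- boxMTest(list(G1, G2))
  expect_equal(got$chi2, 6.8115394837302805, tolerance = 1e-6)
  expect_equal(got$df, 3)
  expect_equal(got$p, 0.07815350841608401, tolerance = 1e-6)

  expect_error(boxMTest(list(A)), "2 groups")
  expect_warning(boxMTest(list(A[1:3, ], A)), "n <= p")
})

test_that("the Loewner order classifies all regimes and stays consistent", {
  I2 <- diag(2)
  expect_equal(loewnerOrder(I2, I2), "equal")
  expect_equal(loewnerOrder(2 * I2, I2), "A>=B")
  expect_equal(loewnerOrder(I2, 2 * I2), "B>=A")
  expect_equal(loewnerOrder(diag(c(1, -1)) + I2, I2), "incomparable")
  expect_error(loewnerOrder(matrix(c(1, 2, 3, 4), 2), I2), "symmetric")
  set.seed(24)
  for (t in 1:30) {
    A <- crossprod(matrix(rnorm(9), 3)); B <- crossprod(matrix(rnorm(9), 3))
    ab <- loewnerOrder(A, B); ba <- loewnerOrder(B, A)
    # never both strictly dominant
    expect_false(ab == "A>=B" && ba == "A>=B")
    if (ab == "A>=B") expect_equal(ba, "B>=A")
    if (ab == "incomparable") expect_equal(ba, "incomparable")
  }
})

test_that("Pearson block matrices reproduce textbook correlations", {
  set.seed(25)
  X <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(NULL, paste0("g", 1:30)))
  ty <- rep(c("e", "i"), each = 3)
  R <- pearsonBlockMatrix(X, ty, X, ty, nPerType = 3, seed = 1)
  # a cell against itself correlates at exactly 1
  expect_equal(unname(diag(R)), rep(1, 6))
  Y <- -X
  Rn <- pearsonBlockMatrix(X, ty, Y, ty, nPerType = 3, seed = 1)
  expect_equal(unname(diag(Rn)), rep(-1, 6))
  # matches the scalar cor() loop
  for (i in 1:6) for (j in 1:6)
    expect_equal(R[i, j], cor(X[i, ], X[j, ]))
  expect_warning(
    pearsonBlockMatrix(X, ty, X, ty, nPerType = 10, seed = 1),
    "only")
})

test_that("compareRuns is symmetric for identical runs and zero at the reference", {
  sim <- simulateFov(smallSimConfig(seed = 7))
  bm <- buildCountMatrix(sim$spots, sim$seg)
  pp <- preprocessCounts(bm$counts)
  cl <- clusterGraph(pp$X, seed = 0, preprocessing = pp$record)
  run <- list(counts = bm$counts, clustering = cl)
  ref <- clusterProfiles(bm$counts, cl)
  cmp <- compareRuns(run, run, ref)
  expect_equal(cmp$frobeniusProfiles[1], cmp$frobeniusProfiles[2])
  expect_equal(cmp$diagDominance[1], cmp$diagDominance[2])
  # the reference equals this run's profiles: distance is exactly 0
  expect_equal(cmp$frobeniusProfiles[2], 0, tolerance = 1e-10)
  d <- withr::local_tempfile(fileext = ".csv")
  compareRuns(run, run, ref, outCsv = d)
  expect_true(file.exists(d))
})
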