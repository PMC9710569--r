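#' @include AllClasses.R io.R
NULL

#' Construct a synthetic field-of-view configuration
#'
#' Defaults emulate a single MERFISH-like FoV: ~80 cells drawn from 5
#' expression programs over a 140-gene panel, ~300 transcripts per cell
#' placed isotropically around the cell center, and a conservative
#' nucleus-disk segmentation that leaves roughly half the transcripts
#' dangling.
#'
#' @param nCells,nGenes,nClusters field composition.
#' @param clusterProportions cluster frequencies (defaults uniform).
#' @param programConcentration Dirichlet concentration of the per-cluster
#'   gene programs; 0.1 yields sparse, well-separated programs.
#' @param countsMean,countsDispersion negative-binomial transcripts per
#'   cell (mu and size).
#' @param cellSigma isotropic Gaussian spread of transcript placement.
#' @param nucleusRadius radius of the segmented nucleus disk.
#' @param fieldSize c(width, height) in pixels.
#' @param minCellSpacing minimum center-to-center distance.
#' @param seed RNG seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nCells = 80, nGenes = 140, nClusters = 5,
                      clusterProportions = NULL,
                      programConcentration = 0.1,
                      countsMean = 300, countsDispersion = 10,
                      cellSigma = 5, nucleusRadius = 6,
                      fieldSize = c(512L, 512L), minCellSpacing = 24,
                      seed = 0L) {
  if (is.null(clusterProportions))
    clusterProportions <- rep(1 / nClusters, nClusters)
  methods::new("SimConfig", nCells = as.integer(nCells),
               nGenes = as.integer(nGenes),
               nClusters = as.integer(nClusters),
               clusterProportions = as.numeric(clusterProportions),
               programConcentration = programConcentration,
               countsMean = countsMean,
               countsDispersion = countsDispersion,
               cellSigma = cellSigma, nucleusRadius = nucleusRadius,
               fieldSize = as.integer(fieldSize),
               minCellSpacing = minCellSpacing, seed = as.integer(seed))
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  x / rowSums(x)
}

# sequential rejection sampling of cell centers with minimum spacing;
# centers are kept at least nucleusRadius away from the field edge so
# every nucleus disk lies fully inside the field
.placeCenters <- function(n, field, rmin, spacing, maxRej) {
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L; rejected <- 0L
  lo <- rmin
  hix <- field[1L] - 1 - rmin
  hiy <- field[2L] - 1 - rmin
  if (hix <= lo || hiy <= lo) stop("placement error: field too small")
  while (placed < n) {
    x <- stats::runif(1L, lo, hix)
    y <- stats::runif(1L, lo, hiy)
    if (placed == 0L ||
        min((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2) >=
          spacing^2) {
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y
    } else {
      rejected <- rejected + 1L
      if (rejected > maxRej)
        stop("placement error: could not honor minCellSpacing; ",
             "use a larger field or fewer cells")
    }
  }
  cbind(x = cx, y = cy)
}

.diskMask <- function(field, centers, radius) {
  w <- field[1L]; h <- field[2L]
  mask <- matrix(0L, h, w)
  bestd2 <- matrix(Inf, h, w)
  for (k in seq_len(nrow(centers))) {
    x0 <- centers[k, 1L]; y0 <- centers[k, 2L]
    cols <- max(0L, floor(x0 - radius)):min(w - 1L, ceiling(x0 + radius))
    rows <- max(0L, floor(y0 - radius)):min(h - 1L, ceiling(y0 + radius))
    d2 <- outer(rows - y0, cols - x0,
                function(dy, dx) dy^2 + dx^2)
    sel <- d2 <= radius^2 & d2 < bestd2[rows + 1L, cols + 1L]
    sub <- mask[rows + 1L, cols + 1L]
    sub[sel] <- k
    mask[rows + 1L, cols + 1L] <- sub
    subd <- bestd2[rows + 1L, cols + 1L]
    subd[sel] <- d2[sel]
    bestd2[rows + 1L, cols + 1L] <- subd
  }
  mask
}

#' Simulate a ground-truth field of view
#'
#' Generative model, in documented draw order under one seeded stream:
#' (1) K gene programs ~ Dirichlet(concentration) over the panel;
#' (2) per-cell cluster ~ Categorical(proportions);
#' (3) cell centers by rejection sampling with minimum spacing;
#' (4) per-cell transcript count ~ NegBin(mean, dispersion);
#' (5) per-transcript gene i.i.d. from the cell's program and position
#' i.i.d. isotropic Gaussian around the center (redrawn until inside the
#' field). The segmentation is a nucleus disk of the configured radius
#' per cell — deliberately conservative, so a large fraction of
#' transcripts dangles.
#'
#' @param cfg a [SimConfig-class].
#' @return list with \code{spots} ([SpotTable-class], statuses all
#'   dangling until [buildCountMatrix()]), \code{seg}
#'   ([Segmentation-class]) and \code{truth} (list: \code{cellOfSpot},
#'   \code{clusterOfCell}, \code{programs}, \code{clusterMoments}).
#' @export
simulateFov <- function(cfg) {
  methods::validObject(cfg)
  set.seed(cfg@seed)
  G <- cfg@nGenes; K <- cfg@nClusters; n <- cfg@nCells
  panel <- sprintf("g%03d", seq_len(G))
  programs <- .rdirichlet(K, rep(cfg@programConcentration, G))
  colnames(programs) <- panel
  rownames(programs) <- seq_len(K)
  clusterOfCell <- sample.int(K, n, replace = TRUE,
                              prob = cfg@clusterProportions)
  # guarantee every cluster is realized (validity of downstream moments)
  missing <- setdiff(seq_len(K), unique(clusterOfCell))
  if (length(missing))
    clusterOfCell[seq_along(missing)] <- missing
  centers <- .placeCenters(n, cfg@fieldSize, cfg@nucleusRadius,
                           cfg@minCellSpacing, 1e4 * n)
  nSpots <- stats::rnbinom(n, mu = cfg@countsMean,
                           size = cfg@countsDispersion)
  nSpots <- pmax(nSpots, 1L)   # a cell without transcripts is unobservable
  total <- sum(nSpots)
  cell <- rep(seq_len(n), nSpots)
  gene <- character(total)
  for (k in seq_len(n)) {
    idx <- which(cell == k)
    gene[idx] <- sample(panel, length(idx), replace = TRUE,
                        prob = programs[clusterOfCell[k], ])
  }
  x <- stats::rnorm(total, centers[cell, 1L], cfg@cellSigma)
  y <- stats::rnorm(total, centers[cell, 2L], cfg@cellSigma)
  out <- x < 0 | x >= cfg@fieldSize[1L] | y < 0 | y >= cfg@fieldSize[2L]
  while (any(out)) {
    i <- which(out)
    x[i] <- stats::rnorm(length(i), centers[cell[i], 1L], cfg@cellSigma)
    y[i] <- stats::rnorm(length(i), centers[cell[i], 2L], cfg@cellSigma)
    out[i] <- x[i] < 0 | x[i] >= cfg@fieldSize[1L] |
      y[i] < 0 | y[i] >= cfg@fieldSize[2L]
  }
  ids <- sprintf("s%06d", seq_len(total))
  spots <- .newSpotTable(
    data.frame(spot_id = ids, gene = gene, x = x, y = y,
               stringsAsFactors = FALSE), panel = panel)
  mask <- .diskMask(cfg@fieldSize, centers, cfg@nucleusRadius)
  seg <- .segFromMask(mask)
  # realized per-cell count vectors and their per-cluster moments
  cm <- table(factor(cell, levels = seq_len(n)),
              factor(gene, levels = panel))
  cm <- matrix(as.integer(cm), n, G, dimnames = list(seq_len(n), panel))
  clusterMoments <- lapply(seq_len(K), function(k) {
    m <- cm[clusterOfCell == k, , drop = FALSE]
    list(mean = colMeans(m),
         cov = if (nrow(m) > 1L) stats::cov(m) else
           matrix(0, G, G, dimnames = list(panel, panel)))
  })
  truth <- list(cellOfSpot = stats::setNames(cell, ids),
                clusterOfCell = stats::setNames(clusterOfCell,
                                                seq_len(n)),
                programs = programs,
                trueCounts = cm,
                centers = centers,
                clusterMoments = clusterMoments)
  list(spots = spots, seg = seg, truth = truth)
}

#' Fraction of spots currently dangling
#'
#' @param spots a [SpotTable-class] with statuses computed.
#' @return |dangling| / |spots|.
#' @export
danglingFraction <- function(spots) {
  df <- spots@spots
  if (!nrow(df)) stop("undefined value: empty spot table")
  mean(df$status == "dangling")
}

#' Score assignment records against simulation ground truth
#'
#' @param records assignment-record data.frame (spot_id, cell_id,
#'   cluster_id, iteration, loglik).
#' @param truth the \code{truth} element returned by [simulateFov()].
#' @return list: \code{assignedFraction} (of all spots),
#'   \code{cellAccuracy} (assigned spot's cell equals its true cell),
#'   \code{clusterAccuracy} (assigned cell's true cluster equals the
#'   true cell's cluster), \code{perIterationFractions}. Accuracies are
#'   NA when nothing was assigned.
#' @export
scoreAssignments <- function(records, truth) {
  total <- length(truth$cellOfSpot)
  if (is.null(records) || !nrow(records)) {
    return(list(assignedFraction = 0, cellAccuracy = NA_real_,
                clusterAccuracy = NA_real_,
                perIterationFractions = numeric(0)))
  }
  unknown <- setdiff(records$spot_id, names(truth$cellOfSpot))
  if (length(unknown))
    stop("consistency error: record references unknown spot ",
         unknown[1L])
  trueCell <- truth$cellOfSpot[records$spot_id]
  cellAcc <- mean(records$cell_id == trueCell)
  cl <- truth$clusterOfCell
  clusterAcc <- mean(cl[as.character(records$cell_id)] ==
                       cl[as.character(trueCell)])
  iters <- sort(unique(records$iteration))
  perIter <- vapply(iters, function(i) sum(records$iteration == i) / total,
                    numeric(1))
  names(perIter) <- iters
  list(assignedFraction = nrow(records) / total,
       cellAccuracy = cellAcc, clusterAccuracy = clusterAcc,
       perIterationFractions = perIter)
}
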