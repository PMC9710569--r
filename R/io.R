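#' @include AllClasses.R
NULL

# Coordinate conventions used throughout:
#  - continuous, 0-based; pixel (i, j) covers [i, i+1) x [j, j+1)
#  - the label mask is a matrix with rows indexing y and columns x, so
#    the pixel containing (x, y) is mask[floor(y)+1, floor(x)+1]
#  - the "center" of pixel (i, j) used for centroids is (i, j) itself

.newSpotTable <- function(df, panel = NULL) {
  df$spot_id <- as.character(df$spot_id)
  df$gene <- as.character(df$gene)
  if (is.null(panel)) panel <- sort(unique(df$gene))
  if (is.null(df$status)) df$status <- rep("dangling", nrow(df))
  if (is.null(df$cell_id)) df$cell_id <- rep(NA_integer_, nrow(df))
  if (is.null(df$iteration)) df$iteration <- rep(NA_integer_, nrow(df))
  rownames(df) <- NULL
  methods::new("SpotTable", spots = df, panel = as.character(panel))
}

.maskCentroids <- function(mask, ids) {
  if (!length(ids)) {
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("x", "y"))))
  }
  idx <- which(mask > 0L)
  lab <- mask[idx]
  r <- ((idx - 1L) %% nrow(mask))        # 0-based row = y
  cc <- ((idx - 1L) %/% nrow(mask))      # 0-based col = x
  cx <- tapply(cc, lab, mean)
  cy <- tapply(r, lab, mean)
  out <- cbind(x = as.numeric(cx[as.character(ids)]),
               y = as.numeric(cy[as.character(ids)]))
  rownames(out) <- ids
  out
}

.segFromMask <- function(mask) {
  storage.mode(mask) <- "integer"
  ids <- sort(unique(mask[mask > 0L]))
  methods::new("Segmentation", mask = mask, polygons = NULL,
               cellIds = as.integer(ids),
               centroids = .maskCentroids(mask, ids))
}

# cross product sign helper for segment intersection
.segsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.polygonSelfIntersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  segs <- lapply(seq_len(n), function(i) {
    rbind(xy[i, ], xy[if (i == n) 1L else i + 1L, ])
  })
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next   # closing edge shares vertex with first
      if (.segsIntersect(segs[[i]][1, ], segs[[i]][2, ],
                         segs[[j]][1, ], segs[[j]][2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Read a spot table from CSV/TSV
#'
#' Parses one row per detected mRNA spot. All statuses are initialized to
#' dangling; [buildCountMatrix()] later splits inside from dangling.
#'
#' @param path CSV or TSV file with a header row.
#' @param columnMap named character vector mapping the required fields
#'   (\code{spot_id}, \code{gene}, \code{x}, \code{y}) to column names in
#'   the file.
#' @param panel optional explicit gene panel (character); defaults to the
#'   sorted unique genes observed.
#' @param sep field separator, inferred from the extension by default.
#' @return a [SpotTable-class].
#' @export
readSpots <- function(path,
                      columnMap = c(spot_id = "spot_id", gene = "gene",
                                    x = "x", y = "y"),
                      panel = NULL, sep = NULL) {
  if (!file.exists(path)) stop("spot file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("spot_id", "gene", "x", "y")
  miss <- setdiff(need, names(columnMap))
  if (length(miss))
    stop("configuration error: columnMap lacks mapping for: ",
         paste(miss, collapse = ", "))
  absent <- setdiff(unname(columnMap[need]), names(df))
  if (length(absent))
    stop("configuration error: missing column(s) in ", path, ": ",
         paste(absent, collapse = ", "))
  out <- data.frame(spot_id = df[[columnMap[["spot_id"]]]],
                    gene = df[[columnMap[["gene"]]]],
                    x = suppressWarnings(as.numeric(df[[columnMap[["x"]]]])),
                    y = suppressWarnings(as.numeric(df[[columnMap[["y"]]]])),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$x) | !is.finite(out$y))
  if (length(bad))
    stop("parse error: non-numeric coordinate at row ", bad[1L],
         " of ", path)
  .newSpotTable(out, panel = panel)
}

#' Read a cell segmentation
#'
#' Accepts a label-mask image (16-bit TIFF or PNG, or a CSV matrix, or an
#' integer matrix already in memory; 0 = background) or a per-cell
#' polygon table (data.frame with columns cell_id, x, y; vertices in
#' order, polygon implicitly closed). Centroids are the arithmetic mean
#' of member pixel positions (mask) or of polygon vertices.
#'
#' @param x path or matrix or polygon data.frame.
#' @return a [Segmentation-class].
#' @export
readSegmentation <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("segmentation file not found: ", x)
    if (grepl("\\.tiff?$", x, ignore.case = TRUE)) {
      m <- tiff::readTIFF(x, as.is = TRUE)
    } else if (grepl("\\.png$", x, ignore.case = TRUE)) {
      m <- round(png::readPNG(x) * 65535)
    } else {
      m <- as.matrix(utils::read.csv(x, header = FALSE))
      dimnames(m) <- NULL
    }
    x <- m
  }
  if (is.matrix(x)) {
    if (any(x != round(x)))
      stop("type error: label mask must be integer-valued")
    if (any(x < 0)) stop("type error: labels must be nonnegative")
    return(.segFromMask(x))
  }
  if (is.data.frame(x)) {
    need <- c("cell_id", "x", "y")
    if (!all(need %in% names(x)))
      stop("polygon table needs columns cell_id, x, y")
    ids <- sort(unique(as.integer(x$cell_id)))
    cents <- matrix(NA_real_, length(ids), 2L,
                    dimnames = list(ids, c("x", "y")))
    for (i in seq_along(ids)) {
      xy <- as.matrix(x[x$cell_id == ids[i], c("x", "y")])
      # drop explicit closing vertex if present
      if (nrow(xy) > 1L && all(xy[1L, ] == xy[nrow(xy), ]))
        xy <- xy[-nrow(xy), , drop = FALSE]
      if (.polygonSelfIntersects(xy))
        stop("validation error: self-intersecting polygon for cell ",
             ids[i])
      cents[i, ] <- colMeans(xy)
    }
    return(methods::new("Segmentation", mask = NULL,
                        polygons = as.data.frame(x),
                        cellIds = ids, centroids = cents))
  }
  stop("unsupported segmentation input")
}

#' Dilate a label mask radially
#'
#' Grows every cell label by a disk structuring element of the given
#' pixel radius, emulating the standard nuclei-then-dilate segmentation
#' heuristic. Where dilated cells collide, each contested pixel goes to
#' the nearest original label (ties to the lower label id), so dilation
#' never flips a pixel from one original cell to another. Centroids are
#' recomputed on the dilated mask.
#'
#' @param seg a [Segmentation-class] with a label mask.
#' @param pixels nonnegative integer dilation radius.
#' @return a new [Segmentation-class].
#' @export
dilateSegmentation <- function(seg, pixels) {
  if (is.null(seg@mask))
    stop("unsupported representation: dilation needs a label mask")
  stopifnot(pixels >= 0, pixels == round(pixels))
  mask <- seg@mask
  if (pixels == 0L || !length(seg@cellIds)) return(.segFromMask(mask))
  h <- nrow(mask); w <- ncol(mask)
  r2max <- pixels^2
  cand_pix <- integer(0); cand_lab <- integer(0); cand_d2 <- numeric(0)
  for (k in seg@cellIds) {
    idx <- which(mask == k)
    kr <- ((idx - 1L) %% h) + 1L
    kc <- ((idx - 1L) %/% h) + 1L
    rows <- max(1L, min(kr) - pixels):min(h, max(kr) + pixels)
    cols <- max(1L, min(kc) - pixels):min(w, max(kc) + pixels)
    sub <- mask[rows, cols, drop = FALSE]
    bg <- which(sub == 0L)
    if (!length(bg)) next
    br <- rows[((bg - 1L) %% length(rows)) + 1L]
    bc <- cols[((bg - 1L) %/% length(rows)) + 1L]
    d2 <- outer(br, kr, "-")^2 + outer(bc, kc, "-")^2
    mind2 <- apply(d2, 1L, min)
    keep <- mind2 <= r2max
    if (any(keep)) {
      cand_pix <- c(cand_pix, (bc[keep] - 1L) * h + br[keep])
      cand_lab <- c(cand_lab, rep(k, sum(keep)))
      cand_d2 <- c(cand_d2, mind2[keep])
    }
  }
  out <- mask
  if (length(cand_pix)) {
    o <- order(cand_pix, cand_d2, cand_lab)
    first <- o[!duplicated(cand_pix[o])]
    out[cand_pix[first]] <- cand_lab[first]
  }
  .segFromMask(out)
}

#' Build the initial cell-by-gene count matrix
#'
#' Splits the spot table into inside and dangling spots by the half-open
#' pixel containment rule: a spot at (x, y) belongs to cell k iff
#' mask pixel (floor(x), floor(y)) carries label k. Inside spots
#' increment the corresponding count; everything else (background pixels
#' and spots outside the image extent) stays dangling.
#'
#' @param spots a [SpotTable-class].
#' @param seg a [Segmentation-class] with a label mask.
#' @return list with elements \code{counts} (a [CellGeneCounts-class])
#'   and \code{spots} (the SpotTable with statuses updated).
#' @export
buildCountMatrix <- function(spots, seg) {
  if (is.null(seg@mask))
    stop("unsupported representation: containment needs a label mask")
  mask <- seg@mask
  df <- spots@spots
  panel <- spots@panel
  ids <- seg@cellIds
  h <- nrow(mask); w <- ncol(mask)
  lab <- integer(nrow(df))
  if (nrow(df)) {
    ci <- floor(df$x) + 1L
    ri <- floor(df$y) + 1L
    inb <- ci >= 1L & ci <= w & ri >= 1L & ri <= h
    nout <- sum(!inb)
    if (nout)
      warning(nout, " spot(s) outside the image extent; left dangling")
    lab[inb] <- mask[cbind(ri[inb], ci[inb])]
  }
  inside <- lab > 0L
  df$status <- ifelse(inside, "inside", "dangling")
  df$cell_id <- ifelse(inside, lab, NA_integer_)
  df$iteration <- rep(NA_integer_, nrow(df))
  cm <- matrix(0L, length(ids), length(panel),
               dimnames = list(ids, panel))
  if (any(inside)) {
    tab <- table(factor(lab[inside], levels = ids),
                 factor(df$gene[inside], levels = panel))
    cm[] <- as.integer(tab)
  }
  counts <- methods::new("CellGeneCounts", counts = cm,
                         cellIds = as.integer(ids), genes = panel,
                         centroids = seg@centroids)
  list(counts = counts, spots = .newSpotTable(df, panel = panel))
}

#' Write a label mask as a 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly through
#' [readSegmentation()].
#'
#' @param seg a [Segmentation-class] with a label mask.
#' @param path output .tif path.
#' @return the path, invisibly.
#' @export
writeMask <- function(seg, path) {
  if (is.null(seg@mask)) stop("unsupported representation: need a mask")
  if (max(seg@mask) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(seg@mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write pipeline outputs
#'
#' Writes the corrected count matrix as MatrixMarket MTX (with
#' barcodes.tsv / genes.tsv index files) and as a dense CSV; the
#' assignment records, per-cell cluster labels, and per-cell "boundary"
#' convex hulls over member spot coordinates as CSVs. Integer data
#' round-trip exactly.
#'
#' @param counts a [CellGeneCounts-class].
#' @param records assignment-record data.frame (possibly 0 rows) with
#'   columns spot_id, cell_id, cluster_id, iteration, loglik.
#' @param spots the final [SpotTable-class].
#' @param outDir output directory (created if needed).
#' @param clustering optional [CellClustering-class] for clusters.csv.
#' @return named character vector of the written paths.
#' @export
writeOutputs <- function(counts, records, spots, outDir,
                         clustering = NULL) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("I/O error: cannot write to ", outDir)
  p <- function(f) file.path(outDir, f)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts@counts,
                                             sparse = TRUE), "CsparseMatrix"),
                  p("counts.mtx"))
  writeLines(as.character(counts@cellIds), p("barcodes.tsv"))
  writeLines(counts@genes, p("genes.tsv"))
  dense <- data.frame(cell_id = counts@cellIds, counts@counts,
                      check.names = FALSE)
  utils::write.csv(dense, p("counts.csv"), row.names = FALSE)
  rec <- if (is.null(records) || !nrow(records)) {
    data.frame(spot_id = character(0), cell_id = integer(0),
               cluster_id = integer(0), iteration = integer(0),
               loglik = numeric(0))
  } else {
    records[, c("spot_id", "cell_id", "cluster_id", "iteration", "loglik")]
  }
  utils::write.csv(rec, p("assignments.csv"), row.names = FALSE)
  cl <- data.frame(cell_id = counts@cellIds,
                   cluster_id = if (is.null(clustering)) NA_integer_ else
                     clustering@labels)
  utils::write.csv(cl, p("clusters.csv"), row.names = FALSE)
  df <- spots@spots
  member <- df[!is.na(df$cell_id), , drop = FALSE]
  hulls <- lapply(split(member, member$cell_id), function(g) {
    xy <- as.matrix(g[, c("x", "y")])
    idx <- grDevices::chull(xy)
    data.frame(cell_id = g$cell_id[1L], vertex = seq_along(idx),
               x = xy[idx, 1L], y = xy[idx, 2L])
  })
  hull_df <- if (length(hulls)) do.call(rbind, hulls) else
    data.frame(cell_id = integer(0), vertex = integer(0),
               x = numeric(0), y = numeric(0))
  utils::write.csv(hull_df, p("boundaries.csv"), row.names = FALSE)
  utils::write.csv(df, p("spots.csv"), row.names = FALSE)
  c(mtx = p("counts.mtx"), barcodes = p("barcodes.tsv"),
    genes = p("genes.tsv"), counts_csv = p("counts.csv"),
    assignments = p("assignments.csv"), clusters = p("clusters.csv"),
    boundaries = p("boundaries.csv"), spots = p("spots.csv"))
}
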