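#' @include AllClasses.R utils-geometry.R
NULL

#' Linearly interpolate short tracking gaps
#'
#' Fills invalid runs of at most \code{maxGapS} seconds per node and
#' coordinate by linear interpolation between the flanking valid frames.
#' Longer gaps (and gaps touching the trajectory edges) stay invalid. Filled
#' cells are recorded in the interpolated mask so downstream stages can flag
#' frames whose features rest on filled coordinates.
#'
#' @param traj a \linkS4class{KeypointTrajectory}.
#' @param maxGapS longest gap to fill, seconds.
#' @return A \linkS4class{KeypointTrajectory}.
#' @export
interpolateTracks <- function(traj, maxGapS = 1) {
  maxGap <- round(maxGapS * traj@fps)
  co <- traj@coords
  valid <- traj@valid
  interp <- traj@interpolated
  n <- dim(co)[1]
  for (a in 1:2) for (nd in 1:8) {
    v <- valid[, a, nd]
    if (all(v) || sum(v) < 2L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      if (r$lengths[k] > maxGap) next
      lo <- starts[k] - 1L
      hi <- ends[k] + 1L
      if (lo < 1L || hi > n) next         # edge gaps stay invalid
      idx <- starts[k]:ends[k]
      w <- (idx - lo) / (hi - lo)
      for (d in 1:2)
        co[idx, a, nd, d] <- (1 - w) * co[lo, a, nd, d] +
          w * co[hi, a, nd, d]
      valid[idx, a, nd] <- TRUE
      interp[idx, a, nd] <- TRUE
    }
  }
  new("KeypointTrajectory", coords = co, valid = valid,
      interpolated = interp, fps = traj@fps)
}

#' Default angle triplets
#'
#' Ordered node triplets (a, b, c) whose interior angle at b is computed per
#' animal: head flexion (nose-head-trunk), ear spread at the head, spine
#' bend at the trunk, and the two hip angles.
#'
#' @return list of character triplets.
#' @export
defaultTriplets <- function() {
  list(c("nose", "head", "trunk"),
       c("left_ear", "head", "right_ear"),
       c("head", "trunk", "tail_base"),
       c("trunk", "left_hip", "tail_base"),
       c("trunk", "right_hip", "tail_base"))
}

#' Posture angle features for one session
#'
#' For each triplet the interior angle at the middle node in [0, pi], for
#' both animals, plus the signed inter-animal heading difference (trunk to
#' head axes). All features are invariant to rigid rotation and translation
#' of the coordinates. Frames with any required node invalid, or with a
#' degenerate (coincident-point) triplet, are dropped. Optionally the
#' per-frame first differences are appended.
#'
#' @param traj a \linkS4class{KeypointTrajectory} (interpolated).
#' @param triplets list of node triplets, see \code{\link{defaultTriplets}}.
#' @param includeDerivatives append first temporal differences.
#' @param frames frame indices to use (default all).
#' @return list(features [frames x p], frames, flagged) where flagged marks
#'   frames whose source coordinates include interpolated cells.
#' @export
angleFeatures <- function(traj, triplets = defaultTriplets(),
                          includeDerivatives = FALSE, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  nodes <- nodeRegistry()
  need <- unique(c(unlist(triplets), "head", "trunk"))
  ni <- match(need, nodes)
  ok <- rep(TRUE, length(frames))
  flagged <- rep(0, length(frames))   # fraction of interpolated source cells
  for (a in 1:2) {
    v <- matrix(traj@valid[frames, a, ni], nrow = length(frames))
    f <- matrix(traj@interpolated[frames, a, ni], nrow = length(frames))
    ok <- ok & (rowSums(v) == length(ni))
    flagged <- flagged + rowSums(f)
  }
  flagged <- flagged / (2 * length(ni))
  frames <- frames[ok]
  flagged <- flagged[ok]
  interiorAngle <- function(a, tri) {
    i <- match(tri, nodes)
    v1x <- traj@coords[frames, a, i[1], 1] - traj@coords[frames, a, i[2], 1]
    v1y <- traj@coords[frames, a, i[1], 2] - traj@coords[frames, a, i[2], 2]
    v2x <- traj@coords[frames, a, i[3], 1] - traj@coords[frames, a, i[2], 1]
    v2y <- traj@coords[frames, a, i[3], 2] - traj@coords[frames, a, i[2], 2]
    n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
    cosang <- (v1x * v2x + v1y * v2y) / (n1 * n2)
    ang <- acos(pmin(1, pmax(-1, cosang)))
    ang[n1 == 0 | n2 == 0] <- NA_real_   # degenerate triplet
    ang
  }
  feats <- list()
  for (a in 1:2) {
    an <- animalRegistry()[a]
    for (tri in triplets)
      feats[[paste(an, tri[2], "angle", tri[1], tri[3], sep = "_")]] <-
        interiorAngle(a, tri)
  }
  hi <- match("head", nodes); ti <- match("trunk", nodes)
  heading <- function(a) {
    atan2(traj@coords[frames, a, hi, 2] - traj@coords[frames, a, ti, 2],
          traj@coords[frames, a, hi, 1] - traj@coords[frames, a, ti, 1])
  }
  feats[["relative_heading"]] <- wrapAngle(heading(1) - heading(2))
  F <- do.call(cbind, feats)
  keep <- stats::complete.cases(F)
  F <- F[keep, , drop = FALSE]
  frames <- frames[keep]
  flagged <- flagged[keep]
  if (includeDerivatives) {
    D <- rbind(0, diff(F))
    colnames(D) <- paste0("d_", colnames(F))
    F <- cbind(F, D)
  }
  list(features = F, frames = frames, flagged = flagged)
}

#' Pooled, normalized feature matrix for a cohort
#'
#' Interpolates each session's tracks, computes angle features on the test
#' span (optionally subsampling frames by \code{stride}), pools frames
#' across sessions and z-normalizes each feature over the pooled dataset.
#'
#' @param sessions list of \linkS4class{SessionRecord} (or simulator
#'   list(session=, truth=) pairs).
#' @param stride keep every stride-th frame (1 = all).
#' @param maxGapS interpolation gap limit, seconds.
#' @param includeDerivatives see \code{\link{angleFeatures}}.
#' @return list(features, subject [factor per row], condition [per row],
#'   flagged, subjects, conditions).
#' @export
featureMatrix <- function(sessions, stride = 3L, maxGapS = 1,
                          includeDerivatives = FALSE) {
  parts <- lapply(sessions, function(s) {
    if (is.list(s)) s <- s$session
    traj <- interpolateTracks(s@trajectory, maxGapS)
    idx <- spanFrames(s@testSpan, traj@fps, nFrames(traj))
    idx <- idx[seq(1L, length(idx), by = stride)]
    af <- angleFeatures(traj, includeDerivatives = includeDerivatives,
                        frames = idx)
    list(F = af$features, flagged = af$flagged,
         subject = s@subjectId, condition = s@condition,
         n = nrow(af$features))
  })
  F <- do.call(rbind, lapply(parts, `[[`, "F"))
  mu <- colMeans(F)
  sdev <- apply(F, 2, stats::sd)
  sdev[sdev == 0] <- 1
  F <- sweep(sweep(F, 2, mu), 2, sdev, `/`)
  subj <- rep(vapply(parts, `[[`, "", "subject"),
              vapply(parts, `[[`, 0L, "n"))
  cond <- rep(vapply(parts, `[[`, "", "condition"),
              vapply(parts, `[[`, 0L, "n"))
  list(features = F, subject = factor(subj, levels = unique(subj)),
       condition = cond,
       flagged = unlist(lapply(parts, `[[`, "flagged")),
       subjects = vapply(parts, `[[`, "", "subject"),
       conditions = vapply(parts, `[[`, "", "condition"))
}

#' PCA reduction to a target explained-variance fraction
#'
#' Principal components of the (already normalized) feature matrix, keeping
#' the smallest number of components whose cumulative explained variance
#' reaches \code{varianceFraction}. Component signs follow a fixed
#' convention (the largest-magnitude loading of each component is positive)
#' so projections are deterministic.
#'
#' @param F numeric feature matrix.
#' @param varianceFraction target cumulative explained variance in (0, 1].
#' @return list(projections, loadings, explainedVariance, k).
#' @export
pcaReduce <- function(F, varianceFraction = 0.95) {
  if (!is.numeric(varianceFraction) || varianceFraction <= 0 ||
      varianceFraction > 1)
    stop("varianceFraction must lie in (0, 1]")
  pc <- stats::prcomp(F, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= varianceFraction - 1e-12)[1]
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  rot <- sweep(pc$rotation, 2, flip, `*`)
  proj <- sweep(pc$x, 2, flip, `*`)
  list(projections = proj[, seq_len(k), drop = FALSE],
       loadings = rot[, seq_len(k), drop = FALSE],
       explainedVariance = ev, k = k)
}

#' Embed projections into two dimensions
#'
#' The embedding is a pluggable contract: two output dimensions, identical
#' inputs and seed give identical output, and nearby points in the input
#' space stay nearby. The default "pca" backend is the deterministic
#' variance-maximizing linear projection to 2-D (fixed sign convention); the
#' "umap" backend runs uwot's UMAP single-threaded with a fixed seed.
#'
#' @param proj numeric matrix of reduced features.
#' @param nNeighbors,minDist manifold parameters (umap backend).
#' @param seed integer seed (umap backend; accepted and ignored by the
#'   deterministic pca backend).
#' @param backend "pca" or "umap".
#' @return numeric matrix [points x 2].
#' @export
embed2d <- function(proj, nNeighbors = 15L, minDist = 0.1, seed = 42L,
                    backend = c("pca", "umap")) {
  backend <- match.arg(backend)
  proj <- as.matrix(proj)
  if (nrow(proj) < nNeighbors + 1L)
    stop("too few frames: need at least nNeighbors + 1 = ", nNeighbors + 1L)
  if (backend == "pca") {
    if (ncol(proj) == 1L) {
      emb <- cbind(dim1 = proj[, 1], dim2 = 0)
      return(emb)
    }
    full <- stats::prcomp(proj, center = TRUE, scale. = FALSE)
    flip <- vapply(1:2, function(j) {
      l <- full$rotation[, j]
      if (l[which.max(abs(l))] < 0) -1 else 1
    }, 0)
    emb <- sweep(full$x[, 1:2, drop = FALSE], 2, flip, `*`)
    colnames(emb) <- c("dim1", "dim2")
    emb
  } else {
    set.seed(seed)
    emb <- uwot::umap(proj, n_neighbors = nNeighbors, min_dist = minDist,
                      n_threads = 1, n_sgd_threads = 1, verbose = FALSE)
    colnames(emb) <- c("dim1", "dim2")
    emb
  }
}

#' Steepest-ascent basin labeling of a density grid
#'
#' Assigns every cell to the local density maximum reached by repeated
#' steepest-ascent moves over the 8-neighborhood. A cell moves to its
#' highest strictly-greater neighbor; ties are broken toward the lower
#' linear (column-major) index. Basins are numbered 1..K by descending peak
#' density (peak ties also toward the lower linear index). Implemented by a
#' vectorized parent-pointer construction with pointer doubling.
#'
#' @param density numeric matrix (finite, non-negative).
#' @return list(labels [same dim, integer], peakIndex, peakDensity).
#' @export
basinLabels <- function(density) {
  n <- nrow(density); m <- ncol(density)
  pad <- matrix(-Inf, n + 2L, m + 2L)
  pad[2:(n + 1), 2:(m + 1)] <- density
  idx <- seq_len(n * m)
  best <- as.vector(density)
  parent <- idx
  # neighbor offsets in ascending linear-index order for the tie rule
  for (dc in c(-1L, 0L, 1L)) for (dr in c(-1L, 0L, 1L)) {
    if (dc == 0L && dr == 0L) next
    nb <- as.vector(pad[(2:(n + 1)) + dr, (2:(m + 1)) + dc])
    upd <- nb > best
    best[upd] <- nb[upd]
    parent[upd] <- idx[upd] + dc * n + dr
  }
  # pointer doubling to the root of each ascent path
  repeat {
    pp <- parent[parent]
    if (identical(pp, parent)) break
    parent <- pp
  }
  roots <- sort(unique(parent))
  ord <- order(-density[roots], roots)
  rank <- integer(length(roots))
  rank[ord] <- seq_along(roots)
  labels <- matrix(rank[match(parent, roots)], n, m)
  list(labels = labels, peakIndex = roots[ord],
       peakDensity = density[roots[ord]])
}

# Binned Gaussian kernel density on a regular grid: 2-D histogram smoothed
# by a separable truncated Gaussian (4 sigma), renormalized to integrate
# to 1 over the grid.
binnedKde2d <- function(x, y, xbreaks, ybreaks, bwx, bwy) {
  nx <- length(xbreaks) - 1L
  ny <- length(ybreaks) - 1L
  ix <- findInterval(x, xbreaks, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ybreaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nx, ny)
  toeplitzKernel <- function(size, sigmaCells) {
    d <- abs(outer(seq_len(size), seq_len(size), `-`))
    K <- stats::dnorm(d, sd = sigmaCells)
    K[d > ceiling(4 * sigmaCells)] <- 0
    K
  }
  cw <- diff(xbreaks)[1]; ch <- diff(ybreaks)[1]
  Kx <- toeplitzKernel(nx, max(bwx / cw, 0.5))
  Ky <- toeplitzKernel(ny, max(bwy / ch, 0.5))
  dens <- Kx %*% counts %*% t(Ky)
  dens / (sum(dens) * cw * ch)
}

#' Watershed segmentation of an embedding's density
#'
#' Estimates a Gaussian kernel density of the embedded points on a regular
#' grid (Scott's rule bandwidth per dimension, times \code{bandwidthFactor})
#' and splits it into regions by watershed: every cell is assigned to the
#' density mode reached by steepest ascent (\code{\link{basinLabels}}), so
#' boundary cells join the steeper-ascent region with ties toward the lower
#' region id. Regions smaller than \code{minRegionAreaFrac} of the occupied
#' cells are merged into the neighboring region with the densest shared
#' boundary, and region ids are renumbered by descending peak density.
#'
#' @param emb numeric matrix [points x 2].
#' @param gridSize grid resolution per axis.
#' @param bandwidthFactor multiplier on the Scott bandwidth.
#' @param minRegionAreaFrac minimum region area as a fraction of occupied
#'   (point-containing) cells.
#' @param pad bounding-box padding fraction.
#' @return A \linkS4class{BehaviorMap}.
#' @export
segmentDensity <- function(emb, gridSize = 200L, bandwidthFactor = 2,
                           minRegionAreaFrac = 0.002, pad = 0.05) {
  emb <- as.matrix(emb)
  if (nrow(emb) < 1L) stop("at least one embedded point required")
  if (bandwidthFactor <= 0) stop("bandwidth must be > 0")
  n <- nrow(emb)
  rng <- apply(emb, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-8)
  lo <- rng[1, ] - pad * span
  hi <- rng[2, ] + pad * span
  xbreaks <- seq(lo[1], hi[1], length.out = gridSize + 1L)
  ybreaks <- seq(lo[2], hi[2], length.out = gridSize + 1L)
  scott <- function(v) stats::sd(v) * n^(-1 / 6)
  bwx <- max(scott(emb[, 1]), 1e-9) * bandwidthFactor
  bwy <- max(scott(emb[, 2]), 1e-9) * bandwidthFactor
  dens <- binnedKde2d(emb[, 1], emb[, 2], xbreaks, ybreaks, bwx, bwy)
  bl <- basinLabels(dens)
  labels <- bl$labels
  # zero-density cells (beyond the truncated kernel's reach) are background;
  # their degenerate singleton basins are ranked last and dropped
  k <- sum(bl$peakDensity > 0)
  labels[dens <= 0 | labels > k] <- 0L
  peakIndex <- bl$peakIndex[seq_len(k)]
  ix <- findInterval(emb[, 1], xbreaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(emb[, 2], ybreaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  cellOf <- (iy - 1L) * gridSize + ix
  occupied <- length(unique(cellOf))
  minCells <- ceiling(minRegionAreaFrac * occupied)
  # merge small regions into the neighbor with the densest shared boundary
  repeat {
    k <- length(peakIndex)
    if (k <= 1L) break
    sizes <- tabulate(labels[labels > 0L], nbins = k)
    small <- which(sizes < minCells)
    if (!length(small)) break
    r <- small[which.min(sizes[small])]
    cells <- which(labels == r)
    rc <- arrayInd(cells, dim(labels))
    bestNb <- 0L; bestD <- -Inf
    for (dc in -1:1) for (dr in -1:1) {
      if (dc == 0L && dr == 0L) next
      ri <- rc[, 1] + dr; ci <- rc[, 2] + dc
      okn <- ri >= 1 & ri <= nrow(labels) & ci >= 1 & ci <= ncol(labels)
      if (!any(okn)) next
      nbl <- labels[cbind(ri[okn], ci[okn])]
      nbd <- dens[cells[okn]]
      other <- nbl != r & nbl > 0L
      if (any(other) && max(nbd[other]) > bestD) {
        bestD <- max(nbd[other])
        bestNb <- nbl[which(other)[which.max(nbd[other])]]
      }
    }
    if (bestNb == 0L) break
    labels[cells] <- bestNb
    peakIndex <- peakIndex[-r]
    labels[labels > r] <- labels[labels > r] - 1L
    ord <- order(-dens[peakIndex], peakIndex)
    relab <- integer(length(ord)); relab[ord] <- seq_along(ord)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    peakIndex <- peakIndex[ord]
  }
  pointRegion <- as.integer(labels[cellOf])
  new("BehaviorMap", embedding = emb, density = dens,
      labels = labels, xgrid = (xbreaks[-1] + xbreaks[-length(xbreaks)]) / 2,
      ygrid = (ybreaks[-1] + ybreaks[-length(ybreaks)]) / 2,
      peakDensity = dens[peakIndex], pointRegion = pointRegion,
      excluded = integer(0))
}

#' Per-subject region occupancy profiles
#'
#' Fraction of each subject's frames falling in every map region (plus a
#' background column for points outside any region); fractions sum to 1 per
#' subject.
#'
#' @param map a \linkS4class{BehaviorMap}.
#' @param subject factor of the same length as the embedded points mapping
#'   each frame to its subject.
#' @return numeric matrix [subjects x regions(+background)].
#' @export
occupancyProfiles <- function(map, subject) {
  if (!is.factor(subject)) subject <- factor(subject)
  if (length(subject) != nrow(map@embedding))
    stop("one subject per embedded point required")
  if (any(table(subject) == 0L))
    stop("subject with 0 frames: ",
         paste(levels(subject)[table(subject) == 0L], collapse = ", "))
  k <- length(map@peakDensity)
  tab <- table(subject, factor(map@pointRegion, levels = 0:k))
  prof <- sweep(unclass(tab), 1, rowSums(tab), `/`)
  colnames(prof) <- c("background", paste0("region_", seq_len(k)))
  prof[, c(paste0("region_", seq_len(k)), "background"), drop = FALSE]
}

#' Flag regions dominated by interpolated or invalid source coordinates
#'
#' Regions whose member frames are built from more than \code{threshold}
#' interpolation-filled source coordinates on average; mirrors excluding map
#' regions that represent outlier/missing tracked points.
#'
#' @param map a \linkS4class{BehaviorMap}.
#' @param flagged per-point fraction of interpolated source coordinates
#'   (from \code{\link{angleFeatures}} / \code{\link{featureMatrix}}).
#' @param threshold mean flagged fraction above which a region is excluded.
#' @return integer region ids.
#' @export
artifactRegions <- function(map, flagged, threshold = 0.5) {
  k <- length(map@peakDensity)
  if (!k) return(integer(0))
  frac <- vapply(seq_len(k), function(r) {
    mem <- map@pointRegion == r
    if (!any(mem)) return(0)
    mean(flagged[mem])
  }, 0)
  which(frac > threshold)
}

#' Region statistics and occupancy decoding
#'
#' Two-tailed independent-samples t tests per non-excluded region comparing
#' the two conditions' occupancy fractions, plus a penalized logistic
#' decoder fitted on the non-excluded occupancy features with coefficients
#' ranked by magnitude.
#'
#' @param profiles occupancy matrix from \code{\link{occupancyProfiles}}.
#' @param labels two-level condition per subject (row).
#' @param excludedRegions integer region ids excluded from tests and
#'   decoding.
#' @param l2Strength decoder ridge penalty.
#' @return list(tests [data.frame], decoder [DecoderReport]).
#' @export
regionStatsAndDecode <- function(profiles, labels,
                                 excludedRegions = integer(0),
                                 l2Strength = 1) {
  regions <- grep("^region_", colnames(profiles), value = TRUE)
  drop <- paste0("region_", excludedRegions)
  keep <- setdiff(regions, drop)
  if (!length(keep)) stop("all regions excluded")
  tests <- do.call(rbind, lapply(keep, function(r) {
    tt <- tryCatch(groupTTest(profiles[, r], labels),
                   error = function(e) list(t = NA, df = NA, p = NA,
                                            estimate = NA, degenerate = TRUE))
    data.frame(region = r, t = tt$t, df = tt$df, p = tt$p,
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  }))
  X <- profiles[, keep, drop = FALSE]
  dec <- fitLogisticDecoder(X, labels, l2Strength = l2Strength)
  list(tests = tests, decoder = dec)
}

#' Default behavior-map parameters
#'
#' @return list of the mapping pipeline's tunables: frame stride,
#'   interpolation gap limit, PCA variance fraction, embedding backend and
#'   parameters, grid size, bandwidth factor, minimum region area and the
#'   artifact-region threshold.
#' @export
mapParams <- function() {
  list(stride = 3L, maxGapS = 1, includeDerivatives = FALSE,
       varianceFraction = 0.95, backend = "pca", nNeighbors = 15L,
       minDist = 0.1, gridSize = 200L, bandwidthFactor = 2,
       minRegionAreaFrac = 0.002, flagThreshold = 0.5)
}

#' Full unsupervised mapping pipeline for a cohort
#'
#' Interpolation, pooled angle features, PCA, 2-D embedding, density
#' watershed, per-subject occupancy, artifact-region flagging and occupancy
#' decoding, end to end and deterministic for a fixed seed.
#'
#' @param sessions list of \linkS4class{SessionRecord} (or simulator pairs).
#' @param params see \code{\link{mapParams}}.
#' @param seed embedding seed.
#' @return list(map, profiles, labels [condition per subject], features,
#'   pca, analysis [regionStatsAndDecode output]).
#' @export
mapCohort <- function(sessions, params = mapParams(), seed = 42L) {
  fm <- featureMatrix(sessions, stride = params$stride,
                      maxGapS = params$maxGapS,
                      includeDerivatives = params$includeDerivatives)
  pca <- pcaReduce(fm$features, params$varianceFraction)
  emb <- embed2d(pca$projections, nNeighbors = params$nNeighbors,
                 minDist = params$minDist, seed = seed,
                 backend = params$backend)
  map <- segmentDensity(emb, gridSize = params$gridSize,
                        bandwidthFactor = params$bandwidthFactor,
                        minRegionAreaFrac = params$minRegionAreaFrac)
  map@excluded <- artifactRegions(map, fm$flagged, params$flagThreshold)
  prof <- occupancyProfiles(map, fm$subject)
  prof <- prof[match(fm$subjects, rownames(prof)), , drop = FALSE]
  analysis <- regionStatsAndDecode(prof, fm$conditions,
                                   excludedRegions = map@excluded)
  list(map = map, profiles = prof, labels = fm$conditions,
       pca = pca, analysis = analysis)
}
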