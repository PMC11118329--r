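#' @include AllClasses.R metrics.R
NULL

#' Default distance bin edges
#'
#' 2-cm bins from zero to the arena diagonal, which bounds any possible
#' nose-to-nose distance.
#'
#' @param arena an \linkS4class{ArenaGeometry}.
#' @param widthCm bin width in cm.
#' @return numeric vector of bin edges.
#' @export
defaultDistanceBins <- function(arena = defaultArena(), widthCm = 2) {
  allv <- rbind(arena@home, arena@tunnel, arena@social)
  diag <- sqrt(diff(range(allv[, 1]))^2 + diff(range(allv[, 2]))^2)
  seq(0, ceiling(diag / widthCm) * widthCm, by = widthCm)
}

#' Threat-imminence profile: behavior rates by nose-to-nose distance bin
#'
#' Assigns every valid-distance test-phase frame to a distance bin. For
#' start-stop behaviors the rate is the fraction of the bin's frames during
#' which the behavior is active; for point events it is events per second of
#' bin time. Bins with no frames are flagged NA rather than zero. Frames
#' where either nose is untracked are excluded (distance is undefined
#' there).
#'
#' @param session a \linkS4class{SessionRecord}.
#' @param distance optional precomputed \code{\link{noseDistanceSeries}}.
#' @param bins increasing bin edges (cm); default
#'   \code{\link{defaultDistanceBins}}.
#' @param behaviors labels to profile; default: every registry behavior
#'   present in the session's log.
#' @return data.frame with one row per bin: edges, frame count, seconds,
#'   and one rate column per behavior.
#' @export
distanceBinProfile <- function(session, distance = NULL, bins = NULL,
                               behaviors = NULL) {
  if (is.null(distance)) distance <- noseDistanceSeries(session@trajectory)
  if (is.null(bins)) bins <- defaultDistanceBins()
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  fps <- frameRate(session)
  n <- nFrames(session)
  idx <- spanFrames(session@testSpan, fps, n)
  idx <- idx[distance$valid[idx]]
  d <- distance$distanceCm[idx]
  inRange <- d >= bins[1] & d < bins[length(bins)]
  idx <- idx[inRange]; d <- d[inRange]
  bin <- findInterval(d, bins)
  nb <- length(bins) - 1L
  frames <- tabulate(bin, nbins = nb)
  ev <- events(session)
  if (is.null(behaviors)) behaviors <- unique(ev$behavior)
  reg <- behaviorRegistry()
  t <- frameTimes(n, fps)
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1],
                    frames = frames, seconds = frames / fps)
  framePos <- integer(n)
  framePos[idx] <- bin
  for (b in behaviors) {
    type <- reg$type[match(b, reg$behavior)]
    if (is.na(type)) stop("unknown behavior label: ", b)
    rate <- rep(NA_real_, nb)
    if (type == "state") {
      act <- logical(n)
      rows <- ev[ev$behavior == b, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        lo <- rows$onset[k]; hi <- rows$offset[k]
        act[t >= lo & t <= hi] <- TRUE
      }
      active <- tabulate(bin[act[idx]], nbins = nb)
      rate[frames > 0] <- active[frames > 0] / frames[frames > 0]
    } else {
      on <- ev$onset[ev$behavior == b]
      fr <- pmin(pmax(floor(on * fps) + 1, 1L), n)
      bi <- framePos[fr]
      cnt <- tabulate(bi[bi > 0], nbins = nb)
      rate[frames > 0] <- cnt[frames > 0] / (frames[frames > 0] / fps)
    }
    out[[gsub(" |-", "_", tolower(b))]] <- rate
  }
  out
}

#' Time-aligned behavior/distance raster of one session
#'
#' The session's behavior intervals and point events on the same time axis
#' as the nose-to-nose distance trace, ready for raster plotting or CSV
#' serialization. Lossless: \code{\link{rasterToEvents}} reconstructs the
#' event log exactly.
#'
#' @param session a \linkS4class{SessionRecord}.
#' @param distance optional precomputed \code{\link{noseDistanceSeries}}.
#' @return list(intervals, points, distance, spans).
#' @export
sessionRaster <- function(session, distance = NULL) {
  if (is.null(distance)) distance <- noseDistanceSeries(session@trajectory)
  ev <- events(session)
  st <- ev$event_type == "state"
  list(intervals = data.frame(behavior = ev$behavior[st],
                              actor = ev$actor[st],
                              onset = ev$onset[st], offset = ev$offset[st],
                              stringsAsFactors = FALSE),
       points = data.frame(behavior = ev$behavior[!st],
                           actor = ev$actor[!st],
                           time = ev$onset[!st], stringsAsFactors = FALSE),
       distance = distance,
       spans = list(baseline = session@baselineSpan,
                    test = session@testSpan))
}

#' Reconstruct an event log from a raster
#' @param raster output of \code{\link{sessionRaster}}.
#' @return An \linkS4class{EventLog}.
#' @export
rasterToEvents <- function(raster) {
  iv <- raster$intervals
  pt <- raster$points
  EventLog(rbind(
    data.frame(behavior = iv$behavior, actor = iv$actor,
               event_type = rep("state", nrow(iv)), onset = iv$onset,
               offset = iv$offset, stringsAsFactors = FALSE),
    data.frame(behavior = pt$behavior, actor = pt$actor,
               event_type = rep("point", nrow(pt)), onset = pt$time,
               offset = rep(NA_real_, nrow(pt)), stringsAsFactors = FALSE)))
}
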