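#' @include AllGenerics.R
NULL

#' @rdname nFrames
#' @export
setMethod("nFrames", "KeypointTrajectory",
          function(x) dim(x@coords)[1L])
#' @rdname nFrames
#' @export
setMethod("nFrames", "SessionRecord", function(x) nFrames(x@trajectory))

#' @rdname frameRate
#' @export
setMethod("frameRate", "KeypointTrajectory", function(x) x@fps)
#' @rdname frameRate
#' @export
setMethod("frameRate", "SessionRecord", function(x) x@trajectory@fps)
#' @rdname frameRate
#' @export
setMethod("frameRate", "ZoneSequence", function(x) x@fps)

#' @rdname coords
#' @export
setMethod("coords", "KeypointTrajectory", function(x) x@coords)

#' @rdname validMask
#' @export
setMethod("validMask", "KeypointTrajectory", function(x) x@valid)

#' @rdname interpolatedMask
#' @export
setMethod("interpolatedMask", "KeypointTrajectory",
          function(x) x@interpolated)

#' @rdname events
#' @export
setMethod("events", "EventLog", function(x) x@events)
#' @rdname events
#' @export
setMethod("events", "SessionRecord", function(x) x@events@events)

#' @rdname zoneLabels
#' @export
setMethod("zoneLabels", "ZoneSequence", function(x) x@zone)

#' @rdname zoneCrossings
#' @export
setMethod("zoneCrossings", "ZoneSequence", function(x) x@crossings)

#' @rdname embedding
#' @export
setMethod("embedding", "BehaviorMap", function(x) x@embedding)

#' @rdname densityGrid
#' @export
setMethod("densityGrid", "BehaviorMap", function(x) x@density)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "BehaviorMap", function(x) x@labels)

#' @rdname regionIds
#' @export
setMethod("regionIds", "BehaviorMap",
          function(x) seq_along(x@peakDensity))

#' @rdname pointRegions
#' @export
setMethod("pointRegions", "BehaviorMap", function(x) x@pointRegion)

#' @rdname excludedRegions
#' @export
setMethod("excludedRegions", "BehaviorMap", function(x) x@excluded)

#' @rdname decoderCoefficients
#' @export
setMethod("decoderCoefficients", "DecoderReport", function(x) {
  stats::setNames(x@coefficients, x@features)
})

#' @rdname trainingAccuracy
#' @export
setMethod("trainingAccuracy", "DecoderReport", function(x) x@accuracy)

setMethod("show", "KeypointTrajectory", function(object) {
  n <- nFrames(object)
  cat("KeypointTrajectory:", n, "frames @", object@fps, "fps,",
      "2 animals x 8 nodes\n")
  cat("  valid cells:",
      sprintf("%.1f%%", 100 * mean(object@valid)), "\n")
  if (any(object@interpolated))
    cat("  interpolated cells:",
        sprintf("%.2f%%", 100 * mean(object@interpolated)), "\n")
})

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat("EventLog:", nrow(ev), "events\n")
  if (nrow(ev)) {
    tab <- table(ev$behavior)
    for (b in names(tab)) cat(sprintf("  %-24s %d\n", b, tab[[b]]))
  }
})

setMethod("show", "SessionRecord", function(object) {
  cat("SessionRecord", object@subjectId,
      sprintf("(%s, %s)\n", object@condition, object@sex))
  cat(sprintf("  baseline [%g, %g) s, test [%g, %g) s\n",
              object@baselineSpan[1], object@baselineSpan[2],
              object@testSpan[1], object@testSpan[2]))
  cat(" ", nFrames(object), "frames,", nrow(events(object)), "events\n")
})

setMethod("show", "ZoneSequence", function(object) {
  cat("ZoneSequence:", length(object@zone), "frames\n")
  tab <- table(factor(object@zone,
                      levels = c("home", "tunnel", "social", "unknown")))
  for (z in names(tab))
    cat(sprintf("  %-8s %5.1f%%\n", z, 100 * tab[[z]] / length(object@zone)))
})

setMethod("show", "BehaviorMap", function(object) {
  cat("BehaviorMap:", nrow(object@embedding), "embedded points,",
      length(object@peakDensity), "watershed regions on a",
      paste(dim(object@density), collapse = " x "), "grid\n")
  if (length(object@excluded))
    cat("  excluded regions:", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "DecoderReport", function(object) {
  cat(sprintf("DecoderReport: %s vs %s, training accuracy %.3f (l2 = %g)\n",
              object@classes[1], object@classes[2], object@accuracy,
              object@l2Strength))
  co <- decoderCoefficients(object)
  co <- co[order(-abs(co))]
  for (i in seq_len(min(10L, length(co))))
    cat(sprintf("  %-28s %+8.4f\n", names(co)[i], co[i]))
  if (length(object@dropped))
    cat("  dropped constant features:",
        paste(object@dropped, collapse = ", "), "\n")
})
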