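#' @import methods
NULL

#' Canonical skeleton node names
#'
#' The eight tracked body points, in fixed order. All trajectory containers
#' use exactly this registry; the nose anchors inter-animal distance and the
#' trunk anchors zone membership.
#'
#' @return Character vector of length 8.
#' @export
nodeRegistry <- function() {
  c("nose", "head", "left_ear", "right_ear",
    "trunk", "left_hip", "right_hip", "tail_base")
}

#' Animal roles in a dyadic session
#'
#' @return Character vector: the experimental subject first, then the
#'   conspecific stimulus animal.
#' @export
animalRegistry <- function() c("experimental", "conspecific")

#' Closed vocabulary of scored behaviors
#'
#' One row per behavior label the event-log reader accepts: the four sniff
#' subtypes, conspecific sniff bouts, tunnel hesitancy behaviors (first
#' tunnel sheltering, reversing), social fear behaviors (social freeze,
#' social reactivity), social initiation, and the non-social behaviors
#' (grooming, non-social freezing, aggression, jumping). `type` is
#' "state" for start-stop behaviors and "point" for instantaneous events;
#' `actor` says which animal the label refers to. Only conspecific sniff is
#' scored on the conspecific. Chamber preference is derived from the
#' trajectory, not from an event label, and the composite "All Sniff" is the
#' sum of the four sniff subtypes.
#'
#' @return data.frame with columns behavior, type, actor.
#' @export
behaviorRegistry <- function() {
  data.frame(
    behavior = c("Face Sniff", "Body Sniff", "Anogenital Sniff", "Tail Sniff",
                 "Conspecific Sniff", "First Tunnel Sheltering",
                 "Reverse in Tunnel", "Social Freeze", "Social Reactivity",
                 "Social Initiation", "Groom", "Non-social Freeze",
                 "Aggression", "Jump"),
    type = c("state", "state", "state", "state",
             "point", "state",
             "state", "state", "point",
             "point", "state", "state",
             "state", "point"),
    actor = c(rep("experimental", 4), "conspecific",
              rep("experimental", 9)),
    stringsAsFactors = FALSE
  )
}

sniffSubtypes <- function() {
  c("Face Sniff", "Body Sniff", "Anogenital Sniff", "Tail Sniff")
}

#' KeypointTrajectory: per-frame dyadic keypoint coordinates
#'
#' Planar coordinates (cm) for 8 skeleton nodes on 2 animals across frames,
#' with a validity mask (FALSE = missing/untracked; coordinates there are NA)
#' and an interpolation mask recording which cells were gap-filled.
#'
#' @slot coords numeric array [frames x 2 animals x 8 nodes x 2 (x,y)], cm.
#' @slot valid logical array [frames x 2 x 8].
#' @slot interpolated logical array [frames x 2 x 8]; TRUE where a cell was
#'   filled by \code{\link{interpolateTracks}}.
#' @slot fps frames per second (> 0).
#' @export
setClass("KeypointTrajectory",
  representation(coords = "array", valid = "array",
                 interpolated = "array", fps = "numeric"))

setValidity("KeypointTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 4L) return("coords must be a 4-d array")
  if (d[2] != 2L) return("exactly 2 animals required")
  if (d[3] != 8L) return("exactly 8 nodes required")
  if (d[4] != 2L) return("last coords dimension must be (x, y)")
  if (!identical(dim(object@valid), d[1:3]))
    return("valid mask dimensions must match coords")
  if (!identical(dim(object@interpolated), d[1:3]))
    return("interpolated mask dimensions must match coords")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  dn <- dimnames(object@coords)
  if (is.null(dn) || !identical(dn[[2]], animalRegistry()) ||
      !identical(dn[[3]], nodeRegistry()))
    return("coords dimnames must carry the animal and node registries")
  # exact but cheap: the non-finite cells must be exactly the invalid ones
  nInvalid <- sum(!object@valid)
  nNonFinite <- sum(!is.finite(object@coords))
  L <- prod(d[1:3])
  bad <- which(!object@valid)
  if (nNonFinite != 2L * nInvalid ||
      (length(bad) && any(is.finite(object@coords[c(bad, bad + L)]))))
    return("coords must be finite wherever valid is TRUE (and NA elsewhere)")
  TRUE
})

#' Construct a KeypointTrajectory
#'
#' @param coords numeric array [frames x 2 x 8 x 2]; dimnames are set from
#'   the registries.
#' @param valid logical array [frames x 2 x 8]; defaults to TRUE wherever
#'   both coordinates are finite.
#' @param fps frames per second.
#' @param interpolated optional logical array marking gap-filled cells.
#' @return A \linkS4class{KeypointTrajectory}.
#' @export
KeypointTrajectory <- function(coords, valid = NULL, fps = 30,
                               interpolated = NULL) {
  dimnames(coords) <- list(NULL, animalRegistry(), nodeRegistry(),
                           c("x", "y"))
  L <- prod(dim(coords)[1:3])
  if (is.null(valid)) {
    fin <- is.finite(coords)
    valid <- fin[seq_len(L)] & fin[L + seq_len(L)]
    dim(valid) <- dim(coords)[1:3]
  }
  bad <- which(!valid)
  if (length(bad)) coords[c(bad, bad + L)] <- NA_real_
  if (is.null(interpolated)) {
    interpolated <- array(FALSE, dim(valid))
  }
  new("KeypointTrajectory", coords = coords, valid = valid,
      interpolated = interpolated, fps = fps)
}

#' EventLog: validated scored behavioral events
#'
#' Start-stop ("state") and instantaneous ("point") events for one session,
#' sorted by onset. Labels are restricted to \code{\link{behaviorRegistry}}.
#'
#' @slot events data.frame with columns behavior, actor, event_type,
#'   onset, offset (seconds from session start; offset is NA for point
#'   events).
#' @export
setClass("EventLog", representation(events = "data.frame"))

setValidity("EventLog", function(object) {
  ev <- object@events
  need <- c("behavior", "actor", "event_type", "onset", "offset")
  if (!all(need %in% names(ev))) return("missing event columns")
  if (nrow(ev) == 0L) return(TRUE)
  reg <- behaviorRegistry()
  bad <- setdiff(unique(ev$behavior), reg$behavior)
  if (length(bad))
    return(paste0("unknown behavior label(s): ", paste(bad, collapse = ", ")))
  m <- match(ev$behavior, reg$behavior)
  if (any(ev$event_type != reg$type[m]))
    return("event_type inconsistent with the behavior registry")
  if (any(ev$actor != reg$actor[m]))
    return("actor inconsistent with the behavior registry (only conspecific sniff is scored on the conspecific)")
  st <- ev$event_type == "state"
  if (any(!is.finite(ev$onset)) || any(ev$onset < 0))
    return("onsets must be finite and non-negative")
  if (any(!is.finite(ev$offset[st])))
    return("state events require a finite offset")
  if (any(ev$offset[st] < ev$onset[st]))
    return("state events require offset >= onset")
  if (any(!is.na(ev$offset[!st])))
    return("point events must not carry an offset")
  if (is.unsorted(ev$onset)) return("events must be sorted by onset")
  TRUE
})

#' Construct an EventLog
#'
#' @param events data.frame with columns behavior, actor, event_type, onset,
#'   offset. Rows are sorted by onset.
#' @return An \linkS4class{EventLog}.
#' @export
EventLog <- function(events = data.frame(behavior = character(),
                                         actor = character(),
                                         event_type = character(),
                                         onset = numeric(),
                                         offset = numeric())) {
  events$onset <- as.numeric(events$onset)
  events$offset <- as.numeric(events$offset)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  new("EventLog", events = events)
}

#' ArenaGeometry: chamber polygons of the two-chamber assay
#'
#' Home chamber, connecting tunnel and social chamber as planar polygons
#' (cm), plus the pixel-to-cm scale of the source video.
#'
#' @slot home,tunnel,social numeric matrices [vertices x 2].
#' @slot pxToCm positive scale factor.
#' @export
setClass("ArenaGeometry",
  representation(home = "matrix", tunnel = "matrix", social = "matrix",
                 pxToCm = "numeric"))

setValidity("ArenaGeometry", function(object) {
  for (nm in c("home", "tunnel", "social")) {
    p <- slot(object, nm)
    if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L)
      return(paste(nm, "polygon must be a numeric matrix with >= 3 vertices"))
  }
  if (object@pxToCm <= 0) return("pxToCm must be > 0")
  polys <- list(object@home, object@tunnel, object@social)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- polys[[i]]; b <- polys[[j]]
    if (any(pointInPolygon(a[, 1], a[, 2], b, strict = TRUE)) ||
        any(pointInPolygon(b[, 1], b[, 2], a, strict = TRUE)) ||
        pointInPolygon(mean(a[, 1]), mean(a[, 2]), b) ||
        pointInPolygon(mean(b[, 1]), mean(b[, 2]), a))
      return("chamber polygons must not overlap")
  }
  TRUE
})

#' Construct an ArenaGeometry
#' @param home,tunnel,social vertex matrices [n x 2] in cm.
#' @param pxToCm pixel-to-cm scale (> 0).
#' @return An \linkS4class{ArenaGeometry}.
#' @export
ArenaGeometry <- function(home, tunnel, social, pxToCm = 1) {
  new("ArenaGeometry", home = as.matrix(home), tunnel = as.matrix(tunnel),
      social = as.matrix(social), pxToCm = pxToCm)
}

rectPoly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Default arena geometry
#'
#' A 30 x 30 cm home chamber, a 15 x 8 cm tunnel, and a 30 x 30 cm social
#' chamber laid out left to right (origin at the top-left of the overhead
#' view, x rightward, y downward, cm).
#'
#' @return An \linkS4class{ArenaGeometry}.
#' @export
defaultArena <- function() {
  ArenaGeometry(home = rectPoly(0, 0, 30, 30),
                tunnel = rectPoly(30, 11, 45, 19),
                social = rectPoly(45, 0, 75, 30),
                pxToCm = 1)
}

#' SessionRecord: one assay session
#'
#' Bundles the trajectory and scored events of a single subject together
#' with its identity, condition label and the phase structure: a solo
#' baseline (default 180 s) followed by a dyadic test (default 600 s).
#'
#' @slot subjectId,sex,condition character scalars.
#' @slot baselineSpan,testSpan numeric [t0, t1] in seconds.
#' @slot trajectory a \linkS4class{KeypointTrajectory}.
#' @slot events an \linkS4class{EventLog}.
#' @export
setClass("SessionRecord",
  representation(subjectId = "character", sex = "character",
                 condition = "character", baselineSpan = "numeric",
                 testSpan = "numeric", trajectory = "KeypointTrajectory",
                 events = "EventLog"))

setValidity("SessionRecord", function(object) {
  if (!nzchar(object@condition)) return("condition label must be non-empty")
  if (length(object@baselineSpan) != 2L || length(object@testSpan) != 2L)
    return("phase spans must be [t0, t1]")
  if (diff(object@baselineSpan) < 0 || diff(object@testSpan) < 0)
    return("phase spans must have t1 >= t0")
  if (object@baselineSpan[2] > object@testSpan[1])
    return("baseline must end before the test phase begins")
  TRUE
})

#' Construct a SessionRecord
#' @param subjectId,sex,condition identifiers.
#' @param trajectory a \linkS4class{KeypointTrajectory}.
#' @param events an \linkS4class{EventLog}.
#' @param baselineSpan,testSpan phase spans [t0, t1] in seconds.
#' @return A \linkS4class{SessionRecord}.
#' @export
SessionRecord <- function(subjectId, condition, trajectory, events,
                          sex = "F", baselineSpan = c(0, 180),
                          testSpan = c(180, 780)) {
  new("SessionRecord", subjectId = subjectId, sex = sex,
      condition = condition, baselineSpan = as.numeric(baselineSpan),
      testSpan = as.numeric(testSpan), trajectory = trajectory,
      events = events)
}

#' GroundTruth: generator-side record of a simulated session
#'
#' Holds the realized per-frame behavioral state of each animal, the true
#' condition label, and summary statistics accumulated by the simulator
#' itself with code independent of the ethogram metric functions, so the
#' metrics can be checked against them exactly.
#'
#' @slot states character matrix [frames x 2 animals].
#' @slot condition character scalar.
#' @slot summaries named numeric vector of per-behavior summaries.
#' @export
setClass("GroundTruth",
  representation(states = "matrix", condition = "character",
                 summaries = "numeric"))

setValidity("GroundTruth", function(object) {
  if (ncol(object@states) != 2L) return("states must have 2 animal columns")
  if (is.null(names(object@summaries))) return("summaries must be named")
  TRUE
})

#' ZoneSequence: per-frame chamber membership
#'
#' @slot zone character vector, one of home/tunnel/social/unknown per frame.
#' @slot fps frames per second.
#' @slot crossings data.frame(frame, time, zone, prev): transitions between
#'   known zones (unknown frames inherit the last known zone).
#' @export
setClass("ZoneSequence",
  representation(zone = "character", fps = "numeric",
                 crossings = "data.frame"))

#' BehaviorMap: density-watershed segmentation of an embedding
#'
#' @slot embedding numeric matrix [points x 2].
#' @slot density numeric matrix [grid x grid], normalized so that
#'   sum(density) * cellArea = 1.
#' @slot labels integer matrix of watershed region ids (0 = background),
#'   regions numbered 1..K by descending peak density.
#' @slot xgrid,ygrid cell-center coordinates.
#' @slot peakDensity numeric, per-region peak density (descending).
#' @slot pointRegion integer region id per embedded point.
#' @slot excluded integer ids of regions flagged for exclusion from decoding.
#' @export
setClass("BehaviorMap",
  representation(embedding = "matrix", density = "matrix",
                 labels = "matrix", xgrid = "numeric", ygrid = "numeric",
                 peakDensity = "numeric", pointRegion = "integer",
                 excluded = "integer"))

setValidity("BehaviorMap", function(object) {
  if (ncol(object@embedding) != 2L) return("embedding must be 2-D")
  if (!identical(dim(object@density), dim(object@labels)))
    return("density and label grids must align")
  if (any(object@density < 0)) return("density must be non-negative")
  k <- length(object@peakDensity)
  if (k && any(object@labels > k)) return("label ids exceed region count")
  if (length(object@pointRegion) != nrow(object@embedding))
    return("one region per embedded point required")
  TRUE
})

#' DecoderReport: penalized logistic decoder fit summary
#'
#' @slot features feature names (after dropping constant columns).
#' @slot coefficients standardized-feature coefficients, one per feature.
#' @slot intercept scalar intercept.
#' @slot accuracy training accuracy in [0, 1].
#' @slot l2Strength ridge penalty used.
#' @slot classes the two class labels; the second is modeled as 1.
#' @slot converged,iterations,gradNorm optimizer diagnostics.
#' @slot dropped names of constant features removed before fitting.
#' @export
setClass("DecoderReport",
  representation(features = "character", coefficients = "numeric",
                 intercept = "numeric", accuracy = "numeric",
                 l2Strength = "numeric", classes = "character",
                 converged = "logical", iterations = "integer",
                 gradNorm = "numeric", dropped = "character"))

setValidity("DecoderReport", function(object) {
  if (length(object@coefficients) != length(object@features))
    return("one coefficient per feature required")
  if (object@accuracy < 0 || object@accuracy > 1)
    return("accuracy must lie in [0, 1]")
  TRUE
})
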