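#' @include AllClasses.R utils-geometry.R
NULL

#' Classify per-frame chamber membership
#'
#' Assigns each frame of the experimental animal's reference node to home,
#' tunnel or social chamber by point-in-polygon membership; frames where the
#' reference node is untracked are "unknown", as are points outside every
#' chamber. Crossings are transitions between known zones (unknown frames
#' inherit the last known zone).
#'
#' @param traj a \linkS4class{KeypointTrajectory}.
#' @param arena an \linkS4class{ArenaGeometry}.
#' @param reference node name used for membership; the trunk is the default
#'   single-node surrogate for whole-body chamber entry.
#' @return A \linkS4class{ZoneSequence}.
#' @export
classifyZones <- function(traj, arena, reference = "trunk") {
  ni <- match(reference, nodeRegistry())
  if (is.na(ni)) stop("unknown reference node: ", reference)
  x <- traj@coords[, 1, ni, 1]
  y <- traj@coords[, 1, ni, 2]
  ok <- traj@valid[, 1, ni]
  zone <- rep("unknown", length(x))
  idx <- which(ok)
  if (length(idx)) {
    px <- x[idx]; py <- y[idx]
    z <- rep("unknown", length(idx))
    z[pointInPolygon(px, py, arena@home)] <- "home"
    z[pointInPolygon(px, py, arena@tunnel)] <- "tunnel"
    z[pointInPolygon(px, py, arena@social)] <- "social"
    zone[idx] <- z
  }
  # carry last known zone across unknown frames to detect crossings
  filled <- zone
  known <- filled != "unknown"
  if (any(known)) {
    lastKnown <- cummax(ifelse(known, seq_along(filled), 0L))
    has <- lastKnown > 0L
    filled[has] <- filled[lastKnown[has]]
  }
  chg <- which(known & c(TRUE, filled[-1] != filled[-length(filled)]))
  chg <- chg[filled[chg] != "unknown"]
  crossings <- data.frame(
    frame = chg,
    time = (chg - 1) / traj@fps,
    zone = filled[chg],
    prev = c("none", filled[chg])[seq_along(chg)],
    stringsAsFactors = FALSE)
  new("ZoneSequence", zone = zone, fps = traj@fps, crossings = crossings)
}

behaviorType <- function(behavior) {
  if (behavior == "All Sniff") return("state")
  reg <- behaviorRegistry()
  i <- match(behavior, reg$behavior)
  if (is.na(i)) stop("unknown behavior label: ", behavior)
  reg$type[i]
}

#' Total duration of a start-stop behavior within a span
#'
#' Sums the overlap of the behavior's intervals with the half-open span
#' [t0, t1). "All Sniff" is the sum over the four sniff subtypes.
#'
#' @param log an \linkS4class{EventLog}.
#' @param behavior a state-type label or "All Sniff".
#' @param span numeric [t0, t1] seconds.
#' @return seconds.
#' @export
stateDuration <- function(log, behavior, span) {
  if (behavior == "All Sniff")
    return(sum(vapply(sniffSubtypes(), stateDuration, 0, log = log,
                      span = span)))
  if (behaviorType(behavior) != "state")
    stop("type error: \"", behavior, "\" is a point event, not start-stop")
  ev <- events(log)
  ev <- ev[ev$behavior == behavior, , drop = FALSE]
  intervalOverlap(ev$onset, ev$offset, span)
}

#' Count point events of a behavior within a span
#'
#' Events with onset in the half-open span [t0, t1); an event exactly at the
#' span end is excluded.
#'
#' @inheritParams stateDuration
#' @param behavior a point-type label.
#' @return integer count.
#' @export
pointCount <- function(log, behavior, span) {
  if (behaviorType(behavior) != "point")
    stop("type error: \"", behavior, "\" is start-stop, not a point event")
  ev <- events(log)
  sum(ev$behavior == behavior & ev$onset >= span[1] & ev$onset < span[2])
}

#' Social reactivity as a percentage of conspecific sniff bouts
#'
#' 100 x reactivity events / conspecific sniff events within the span. With
#' zero conspecific sniffs the ratio is undefined and NA is returned (a
#' flagged value, not an error); downstream z-scoring skips it.
#'
#' @inheritParams stateDuration
#' @return percent, or NA when no conspecific sniff occurred.
#' @export
socialReactivityPct <- function(log, span) {
  cs <- pointCount(log, "Conspecific Sniff", span)
  if (cs == 0L) return(NA_real_)
  100 * pointCount(log, "Social Reactivity", span) / cs
}

#' Social chamber preference
#'
#' 100 x social-chamber time / span length. Tunnel and unknown frames count
#' in the denominator only.
#'
#' @param zones a \linkS4class{ZoneSequence}.
#' @param span numeric [t0, t1] seconds.
#' @return percent in [0, 100].
#' @export
chamberPreferencePct <- function(zones, span) {
  idx <- spanFrames(span, zones@fps, length(zones@zone))
  if (!length(idx)) stop("span contains no frames")
  100 * mean(zones@zone[idx] == "social")
}

#' Tunnel hesitancy metrics
#'
#' First tunnel sheltering sums every "First Tunnel Sheltering" interval
#' preceding the first social-chamber entry (there can be several bouts
#' before entering); reversing metrics come from "Reverse in Tunnel" events;
#' latency is the time from span start to the first social-zone entry. When
#' the animal never enters, latency is NA (flagged "never") and all shelter
#' time counts.
#'
#' @param log an \linkS4class{EventLog}.
#' @param zones a \linkS4class{ZoneSequence} for the same session.
#' @param span the test span [t0, t1].
#' @return list(firstShelterS, reverseCount, reverseS, latencyToSocialS,
#'   neverEntered).
#' @export
tunnelHesitancy <- function(log, zones, span) {
  cr <- zones@crossings
  ent <- cr$time[cr$zone == "social" & cr$time >= span[1] & cr$time < span[2]]
  firstEntry <- if (length(ent)) min(ent) else NA_real_
  cutoff <- if (is.na(firstEntry)) span[2] else firstEntry
  ev <- events(log)
  sh <- ev[ev$behavior == "First Tunnel Sheltering" & ev$onset < cutoff, ,
           drop = FALSE]
  firstShelter <- intervalOverlap(sh$onset, pmin(sh$offset, cutoff), span)
  rv <- ev[ev$behavior == "Reverse in Tunnel", , drop = FALSE]
  inSpan <- rv$onset >= span[1] & rv$onset < span[2]
  list(firstShelterS = firstShelter,
       reverseCount = sum(inSpan),
       reverseS = intervalOverlap(rv$onset[inSpan], rv$offset[inSpan], span),
       latencyToSocialS = if (is.na(firstEntry)) NA_real_ else
         firstEntry - span[1],
       neverEntered = is.na(firstEntry))
}

#' Per-frame nose-to-nose distance
#'
#' Euclidean distance between the two animals' noses, NA (invalid) wherever
#' either nose is untracked.
#'
#' @param traj a \linkS4class{KeypointTrajectory}.
#' @return data.frame(frame, time, distanceCm, valid).
#' @export
noseDistanceSeries <- function(traj) {
  ni <- match("nose", nodeRegistry())
  dx <- traj@coords[, 1, ni, 1] - traj@coords[, 2, ni, 1]
  dy <- traj@coords[, 1, ni, 2] - traj@coords[, 2, ni, 2]
  ok <- traj@valid[, 1, ni] & traj@valid[, 2, ni]
  d <- sqrt(dx^2 + dy^2)
  d[!ok] <- NA_real_
  data.frame(frame = seq_len(nFrames(traj)),
             time = frameTimes(nFrames(traj), traj@fps),
             distanceCm = d, valid = ok)
}

#' Score one session into a behavior table row
#'
#' Fills every column of the behavior score table: sniffing durations and
#' their "All Sniff" sum, conspecific sniff bouts, social reactivity,
#' social freezing, tunnel hesitancy (first sheltering, reversing, latency),
#' prosocial initiations, chamber preference, grooming, non-social freezing
#' on both phases, aggression, jumps, and baseline thigmotaxis (fraction of
#' valid baseline frames with the trunk within \code{wallMarginCm} of the
#' home-chamber wall). Social metrics use the test span, baseline metrics
#' the baseline span; undefined ratios propagate as NA.
#'
#' @param session a \linkS4class{SessionRecord}.
#' @param arena an \linkS4class{ArenaGeometry}.
#' @param wallMarginCm thigmotaxis wall distance threshold (cm).
#' @return one-row data.frame with the columns of \code{scoreColumns()}.
#' @export
scoreSession <- function(session, arena, wallMarginCm = 2) {
  log <- session@events
  test <- session@testSpan
  base <- session@baselineSpan
  traj <- session@trajectory
  zones <- classifyZones(traj, arena)
  hes <- tunnelHesitancy(log, zones, test)
  # thigmotaxis on valid baseline frames
  ti <- match("trunk", nodeRegistry())
  bidx <- spanFrames(base, traj@fps, nFrames(traj))
  bok <- bidx[traj@valid[bidx, 1, ti]]
  thig <- if (length(bok)) {
    d <- distanceToBoundary(traj@coords[bok, 1, ti, 1],
                            traj@coords[bok, 1, ti, 2], arena@home)
    100 * mean(d <= wallMarginCm)
  } else NA_real_
  data.frame(
    subject_id = session@subjectId,
    sex = session@sex,
    condition = session@condition,
    face_sniff_s = stateDuration(log, "Face Sniff", test),
    body_sniff_s = stateDuration(log, "Body Sniff", test),
    anogenital_sniff_s = stateDuration(log, "Anogenital Sniff", test),
    tail_sniff_s = stateDuration(log, "Tail Sniff", test),
    all_sniff_s = stateDuration(log, "All Sniff", test),
    conspecific_sniff_bouts = pointCount(log, "Conspecific Sniff", test),
    social_reactivity_pct = socialReactivityPct(log, test),
    social_freeze_s = stateDuration(log, "Social Freeze", test),
    first_tunnel_shelter_s = hes$firstShelterS,
    reverse_count = hes$reverseCount,
    reverse_s = hes$reverseS,
    latency_to_social_s = hes$latencyToSocialS,
    prosocial_initiations = pointCount(log, "Social Initiation", test),
    chamber_preference_pct = chamberPreferencePct(zones, test),
    groom_s = stateDuration(log, "Groom", test),
    nonsocial_freeze_baseline_s = stateDuration(log, "Non-social Freeze", base),
    nonsocial_freeze_test_s = stateDuration(log, "Non-social Freeze", test),
    aggression_s = stateDuration(log, "Aggression", test),
    jump_count = pointCount(log, "Jump", test),
    thigmotaxis_pct = thig,
    stringsAsFactors = FALSE)
}

#' Score every session of a cohort
#'
#' @param sessions list of \linkS4class{SessionRecord} (or of
#'   list(session=, truth=) pairs as returned by the simulator).
#' @param arena an \linkS4class{ArenaGeometry}.
#' @param wallMarginCm thigmotaxis threshold, see \code{\link{scoreSession}}.
#' @return data.frame, one row per subject.
#' @export
scoreCohort <- function(sessions, arena = defaultArena(), wallMarginCm = 2) {
  rows <- lapply(sessions, function(s) {
    if (is.list(s)) s <- s$session
    scoreSession(s, arena, wallMarginCm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
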