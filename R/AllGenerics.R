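#' @include AllClasses.R
NULL

#' Number of frames in a trajectory
#' @param x a KeypointTrajectory or SessionRecord.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame rate accessor
#' @param x a KeypointTrajectory, SessionRecord or ZoneSequence.
#' @return frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Coordinate array accessor
#' @param x a KeypointTrajectory.
#' @return numeric array [frames x animal x node x (x,y)] in cm.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Validity mask accessor
#' @param x a KeypointTrajectory.
#' @return logical array [frames x animal x node].
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Interpolation mask accessor
#' @param x a KeypointTrajectory.
#' @return logical array marking gap-filled cells.
#' @export
setGeneric("interpolatedMask", function(x) standardGeneric("interpolatedMask"))

#' Event table accessor
#' @param x an EventLog or SessionRecord.
#' @return data.frame of events sorted by onset.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Zone label accessor
#' @param x a ZoneSequence.
#' @return character vector of per-frame zone labels.
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))

#' Zone crossing accessor
#' @param x a ZoneSequence.
#' @return data.frame(frame, time, zone, prev) of known-zone transitions.
#' @export
setGeneric("zoneCrossings", function(x) standardGeneric("zoneCrossings"))

#' Embedding coordinates of a behavior map
#' @param x a BehaviorMap.
#' @return numeric matrix [points x 2].
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' Density grid of a behavior map
#' @param x a BehaviorMap.
#' @return numeric matrix.
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

#' Watershed label grid of a behavior map
#' @param x a BehaviorMap.
#' @return integer matrix (0 = background).
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Region ids of a behavior map
#' @param x a BehaviorMap.
#' @return integer vector 1..K (ordered by descending peak density).
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Region membership of each embedded point
#' @param x a BehaviorMap.
#' @return integer vector of region ids per point (0 = background).
#' @export
setGeneric("pointRegions", function(x) standardGeneric("pointRegions"))

#' Excluded-region accessor
#' @param x a BehaviorMap.
#' @return integer vector of region ids flagged for exclusion.
#' @export
setGeneric("excludedRegions", function(x) standardGeneric("excludedRegions"))

#' Decoder coefficient accessor
#' @param x a DecoderReport.
#' @return named numeric vector of standardized-feature coefficients.
#' @export
setGeneric("decoderCoefficients",
           function(x) standardGeneric("decoderCoefficients"))

#' Decoder training accuracy accessor
#' @param x a DecoderReport.
#' @return training accuracy in [0, 1].
#' @export
setGeneric("trainingAccuracy", function(x) standardGeneric("trainingAccuracy"))
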