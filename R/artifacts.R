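#' @include AllClasses.R
NULL

#' Exchange the two animals' coordinates over frame windows
#'
#' Applying the same windows twice restores the original trajectory
#' (swapping is an involution), which is how corrected tracks are modeled.
#'
#' @param traj a \linkS4class{KeypointTrajectory}.
#' @param windows data.frame(start, end) of frame windows (inclusive).
#' @return A \linkS4class{KeypointTrajectory}.
#' @export
swapWindows <- function(traj, windows) {
  co <- traj@coords; valid <- traj@valid; interp <- traj@interpolated
  for (k in seq_len(nrow(windows))) {
    idx <- windows$start[k]:windows$end[k]
    tmp <- co[idx, 1, , , drop = FALSE]
    co[idx, 1, , ] <- co[idx, 2, , , drop = FALSE]
    co[idx, 2, , ] <- tmp
    tmpv <- valid[idx, 1, , drop = FALSE]
    valid[idx, 1, ] <- valid[idx, 2, , drop = FALSE]
    valid[idx, 2, ] <- tmpv
    tmpi <- interp[idx, 1, , drop = FALSE]
    interp[idx, 1, ] <- interp[idx, 2, , drop = FALSE]
    interp[idx, 2, ] <- tmpi
  }
  new("KeypointTrajectory", coords = co, valid = valid,
      interpolated = interp, fps = traj@fps)
}

#' Inject tracking artifacts into a trajectory
#'
#' Models the defects of real multi-animal pose tracking: random coordinate
#' cells marked missing at \code{missingRate}, and identity swaps — the two
#' animals' coordinates exchanged over random contiguous windows (geometric
#' lengths, mean ~1 s at 30 fps) covering about \code{swapRate} of frames.
#' The swap windows are returned so tests can verify that re-swapping
#' restores the original trajectory.
#'
#' @param traj a \linkS4class{KeypointTrajectory}.
#' @param missingRate per-cell missing probability in [0, 1].
#' @param swapRate expected fraction of frames with swapped identities.
#' @param seed integer seed.
#' @return list(trajectory, windows) with windows a data.frame(start, end).
#' @export
injectArtifacts <- function(traj, missingRate = 0, swapRate = 0, seed = 1L) {
  stopifnot(missingRate >= 0, missingRate <= 1, swapRate >= 0, swapRate <= 1)
  if (missingRate == 0 && swapRate == 0)
    return(list(trajectory = traj, windows = data.frame(start = integer(),
                                                        end = integer())))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  n <- nFrames(traj)
  windows <- data.frame(start = integer(), end = integer())
  if (swapRate > 0) {
    meanLen <- 30
    nW <- max(if (swapRate > 0) 1L else 0L,
              stats::rpois(1, n * swapRate / meanLen))
    starts <- sort(sample.int(n, min(nW, n)))
    lens <- stats::rgeom(length(starts), 1 / meanLen) + 1L
    ends <- pmin(starts + lens - 1L, n)
    keep <- !duplicated(starts)
    windows <- data.frame(start = starts[keep], end = ends[keep])
    # drop overlapping windows so re-swapping is a clean involution
    if (nrow(windows) > 1L) {
      ok <- rep(TRUE, nrow(windows))
      lastEnd <- windows$end[1]
      for (k in 2:nrow(windows)) {
        if (windows$start[k] <= lastEnd) ok[k] <- FALSE
        else lastEnd <- windows$end[k]
      }
      windows <- windows[ok, , drop = FALSE]
    }
    traj <- swapWindows(traj, windows)
  }
  if (missingRate > 0) {
    valid <- traj@valid
    hit <- array(stats::runif(length(valid)) < missingRate, dim(valid))
    valid[hit] <- FALSE
    co <- traj@coords
    co[, , , 1][!valid] <- NA_real_
    co[, , , 2][!valid] <- NA_real_
    traj <- new("KeypointTrajectory", coords = co, valid = valid,
                interpolated = traj@interpolated, fps = traj@fps)
  }
  list(trajectory = traj, windows = windows)
}

#' Write a simulated cohort to disk
#'
#' One directory per session (keypoints + events + ground-truth summaries)
#' plus a cohort manifest JSON.
#'
#' @param cohort list of list(session=, truth=) from
#'   \code{\link{simulateCohort}}.
#' @param dir output directory (created).
#' @param schema keypoint dialect, see \code{\link{writeKeypoints}}.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, schema = "wide-csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(s) {
    sess <- s$session
    sdir <- file.path(dir, sess@subjectId)
    dir.create(sdir, showWarnings = FALSE)
    kp <- file.path(sdir, if (schema == "wide-csv") "keypoints.csv"
                    else "keypoints.h5")
    writeKeypoints(sess@trajectory, kp, schema)
    writeEvents(sess@events, file.path(sdir, "events.csv"))
    jsonlite::write_json(as.list(s$truth@summaries),
                         file.path(sdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    list(subject_id = sess@subjectId, sex = sess@sex,
         condition = sess@condition,
         baseline = sess@baselineSpan, test = sess@testSpan,
         fps = frameRate(sess), keypoints = basename(kp),
         events = "events.csv", schema = schema)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by \code{\link{writeCohort}}
#' @param dir cohort directory containing manifest.json.
#' @return list of \linkS4class{SessionRecord}.
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  lapply(manifest, function(m) {
    sdir <- file.path(dir, m$subject_id)
    traj <- readKeypoints(file.path(sdir, m$keypoints), m$schema,
                          fps = m$fps)
    SessionRecord(m$subject_id, m$condition, traj,
                  readEvents(file.path(sdir, m$events)), sex = m$sex,
                  baselineSpan = unlist(m$baseline),
                  testSpan = unlist(m$test))
  })
}
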