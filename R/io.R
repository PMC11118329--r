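#' @include AllClasses.R
NULL

kpColumnNames <- function() {
  ans <- "frame"
  for (a in animalRegistry())
    for (n in nodeRegistry())
      ans <- c(ans, paste(a, n, "x", sep = "."), paste(a, n, "y", sep = "."))
  ans
}

#' Read a keypoint trajectory file
#'
#' Two dialects are supported. \code{"wide-csv"}: one row per frame with a
#' \code{frame} column followed by \code{<animal>.<node>.x/.y} columns for
#' both animals and all eight registry nodes; empty/NaN cells mark missing
#' points. \code{"hdf5-tracks"}: an HDF5 file with datasets \code{tracks}
#' [animal x frame x node x 2], \code{node_names}, \code{track_names} and
#' optionally \code{fps}. Coordinates are rescaled to cm by \code{pxToCm}.
#'
#' @param path file path.
#' @param schema "wide-csv" or "hdf5-tracks".
#' @param fps frames per second to stamp on the trajectory (wide-csv has no
#'   fps record; for hdf5-tracks a stored \code{fps} dataset wins).
#' @param pxToCm scale factor applied to raw coordinates.
#' @return A \linkS4class{KeypointTrajectory} with the validity mask FALSE
#'   wherever a coordinate was missing.
#' @export
readKeypoints <- function(path, schema = c("wide-csv", "hdf5-tracks"),
                          fps = 30, pxToCm = 1) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("keypoint file not found: ", path)
  if (pxToCm <= 0) stop("pxToCm must be > 0")
  if (schema == "wide-csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    want <- kpColumnNames()
    if (!identical(names(df), want)) {
      miss <- setdiff(want, names(df))
      if (length(miss))
        stop("keypoint schema error: missing column(s) ",
             paste(utils::head(miss, 3), collapse = ", "))
      stop("keypoint schema error: unexpected column layout")
    }
    if (nrow(df) == 0L) stop("keypoint format error: no frames in ", path)
    fr <- df$frame
    if (anyNA(fr) || is.unsorted(fr, strictly = TRUE))
      stop("keypoint format error: frame index not strictly increasing at row ",
           which(is.na(fr) | c(FALSE, diff(fr) <= 0))[1])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop("keypoint format error: non-numeric coordinate at row ",
           which(!stats::complete.cases(suppressWarnings(
         apply(df[, -1, drop = FALSE], 2, as.numeric))))[1])
    n <- nrow(m)
    co <- array(NA_real_, c(n, 2, 8, 2))
    k <- 0L
    for (a in 1:2) for (nd in 1:8) {
      co[, a, nd, 1] <- m[, k + 1L]
      co[, a, nd, 2] <- m[, k + 2L]
      k <- k + 2L
    }
    KeypointTrajectory(co * pxToCm, fps = fps)
  } else {
    cont <- tryCatch(rhdf5::h5ls(path), error = function(e)
      stop("keypoint format error: not a readable HDF5 file: ", path))
    need <- c("tracks", "node_names", "track_names")
    miss <- setdiff(need, cont$name)
    if (length(miss))
      stop("keypoint format error: missing dataset(s) ",
           paste(miss, collapse = ", "))
    tr <- rhdf5::h5read(path, "tracks")
    nodes <- as.character(rhdf5::h5read(path, "node_names"))
    tracks <- as.character(rhdf5::h5read(path, "track_names"))
    if ("fps" %in% cont$name) fps <- as.numeric(rhdf5::h5read(path, "fps"))
    if (length(tracks) != 2L || dim(tr)[1] != 2L)
      stop("keypoint schema error: expected exactly 2 tracks, found ",
           max(length(tracks), dim(tr)[1]))
    if (length(nodes) != 8L || dim(tr)[3] != 8L)
      stop("keypoint schema error: expected exactly 8 nodes, found ",
           max(length(nodes), dim(tr)[3]))
    if (!identical(sort(nodes), sort(nodeRegistry())))
      stop("keypoint schema error: node names do not match the registry")
    n <- dim(tr)[2]
    co <- array(NA_real_, c(n, 2, 8, 2))
    ord <- match(nodeRegistry(), nodes)
    for (a in 1:2) for (nd in 1:8) {
      co[, a, nd, 1] <- tr[a, , ord[nd], 1]
      co[, a, nd, 2] <- tr[a, , ord[nd], 2]
    }
    KeypointTrajectory(co * pxToCm, fps = fps)
  }
}

#' Write a keypoint trajectory file
#'
#' Inverse of \code{\link{readKeypoints}}; missing cells are written as NA
#' (CSV) or NaN (HDF5) so the validity mask round-trips exactly.
#'
#' @param traj a \linkS4class{KeypointTrajectory}.
#' @param path output path.
#' @param schema "wide-csv" or "hdf5-tracks".
#' @return \code{path}, invisibly.
#' @export
writeKeypoints <- function(traj, path, schema = c("wide-csv", "hdf5-tracks")) {
  schema <- match.arg(schema)
  co <- traj@coords
  n <- nFrames(traj)
  if (schema == "wide-csv") {
    out <- data.frame(frame = seq_len(n))
    for (a in 1:2) for (nd in 1:8) {
      out[[paste(animalRegistry()[a], nodeRegistry()[nd], "x", sep = ".")]] <-
        co[, a, nd, 1]
      out[[paste(animalRegistry()[a], nodeRegistry()[nd], "y", sep = ".")]] <-
        co[, a, nd, 2]
    }
    utils::write.csv(out, path, row.names = FALSE, na = "NaN")
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    tr <- array(NaN, c(2, n, 8, 2))
    for (a in 1:2) for (nd in 1:8) {
      tr[a, , nd, 1] <- co[, a, nd, 1]
      tr[a, , nd, 2] <- co[, a, nd, 2]
    }
    rhdf5::h5write(tr, path, "tracks")
    rhdf5::h5write(nodeRegistry(), path, "node_names")
    rhdf5::h5write(animalRegistry(), path, "track_names")
    rhdf5::h5write(traj@fps, path, "fps")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Read a scored event log
#'
#' CSV with columns behavior, actor, event_type, onset, offset. Labels are
#' validated against \code{\link{behaviorRegistry}}; state events require
#' offset >= onset, point events must leave offset empty.
#'
#' @param path CSV path.
#' @return An \linkS4class{EventLog} sorted by onset.
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("behavior", "actor", "event_type", "onset", "offset")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(EventLog())
  reg <- behaviorRegistry()
  bad <- which(!(df$behavior %in% reg$behavior))
  if (length(bad))
    stop("vocabulary error: unknown behavior \"", df$behavior[bad[1]],
         "\" at row ", bad[1])
  st <- df$event_type == "state"
  viol <- which(st & (is.na(df$offset) | df$offset < df$onset))
  if (length(viol))
    stop("record error: offset < onset (or missing) at row ", viol[1])
  df$offset[!st] <- NA_real_
  EventLog(df[, need])
}

#' Write a scored event log
#' @param log an \linkS4class{EventLog}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(log, path) {
  utils::write.csv(events(log), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a session configuration
#'
#' JSON document with optional keys \code{fps}, \code{baseline} ([t0, t1]),
#' \code{test} ([t0, t1]), \code{px_to_cm} and \code{arena} (each chamber a
#' vertex list). Absent keys fall back to the defaults: 30 fps, a 180 s
#' baseline, a 600 s test, unit scale and \code{\link{defaultArena}}.
#'
#' @param path JSON path, or NULL for the all-defaults configuration.
#' @return list(arena, baselineSpan, testSpan, fps, pxToCm).
#' @export
loadSessionConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else jsonlite::fromJSON(path)
  fps <- if (!is.null(cfg$fps)) cfg$fps else 30
  pxToCm <- if (!is.null(cfg$px_to_cm)) cfg$px_to_cm else 1
  baseline <- if (!is.null(cfg$baseline)) as.numeric(cfg$baseline) else c(0, 180)
  test <- if (!is.null(cfg$test)) as.numeric(cfg$test) else
    c(baseline[2], baseline[2] + 600)
  if (fps <= 0) stop("config validation error: fps must be > 0")
  if (pxToCm <= 0) stop("config validation error: px_to_cm must be > 0")
  if (length(baseline) != 2L || length(test) != 2L ||
      diff(baseline) < 0 || diff(test) < 0)
    stop("config validation error: phase spans must be [t0, t1]")
  if (baseline[2] > test[1])
    stop("phase-overlap error: baseline [", baseline[1], ", ", baseline[2],
         "] overlaps test [", test[1], ", ", test[2], "]")
  arena <- if (!is.null(cfg$arena)) {
    ArenaGeometry(home = matrix(unlist(cfg$arena$home), ncol = 2),
                  tunnel = matrix(unlist(cfg$arena$tunnel), ncol = 2),
                  social = matrix(unlist(cfg$arena$social), ncol = 2),
                  pxToCm = pxToCm)
  } else {
    a <- defaultArena(); a@pxToCm <- pxToCm; a
  }
  list(arena = arena, baselineSpan = baseline, testSpan = test,
       fps = fps, pxToCm = pxToCm)
}

scoreColumns <- function() {
  c("subject_id", "sex", "condition",
    "face_sniff_s", "body_sniff_s", "anogenital_sniff_s", "tail_sniff_s",
    "all_sniff_s", "conspecific_sniff_bouts", "social_reactivity_pct",
    "social_freeze_s", "first_tunnel_shelter_s", "reverse_count",
    "reverse_s", "latency_to_social_s", "prosocial_initiations",
    "chamber_preference_pct", "groom_s", "nonsocial_freeze_baseline_s",
    "nonsocial_freeze_test_s", "aggression_s", "jump_count",
    "thigmotaxis_pct")
}

#' Write a behavior score table
#'
#' One subject per row, columns in the canonical order. Undefined-flag
#' entries (e.g. reactivity with zero conspecific sniffs) are written as
#' empty cells and round-trip as NA.
#'
#' @param table data.frame as produced by \code{\link{scoreSession}} /
#'   \code{\link{scoreCohort}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("score table must be a non-empty data.frame")
  if (anyDuplicated(table$subject_id))
    stop("uniqueness error: duplicated subject id \"",
         table$subject_id[duplicated(table$subject_id)][1], "\"")
  cols <- intersect(scoreColumns(), names(table))
  utils::write.csv(table[, c(cols, setdiff(names(table), cols))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a behavior score table written by \code{\link{writeScores}}
#' @param path CSV path.
#' @return data.frame, one subject per row.
#' @export
readScores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
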