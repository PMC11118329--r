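mkSession <- function(traj, log, baseline = c(0, 0), test = NULL) {
  if (is.null(test)) test <- c(0, nFrames(traj) / frameRate(traj))
  SessionRecord("s1", "GH", traj, log, baselineSpan = baseline,
                testSpan = test)
}

test_that("bin rates match hand-counted fractions on a constructed session", {
  # 20 frames at 1 fps: nose distance 1..20 cm, Groom active over [4, 10]
  n <- 20
  traj <- plantedTrajectory(n, fps = 1)
  co <- coords(traj)
  co[, 1, 1, ] <- cbind(rep(0, n), rep(0, n))
  co[, 2, 1, ] <- cbind(1:n, rep(0, n))
  traj <- KeypointTrajectory(co, fps = 1)
  log <- EventLog(data.frame(
    behavior = c("Groom", "Jump"), actor = "experimental",
    event_type = c("state", "point"), onset = c(4, 7.2),
    offset = c(10, NA), stringsAsFactors = FALSE))
  ses <- mkSession(traj, log)
  prof <- distanceBinProfile(ses, bins = c(0, 5, 10, 15, 20, 25))
  # frame i (time i - 1) has distance i; groom covers times 4..10, which
  # are frames 5..11, i.e. distances 5..11
  expect_equal(prof$frames, c(4, 5, 5, 5, 1))
  expect_equal(prof$groom, c(0, 1, 2 / 5, 0, 0))
  # the jump at t=7.2 lands in frame 8 (distance 8), bin [5,10) of 5 s
  expect_equal(prof$jump[2], 1 / 5)
  expect_equal(sum(prof$frames), n)      # every valid frame is binned

  expect_error(distanceBinProfile(ses, bins = c(0, 5, 5, 10)),
               "strictly increasing")
})

test_that("a fully active bin rates 1 and empty bins are flagged NA", {
  n <- 10
  traj <- plantedTrajectory(n, fps = 1)
  co <- coords(traj)
  co[, 1, 1, ] <- cbind(rep(0, n), 0)
  co[, 2, 1, ] <- cbind(rep(3, n), 0)    # constant distance 3
  traj <- KeypointTrajectory(co, fps = 1)
  log <- EventLog(data.frame(behavior = "Groom", actor = "experimental",
                             event_type = "state", onset = 0, offset = 10,
                             stringsAsFactors = FALSE))
  prof <- distanceBinProfile(mkSession(traj, log), bins = c(0, 2, 4, 6))
  expect_equal(prof$groom, c(NA, 1, NA))
  expect_equal(prof$frames, c(0, 10, 0))
})

test_that("refining bins and re-aggregating reproduces coarse state rates", {
  s <- simulateSession(quickConfig(), "SI", seed = 19)
  ses <- s$session
  coarse <- distanceBinProfile(ses, bins = seq(0, 80, by = 8),
                               behaviors = "Face Sniff")
  fine <- distanceBinProfile(ses, bins = seq(0, 80, by = 2),
                             behaviors = "Face Sniff")
  for (k in seq_len(nrow(coarse))) {
    rows <- which(fine$bin_lo >= coarse$bin_lo[k] &
                    fine$bin_hi <= coarse$bin_hi[k])
    nf <- sum(fine$frames[rows])
    expect_equal(nf, coarse$frames[k])
    if (nf > 0) {
      agg <- sum(fine$face_sniff[rows] * fine$frames[rows], na.rm = TRUE) / nf
      expect_equal(agg, coarse$face_sniff[k], tolerance = 1e-9)
    }
  }
})

test_that("rasters are lossless and carry the distance trace", {
  s <- simulateSession(quickConfig(), "SI", seed = 23)
  r <- sessionRaster(s$session)
  back <- rasterToEvents(r)
  expect_equal(events(back), events(s$session@events), tolerance = 1e-12)
  expect_equal(nrow(r$distance), nFrames(s$session))

  empty <- mkSession(s$session@trajectory, EventLog(),
                     baseline = s$session@baselineSpan,
                     test = s$session@testSpan)
  r2 <- sessionRaster(empty)
  expect_equal(nrow(r2$intervals), 0L)
  expect_equal(nrow(r2$distance), nFrames(empty))
})

test_that("sheltering happens farther from the conspecific than freezing", {
  # generator-implied threat-imminence ordering, default SI parameters
  gaps <- vapply(1:5, function(seed) {
    s <- simulateSession(generatorConfig(), "SI", seed = 400 + seed)
    d <- noseDistanceSeries(s$session@trajectory)
    ev <- events(s$session)
    meanDist <- function(b) {
      rows <- ev[ev$behavior == b, , drop = FALSE]
      if (!nrow(rows)) return(NA_real_)
      sel <- rep(FALSE, nrow(d))
      for (k in seq_len(nrow(rows)))
        sel <- sel | (d$time >= rows$onset[k] & d$time <= rows$offset[k])
      mean(d$distanceCm[sel], na.rm = TRUE)
    }
    meanDist("First Tunnel Sheltering") - meanDist("Social Freeze")
  }, 0)
  gaps <- gaps[is.finite(gaps)]
  expect_gt(length(gaps), 2)
  expect_true(all(gaps > 0))
})
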