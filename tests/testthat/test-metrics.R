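arena <- defaultArena()

test_that("zone classification pins, paths and invalid frames behave", {
  # pinned at the social-chamber centroid
  traj <- plantedTrajectory(10, centerA = c(60, 15))
  z <- classifyZones(traj, arena)
  expect_true(all(zoneLabels(z) == "social"))

  # straight walk home -> tunnel -> social gives one entry per zone in order
  n <- 90
  co <- array(NA_real_, c(n, 2, 8, 2))
  for (nd in 1:8) {
    co[, 1, nd, 1] <- seq(5, 70, length.out = n)
    co[, 1, nd, 2] <- 15
    co[, 2, nd, 1] <- 60; co[, 2, nd, 2] <- 25
  }
  z2 <- classifyZones(KeypointTrajectory(co), arena)
  cr <- zoneCrossings(z2)
  expect_equal(cr$zone, c("home", "tunnel", "social"))

  # an invalid reference node yields unknown at that frame only
  traj3 <- plantedTrajectory(5, centerA = c(15, 15))
  v <- validMask(traj3); v[3, 1, 5] <- FALSE
  traj3 <- KeypointTrajectory(coords(traj3), valid = v)
  z3 <- classifyZones(traj3, arena)
  expect_equal(zoneLabels(z3)[3], "unknown")
  expect_true(all(zoneLabels(z3)[-3] == "home"))
  expect_error(classifyZones(traj3, arena, reference = "paw"), "unknown")
})

test_that("state durations sum, compose and clip correctly", {
  mk <- function(b, on, off) data.frame(
    behavior = b, actor = "experimental", event_type = "state",
    onset = on, offset = off, stringsAsFactors = FALSE)
  span <- c(0, 600)
  log <- EventLog(mk("Social Freeze", 12, 14.5))
  expect_equal(stateDuration(log, "Social Freeze", span), 2.5)

  log2 <- EventLog(rbind(mk("Face Sniff", 0, 3), mk("Body Sniff", 10, 12),
                         mk("Anogenital Sniff", 20, 21),
                         mk("Tail Sniff", 30, 30.5)))
  expect_equal(stateDuration(log2, "All Sniff", span), 6.5)

  log3 <- EventLog(mk("Groom", 590, 610))
  expect_equal(stateDuration(log3, "Groom", span), 10)

  expect_error(stateDuration(log, "Jump", span), "type error")
  expect_error(pointCount(log, "Groom", span), "type error")
})

test_that("point counts respect the half-open span rule", {
  mkp <- function(b, on) data.frame(
    behavior = b, actor = if (b == "Conspecific Sniff") "conspecific"
    else "experimental",
    event_type = "point", onset = on, offset = NA_real_,
    stringsAsFactors = FALSE)
  log <- EventLog(do.call(rbind, lapply(c(10, 20, 30, 599.99),
                                        mkp, b = "Social Initiation")))
  expect_equal(pointCount(log, "Social Initiation", c(0, 600)), 4L)
  expect_equal(pointCount(log, "Jump", c(0, 600)), 0L)
  atEnd <- EventLog(mkp("Jump", 600))
  expect_equal(pointCount(atEnd, "Jump", c(0, 600)), 0L)
  expect_equal(pointCount(atEnd, "Jump", c(0, 600.1)), 1L)
})

test_that("social reactivity is a percentage with a flagged empty denominator", {
  mkp <- function(b, on, actor) data.frame(
    behavior = b, actor = actor, event_type = "point", onset = on,
    offset = NA_real_, stringsAsFactors = FALSE)
  cs <- do.call(rbind, lapply(seq(10, 100, by = 10), mkp,
                              b = "Conspecific Sniff", actor = "conspecific"))
  re <- do.call(rbind, lapply(c(15, 25), mkp, b = "Social Reactivity",
                              actor = "experimental"))
  expect_equal(socialReactivityPct(EventLog(rbind(cs, re)), c(0, 600)), 20)
  expect_equal(socialReactivityPct(EventLog(cs[1:5, ]), c(0, 600)), 0)
  expect_true(is.na(socialReactivityPct(EventLog(re), c(0, 600))))
})

test_that("chamber preference counts social time over the whole span", {
  mkZone <- function(zones, fps = 1) {
    n <- length(zones)
    new("ZoneSequence", zone = zones, fps = fps,
        crossings = data.frame(frame = integer(), time = numeric(),
                               zone = character(), prev = character()))
  }
  z <- mkZone(rep(c("social", "home"), each = 300))
  expect_equal(chamberPreferencePct(z, c(0, 600)), 50)
  expect_equal(chamberPreferencePct(mkZone(rep("home", 600)), c(0, 600)), 0)
  z3 <- mkZone(c(rep("social", 45), rep("home", 540), rep("tunnel", 15)))
  expect_equal(chamberPreferencePct(z3, c(0, 600)), 7.5)
})

test_that("tunnel hesitancy sums all pre-entry shelters and flags never-entry", {
  mk <- function(b, on, off) data.frame(
    behavior = b, actor = "experimental", event_type = "state",
    onset = on, offset = off, stringsAsFactors = FALSE)
  zoneAt <- function(entryFrame, n = 600, fps = 1) {
    zones <- rep("home", n)
    if (!is.na(entryFrame)) zones[entryFrame:n] <- "social"
    cr <- if (is.na(entryFrame)) {
      data.frame(frame = 1L, time = 0, zone = "home", prev = "none")
    } else {
      data.frame(frame = c(1L, entryFrame),
                 time = c(0, entryFrame - 1),
                 zone = c("home", "social"), prev = c("none", "home"))
    }
    new("ZoneSequence", zone = zones, fps = fps, crossings = cr)
  }
  log <- EventLog(rbind(mk("First Tunnel Sheltering", 5, 20),
                        mk("First Tunnel Sheltering", 30, 40)))
  h <- tunnelHesitancy(log, zoneAt(42), c(0, 600))   # entry at t = 41
  expect_equal(h$firstShelterS, 25)
  expect_equal(h$latencyToSocialS, 41)
  expect_false(h$neverEntered)

  h2 <- tunnelHesitancy(log, zoneAt(NA), c(0, 600))
  expect_true(h2$neverEntered)
  expect_true(is.na(h2$latencyToSocialS))
  expect_equal(h2$firstShelterS, 25)

  log3 <- EventLog(rbind(mk("First Tunnel Sheltering", 5, 20),
                         mk("First Tunnel Sheltering", 50, 60)))
  h3 <- tunnelHesitancy(log3, zoneAt(42), c(0, 600))
  expect_equal(h3$firstShelterS, 15)  # post-entry shelter does not count
})

test_that("nose distance is Euclidean with validity propagation", {
  traj <- plantedTrajectory(3)
  co <- coords(traj)
  co[, 1, 1, ] <- rep(c(0, 0), each = 3)
  co[, 2, 1, ] <- rep(c(3, 4), each = 3)
  co[2, 2, 1, ] <- c(0, 0)
  v <- validMask(traj); v[3, 2, 1] <- FALSE
  d <- noseDistanceSeries(KeypointTrajectory(co, valid = v))
  expect_equal(d$distanceCm[1], 5)
  expect_equal(d$distanceCm[2], 0)
  expect_true(is.na(d$distanceCm[3]) && !d$valid[3])
})

test_that("scoring an empty event log still yields trajectory metrics", {
  s <- simulateSession(quickConfig(), "GH", seed = 6)
  empty <- SessionRecord(s$session@subjectId, "GH", s$session@trajectory,
                         EventLog(), baselineSpan = s$session@baselineSpan,
                         testSpan = s$session@testSpan)
  row <- scoreSession(empty, arena)
  expect_equal(row$all_sniff_s, 0)
  expect_equal(row$social_freeze_s, 0)
  expect_true(is.na(row$social_reactivity_pct))
  expect_true(row$chamber_preference_pct >= 0)
  expect_true(is.finite(row$thigmotaxis_pct))
  # determinism: identical sessions give identical rows
  expect_identical(scoreSession(s$session, arena),
                   scoreSession(s$session, arena))
})

test_that("metrics are invariant to event-log row order and subtype sums hold", {
  for (seed in 1:10) {
    log <- randomEventLog(seed)
    ev <- events(log)
    set.seed(seed + 1000)
    shuffled <- EventLog(ev[sample(nrow(ev)), ])
    span <- c(180, 780)
    for (b in c("All Sniff", "Social Freeze", "Groom"))
      expect_identical(stateDuration(log, b, span),
                       stateDuration(shuffled, b, span))
    expect_identical(socialReactivityPct(log, span),
                     socialReactivityPct(shuffled, span))
    subs <- sum(stateDuration(log, "Face Sniff", span),
                stateDuration(log, "Body Sniff", span),
                stateDuration(log, "Anogenital Sniff", span),
                stateDuration(log, "Tail Sniff", span))
    expect_identical(stateDuration(log, "All Sniff", span), subs)
  }
})

test_that("zone fractions account for every frame", {
  s <- simulateSession(quickConfig(), "SI", seed = 13)
  z <- classifyZones(s$session@trajectory, arena)
  idx <- spanFrames(s$session@testSpan, frameRate(z), length(zoneLabels(z)))
  zl <- zoneLabels(z)[idx]
  total <- mean(zl == "social") + mean(zl == "home") +
    mean(zl == "tunnel") + mean(zl == "unknown")
  expect_equal(total * 100, 100, tolerance = 1e-9)
})
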