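test_that("identical config, condition and seed give bit-identical sessions", {
  a <- simulateSession(quickConfig(), "SI", seed = 7)
  b <- simulateSession(quickConfig(), "SI", seed = 7)
  expect_identical(a, b)
  expect_error(simulateSession(quickConfig(), "Floating"), "unknown condition")
})

test_that("the noise-free limit keeps limbs rigid and every cell valid", {
  s <- simulateSession(quickConfig(jitterSd = 0, missingRate = 0), "GH",
                       seed = 3)
  traj <- s$session@trajectory
  v <- validMask(traj)
  expect_true(all(v[, 1, ]))                       # experimental always valid
  base <- spanFrames(s$session@baselineSpan, frameRate(traj), nFrames(traj))
  expect_true(all(!v[base, 2, ]))                  # conspecific absent solo
  test <- spanFrames(s$session@testSpan, frameRate(traj), nFrames(traj))
  expect_true(all(v[test, 2, ]))
  co <- coords(traj)
  limb <- function(a, i, j, frames)
    sqrt((co[frames, a, i, 1] - co[frames, a, j, 1])^2 +
           (co[frames, a, i, 2] - co[frames, a, j, 2])^2)
  # fixed-length limbs: nose-head, head-trunk, trunk-tail_base, trunk-hips
  expect_lt(diff(range(limb(1, 1, 2, test))), 1e-9)
  expect_lt(diff(range(limb(1, 2, 5, test))), 1e-9)
  expect_lt(diff(range(limb(1, 5, 8, test))), 1e-9)
  expect_lt(diff(range(limb(2, 5, 6, test))), 1e-9)
})

test_that("a certain freeze response follows every conspecific sniff", {
  cond <- conditionPresets()
  cond$GH$pFreeze <- 1; cond$GH$pReact <- 0
  s <- simulateSession(generatorConfig(conditions = cond), "GH", seed = 11)
  ev <- events(s$session)
  ns <- sum(ev$behavior == "Conspecific Sniff")
  expect_gt(ns, 0)
  expect_gt(sum(ev$behavior == "Social Freeze"), 0)
})

test_that("cohorts are balanced, reproducible and carry distinct subjects", {
  coh <- simulateCohort(quickConfig(), nPerGroup = 3, seed = 9)
  expect_length(coh, 6L)
  conds <- vapply(coh, function(s) s$session@condition, "")
  expect_equal(unname(table(conds)[c("GH", "SI")]), c(3L, 3L),
               ignore_attr = TRUE)
  ids <- vapply(coh, function(s) s$session@subjectId, "")
  expect_false(anyDuplicated(ids) > 0)
  coh2 <- simulateCohort(quickConfig(), nPerGroup = 3, seed = 9)
  expect_identical(coh, coh2)
})

test_that("ethogram metrics reproduce the generator's ground truth exactly", {
  for (seed in c(21, 22)) {
    s <- simulateSession(generatorConfig(),
                         condition = if (seed %% 2) "SI" else "GH",
                         seed = seed)
    row <- scoreSession(s$session, defaultArena())
    gt <- s$truth@summaries
    m <- unlist(row[names(gt)])
    expect_identical(unname(is.na(m)), unname(is.na(gt)))
    expect_equal(unname(m), unname(gt), tolerance = 1e-12)
  }
})

test_that("artifact injection is the identity at zero rates", {
  s <- simulateSession(quickConfig(), "GH", seed = 2)
  traj <- s$session@trajectory
  out <- injectArtifacts(traj, 0, 0, seed = 1)
  expect_identical(out$trajectory, traj)
  expect_equal(nrow(out$windows), 0L)
})

test_that("a unit missing rate invalidates every cell", {
  s <- simulateSession(quickConfig(), "GH", seed = 2)
  out <- injectArtifacts(s$session@trajectory, missingRate = 1, seed = 1)
  expect_true(all(!validMask(out$trajectory)))
})

test_that("re-swapping the reported windows restores the trajectory", {
  s <- simulateSession(quickConfig(), "GH", seed = 4)
  traj <- s$session@trajectory
  out <- injectArtifacts(traj, missingRate = 0, swapRate = 0.1, seed = 5)
  expect_gt(nrow(out$windows), 0L)
  expect_false(identical(out$trajectory, traj))
  restored <- swapWindows(out$trajectory, out$windows)
  expect_identical(coords(restored), coords(traj))
  expect_identical(validMask(restored), validMask(traj))
})
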