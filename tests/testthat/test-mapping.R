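test_that("short gaps are filled linearly, long gaps stay invalid", {
  traj <- plantedTrajectory(10, fps = 1)
  co <- coords(traj)
  co[, 1, 1, 1] <- 0:9; co[, 1, 1, 2] <- 0
  v <- validMask(traj)
  v[2:4, 1, 1] <- FALSE       # 3-frame gap between (0,0) and (4,0)
  v[6:9, 1, 2] <- FALSE       # 4-frame gap touching nothing valid after
  out <- interpolateTracks(KeypointTrajectory(co, valid = v, fps = 1),
                           maxGapS = 3)
  expect_equal(unname(coords(out)[2:4, 1, 1, 1]), c(1, 2, 3))
  expect_equal(unname(coords(out)[2:4, 1, 1, 2]), c(0, 0, 0))
  expect_true(all(validMask(out)[, 1, 1]))
  expect_true(all(interpolatedMask(out)[2:4, 1, 1]))
  expect_true(all(!validMask(out)[6:9, 1, 2]))   # gap longer than maxGap

  full <- plantedTrajectory(5)
  expect_identical(coords(interpolateTracks(full)), coords(full))
})

test_that("interior angles hit the collinear and right-angle landmarks", {
  traj <- plantedTrajectory(4)
  co <- coords(traj)
  # nose-head-trunk collinear, then at a right angle, for animal 1
  co[, 1, 1, ] <- cbind(c(2, 2, 0, 0), c(0, 0, 1, 1)) # nose
  co[, 1, 2, ] <- 0                                    # head at origin
  co[, 1, 5, ] <- cbind(c(-2, -2, 1, 1), c(0, 0, 0, 0)) # trunk
  af <- angleFeatures(KeypointTrajectory(co, fps = 30))
  a <- af$features[, "experimental_head_angle_nose_trunk"]
  expect_equal(a[1], pi, tolerance = 1e-12)
  expect_equal(a[3], pi / 2, tolerance = 1e-12)
})

test_that("angle features are invariant to rigid motion", {
  s <- simulateSession(quickConfig(), "GH", seed = 8)
  traj <- interpolateTracks(s$session@trajectory)
  idx <- spanFrames(s$session@testSpan, frameRate(traj), nFrames(traj))[1:200]
  ref <- angleFeatures(traj, frames = idx)
  for (theta in c(0.7, 2.1, -1.2)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    co <- coords(traj)
    flat <- matrix(co, ncol = 2)
    rot <- flat %*% R
    rot[, 1] <- rot[, 1] + 11; rot[, 2] <- rot[, 2] - 4
    co2 <- array(rot, dim(co))
    rtraj <- KeypointTrajectory(co2, valid = validMask(traj),
                                fps = frameRate(traj),
                                interpolated = interpolatedMask(traj))
    got <- angleFeatures(rtraj, frames = idx)
    expect_lt(max(abs(got$features - ref$features)), 1e-9)
  }
})

test_that("PCA keeps the smallest sufficient dimension and matches eigen", {
  # points on a line collapse to one component
  set.seed(2)
  t <- rnorm(400)
  line <- cbind(t * 2, t * -1) + matrix(rnorm(800, sd = 1e-4), ncol = 2)
  pr <- pcaReduce(line, 0.95)
  expect_equal(pr$k, 1L)
  expect_gt(pr$explainedVariance[1], 0.999)

  # eigendecomposition oracle on a 3-feature toy dataset
  set.seed(3)
  X <- matrix(rnorm(300 * 3), 300, 3) %*%
    matrix(c(2, 0.5, 0, 0.5, 1, 0.2, 0, 0.2, 0.3), 3, 3)
  pr3 <- pcaReduce(X, 1)
  ev <- eigen(stats::cov(X))$values
  got <- pr3$explainedVariance * sum(ev)
  expect_equal(got, ev / sum(ev) * sum(ev), tolerance = 1e-9)

  expect_error(pcaReduce(X, 0), "varianceFraction")
  expect_error(pcaReduce(X, 1.2), "varianceFraction")
})

test_that("the embedding contract holds for both backends", {
  set.seed(9)
  clusters <- rbind(matrix(rnorm(500 * 4, 0), ncol = 4),
                    matrix(rnorm(500 * 4, 10), ncol = 4))
  label <- rep(1:2, each = 500)
  for (backend in c("pca", "umap")) {
    emb <- embed2d(clusters, seed = 33, backend = backend)
    expect_equal(dim(emb), c(1000L, 2L))
    nn <- vapply(seq_len(nrow(emb)), function(i) {
      d <- sqrt(rowSums(sweep(emb, 2, emb[i, ])^2))
      d[i] <- Inf
      label[which.min(d)]
    }, 0L)
    expect_gte(mean(nn == label), 0.95)
    expect_identical(emb, embed2d(clusters, seed = 33, backend = backend))
  }
  expect_error(embed2d(clusters[1:5, ], nNeighbors = 15), "too few")
  dup <- matrix(1, 40, 3)
  expect_true(all(is.finite(embed2d(dup, backend = "pca"))))
})

test_that("watershed splits match cluster structure", {
  set.seed(21)
  one <- matrix(rnorm(2000), ncol = 2)
  m1 <- segmentDensity(one, gridSize = 80)
  expect_equal(length(m1@peakDensity), 1L)

  two <- rbind(matrix(rnorm(1000), ncol = 2),
               matrix(rnorm(1000, mean = 12), ncol = 2))
  m2 <- segmentDensity(two, gridSize = 80)
  expect_equal(length(m2@peakDensity), 2L)
  first <- pointRegions(m2)[1:500]
  second <- pointRegions(m2)[501:1000]
  expect_gte(mean(first == as.integer(names(which.max(table(first))))), 0.99)
  expect_false(names(which.max(table(first))) ==
                 names(which.max(table(second))))
  expect_error(segmentDensity(two, bandwidthFactor = 0), "bandwidth")
})

test_that("basin labels equal the brute-force steepest-ascent oracle", {
  set.seed(14)
  for (i in 1:15) {
    n <- sample(8:40, 1); m <- sample(8:40, 1)
    d <- matrix(runif(n * m), n, m)
    expect_identical(basinLabels(d)$labels, hillClimbOracle(d))
  }
})

test_that("occupancy fractions are conserved and errors are raised", {
  set.seed(25)
  emb <- rbind(matrix(rnorm(600), ncol = 2),
               matrix(rnorm(600, mean = 10), ncol = 2))
  map <- segmentDensity(emb, gridSize = 60)
  subject <- rep(c("s1", "s2", "s3"), each = 200)
  prof <- occupancyProfiles(map, subject)
  expect_equal(unname(rowSums(prof)), rep(1, 3), tolerance = 1e-9)
  # a subject pinned in one cluster occupies one region fully
  expect_equal(max(prof["s1", ]), 1)
  expect_error(occupancyProfiles(map, factor(subject,
                                             levels = c(unique(subject), "s4"))),
               "0 frames")
})

test_that("occupancy decoding recovers a planted region effect", {
  planted <- 3L
  labels <- rep(c("GH", "SI"), each = 18)
  prof <- plantedProfiles(1, planted = planted)
  res <- regionStatsAndDecode(prof, labels)
  co <- decoderCoefficients(res$decoder)
  expect_equal(names(which.max(abs(co))), "region_3")
  expect_lt(res$tests$p[res$tests$region == "region_3"], 0.05)

  # ablating the planted region costs accuracy
  res2 <- regionStatsAndDecode(prof, labels, excludedRegions = planted)
  expect_lte(trainingAccuracy(res2$decoder),
             trainingAccuracy(res$decoder))
  expect_error(regionStatsAndDecode(prof, labels, excludedRegions = 1:8),
               "all regions excluded")
})

test_that("regions dominated by interpolated coordinates are flagged", {
  set.seed(61)
  emb <- rbind(matrix(rnorm(800), ncol = 2),
               matrix(rnorm(800, mean = 10), ncol = 2))
  map <- segmentDensity(emb, gridSize = 60)
  flagged <- c(rep(0, 400), rep(0.8, 400))  # second cluster mostly filled
  ex <- artifactRegions(map, flagged)
  expect_length(ex, 1L)
  expect_equal(mean(flagged[pointRegions(map) == ex]), 0.8, tolerance = 0.05)
})

test_that("the full mapping pipeline is deterministic for a fixed seed", {
  coh <- simulateCohort(quickConfig(), nPerGroup = 2, seed = 17)
  p <- mapParams(); p$gridSize <- 80L
  a <- mapCohort(coh, p, seed = 5)
  b <- mapCohort(coh, p, seed = 5)
  expect_identical(a$map@density, b$map@density)
  expect_identical(a$map@labels, b$map@labels)
  expect_identical(a$profiles, b$profiles)
  expect_identical(decoderCoefficients(a$analysis$decoder),
                   decoderCoefficients(b$analysis$decoder))
})
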