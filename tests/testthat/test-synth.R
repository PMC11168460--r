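test_that("noise-free bead rendering hits the programmed intensities", {
  spec <- beadSceneSpec(c(64, 64),
    beads = data.frame(x = 30, y = 30, radius = 12, rim_thickness = 4),
    rimIntensity = 100, coreIntensity = 0,
    backgroundLevel = c(mCherry = 0))
  out <- simulateBeadScene(spec)
  img <- getChannel(out$scene, "mCherry")
  expect_equal(max(img), 100)
  expect_equal(img[31, 31], 0)              # core pixel at the center
  # programmed intensities recoverable by direct pixel lookup
  expect_equal(img[31, 31 + 10], 100)       # 10 px right of center: rim

  empty <- simulateBeadScene(beadSceneSpec(c(32, 32),
    beads = data.frame(x = numeric(0), y = numeric(0),
                       radius = numeric(0), rim_thickness = numeric(0)),
    rimIntensity = numeric(0), coreIntensity = numeric(0),
    backgroundLevel = c(mCherry = 10)))
  expect_true(all(getChannel(empty$scene, "mCherry") == 10))
})

test_that("generators are bitwise deterministic for identical spec and seed", {
  beads <- data.frame(x = c(20, 60, 100, 20, 60, 100, 20, 60, 100, 20, 60, 100),
                      y = rep(c(20, 55, 90, 125), each = 3),
                      radius = 12, rim_thickness = 4)
  spec <- beadSceneSpec(c(150, 120), beads, rimIntensity = 80,
                        coreIntensity = 5,
                        backgroundLevel = c(mCherry = 10, EGFP = 12),
                        noiseSd = 3, seed = 42L)
  a <- simulateBeadScene(spec); b <- simulateBeadScene(spec)
  expect_identical(a$scene@channels, b$scene@channels)
  expect_identical(truthObjects(a$truth), truthObjects(b$truth))
  expect_equal(nrow(truthObjects(a$truth)), 12L)

  cs <- condensateSceneSpec(c(128, 128), nSpots = c(3L, 6L),
                            timePoints = c(0, 30), colocFraction = 0.5,
                            noiseSd = 2, seed = 9L)
  c1 <- simulateCondensateSeries(cs); c2 <- simulateCondensateSeries(cs)
  expect_identical(lapply(c1$scenes, slot, "channels"),
                   lapply(c2$scenes, slot, "channels"))
  expect_identical(truthObjects(c1$truth), truthObjects(c2$truth))

  fs <- frapSpec(noiseSd = 2, seed = 5L)
  expect_identical(frapIntensities(generateFrapTrace(fs)),
                   frapIntensities(generateFrapTrace(fs)))

  ts <- beadTableSpec(seed = 11L)
  expect_identical(simulateBeadTable(ts), simulateBeadTable(ts))
})

test_that("invalid scene specs are rejected with the violated invariant named", {
  b <- data.frame(x = 30, y = 30, radius = 3, rim_thickness = 4)
  expect_error(beadSceneSpec(c(64, 64), b, 100, 0, c(m = 0)),
               "radius > rim_thickness")
  b2 <- data.frame(x = 100, y = 30, radius = 10, rim_thickness = 4)
  expect_error(beadSceneSpec(c(64, 64), b2, 100, 0, c(m = 0)),
               "centers inside image")
  b3 <- data.frame(x = 30, y = 30, radius = 10, rim_thickness = 4)
  expect_error(beadSceneSpec(c(64, 64), b3, -5, 0, c(m = 0)),
               "intensities >= 0")
  expect_error(condensateSceneSpec(c(64, 64), nSpots = 3L, timePoints = 0,
                                   colocFraction = 1.2), "coloc_fraction")
  expect_error(condensateSceneSpec(c(64, 64), nSpots = c(1L, 1L),
                                   timePoints = c(10, 10)),
               "strictly increasing")
  # overlapping beads only allowed when adjacency testing is flagged
  b4 <- data.frame(x = c(30, 40), y = c(30, 30), radius = 10,
                   rim_thickness = 3)
  expect_error(beadSceneSpec(c(64, 64), b4, 100, 0, c(m = 0)), "overlap")
  expect_silent(beadSceneSpec(c(64, 64), b4, 100, 0, c(m = 0),
                              allowAdjacent = TRUE))
})

test_that("background noise is calibrated to the programmed SD", {
  spec <- beadSceneSpec(c(128, 128),
    beads = data.frame(x = numeric(0), y = numeric(0),
                       radius = numeric(0), rim_thickness = numeric(0)),
    rimIntensity = numeric(0), coreIntensity = numeric(0),
    backgroundLevel = c(mCherry = 200), noiseSd = 10, seed = 4L)
  img <- getChannel(simulateBeadScene(spec)$scene, "mCherry")
  expect_gte(length(img), 1e4)
  expect_lt(abs(sd(img) - 10) / 10, 0.05)
})

test_that("condensate series truth matches the programmed counts and flags", {
  spec <- condensateSceneSpec(c(200, 200), nSpots = c(0L, 5L, 9L),
                              timePoints = c(0, 30, 60),
                              colocFraction = 1, noiseSd = 0, seed = 2L)
  sim <- simulateCondensateSeries(spec)
  expect_length(sim$scenes, 3L)
  tr <- truthObjects(sim$truth)
  expect_equal(as.vector(table(factor(tr$time, levels = c(0, 30, 60)))),
               c(0L, 5L, 9L))
  expect_true(all(tr$coloc))
  # spot count exceeding placeable positions errors with the capacity named
  tiny <- condensateSceneSpec(c(40, 40), nSpots = 50L, timePoints = 0,
                              seed = 1L)
  expect_error(simulateCondensateSeries(tiny), "capacity")
})

test_that("FRAP traces follow the closed-form recovery model", {
  # full recovery limit
  tr <- generateFrapTrace(frapSpec(mobileFraction = 1, rate = 50,
                                   noiseSd = 0))
  expect_equal(tail(frapIntensities(tr), 1), 100, tolerance = 1e-6)
  # immobile limit: all post-bleach frames stay at the bleach level
  tr0 <- generateFrapTrace(frapSpec(mobileFraction = 0, noiseSd = 0))
  post <- (tr0@bleachIndex):length(frapTimes(tr0))
  expect_true(all(frapIntensities(tr0)[post] == 20))
  # closed form at t = 30 s
  tr4 <- generateFrapTrace(frapSpec(pre = 100, bleachDepth = 80,
                                    mobileFraction = 0.4, rate = 0.5,
                                    noiseSd = 0))
  expect_equal(tail(frapIntensities(tr4), 1),
               20 + 0.4 * 80 * (1 - exp(-15)), tolerance = 1e-12)
  expect_error(frapSpec(duration = 0.5, frameInterval = 1),
               "shorter than one frame")
})

test_that("bead tables realize the programmed fixed and random structure", {
  # all effects and SDs zero: every response identical
  s0 <- beadTableSpec(conditionEffects = c(a = 0, b = 0), replicateSd = 0,
                      wellSd = 0, residualSd = 0)
  expect_true(all(simulateBeadTable(s0)$mean_score == 100))
  # residual 0, single Delta = 50: group means differ exactly by 50
  s1 <- beadTableSpec(conditionEffects = c(empty = 0, coated = 50),
                      replicateSd = 5, wellSd = 0, residualSd = 0,
                      seed = 3L)
  t1 <- simulateBeadTable(s1)
  mns <- tapply(t1$mean_score, t1$condition, mean)
  expect_equal(unname(mns["coated"] - mns["empty"]), 50)
})

test_that("empirical variance components track the programmed values", {
  # isolate each component in turn and check its Monte-Carlo SD
  nrep <- 400L
  relErr <- function(sds, target) abs(sqrt(mean(sds^2)) - target) / target
  # 3 SE of an SD estimate from n draws is roughly 3/sqrt(2 n)
  repSds <- vapply(seq_len(nrep), function(i) {
    t <- simulateBeadTable(beadTableSpec(nReplicates = 2L, nWells = 1L,
      nBeads = 1L, replicateSd = 10, wellSd = 0, residualSd = 0, seed = i))
    sd(tapply(t$mean_score, t$replicate_id, mean))
  }, numeric(1))
  expect_lt(relErr(repSds, 10), 3 / sqrt(2 * nrep))
  wellSds <- vapply(seq_len(nrep), function(i) {
    t <- simulateBeadTable(beadTableSpec(nReplicates = 1L, nWells = 4L,
      nBeads = 1L, replicateSd = 0, wellSd = 10, residualSd = 0, seed = i))
    sd(t$mean_score[t$condition == "empty"])
  }, numeric(1))
  expect_lt(relErr(wellSds, 10), 3 / sqrt(2 * nrep))
  resSds <- vapply(seq_len(nrep), function(i) {
    t <- simulateBeadTable(beadTableSpec(nReplicates = 1L, nWells = 1L,
      nBeads = 30L, replicateSd = 0, wellSd = 0, residualSd = 20, seed = i))
    sd(t$mean_score[t$condition == "empty"])
  }, numeric(1))
  expect_lt(relErr(resSds, 20), 3 / sqrt(2 * nrep * 29))
})
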