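test_that("reference detector recovers disjoint beads and rejects doublets", {
  spec <- makeBeadScene(5, 0, rim = 100, noiseSd = 0)
  sim <- simulateBeadScene(spec)
  img <- getChannel(sim$scene, "EGFP")
  mask <- detectBeads(img)
  truth <- truthObjects(sim$truth)
  expect_equal(max(mask), 5L)
  for (l in 1:5) {
    roi <- fitCircularROI(mask, l)
    d <- sqrt((truth$x - roi$x)^2 + (truth$y - roi$y)^2)
    expect_lt(min(d), 1)
  }
  # constant image: empty mask, not an error
  expect_equal(max(detectBeads(matrix(7, 50, 50))), 0L)
  # two beads in contact merge into one low-fill component and are discarded
  touching <- beadSceneSpec(c(90, 120),
    beads = data.frame(x = c(40, 66), y = 45, radius = 13,
                       rim_thickness = 4),
    rimIntensity = 100, coreIntensity = 60,
    backgroundLevel = c(EGFP = 0), allowAdjacent = TRUE)
  m2 <- detectBeads(getChannel(simulateBeadScene(touching)$scene, "EGFP"))
  expect_equal(max(m2), 0L)
  expect_true("low-fill-fraction" %in% attr(m2, "discarded")$reason)
})

test_that("circular ROI fit is exact for disks and flags degenerate labels", {
  mask <- diskMask(64, 64, cx = 30, cy = 30, r = 20)
  roi <- fitCircularROI(mask, 1L)
  expect_lt(abs(roi$radius - 20), 0.5)
  expect_equal(c(roi$x, roi$y), c(30, 30), tolerance = 0.05)
  # half disk: center is the centroid of the half-disk mask
  half <- mask
  half[, 32:64] <- 0L                      # keep x <= 30
  roiH <- fitCircularROI(half, 1L)
  expect_lt(roiH$x, 29)                    # pulled off the disk center
  expect_equal(roiH$y, 30, tolerance = 0.05)
  # 1-px label flagged below the minimum radius
  tiny <- matrix(0L, 16, 16); tiny[8, 8] <- 1L
  roiT <- fitCircularROI(tiny, 1L)
  expect_false(roiT$ok)
  expect_equal(roiT$reason, "below-min-radius")
  expect_error(fitCircularROI(mask, 9L), "label 9")
})

test_that("profile geometry: angles, sample grid and bounds handling", {
  roi <- structure(list(beadId = 1L, x = 60, y = 60, radius = 20,
                        ok = TRUE, reason = "none"), class = "BeadROI")
  img <- matrix(0, 121, 121)
  prof <- drawProfiles(roi, img, nLines = 8L, extensionFrac = 0.2, step = 1)
  expect_equal(vapply(prof, `[[`, numeric(1), "angle"),
               2 * pi * (0:7) / 8)
  # radius 20, extension 0.2, step 1: samples at distances 0..24
  expect_length(prof[[1]]$samples, 25L)
  expect_equal(prof[[1]]$distances, 0:24)
  expect_false(any(vapply(prof, `[[`, logical(1), "excluded")))
  # a bead near the border loses the rays that leave the image
  roiEdge <- structure(list(beadId = 1L, x = 5, y = 60, radius = 20,
                            ok = TRUE, reason = "none"), class = "BeadROI")
  pe <- drawProfiles(roiEdge, img)
  reasons <- vapply(pe, `[[`, character(1), "reason")
  expect_true("out-of-bounds" %in% reasons)
})

test_that("adjacency exclusion removes exactly the rays that hit neighbors", {
  # isolated bead: nothing excluded
  mask <- diskMask(100, 100, cx = 40, cy = 40, r = 10)
  roi <- fitCircularROI(mask, 1L)
  img <- matrix(0, 100, 100)
  prof <- excludeAdjacent(drawProfiles(roi, img), mask, 1L)
  expect_equal(sum(vapply(prof, `[[`, logical(1), "excluded")), 0L)
  # one neighbor placed on the 0-rad ray: exactly that ray excluded
  mask2 <- diskMask(100, 100, cx = 52, cy = 30, r = 10, label = 2L,
                    mask = diskMask(100, 100, cx = 30, cy = 30, r = 10))
  roi2 <- fitCircularROI(mask2, 1L)
  prof2 <- excludeAdjacent(drawProfiles(roi2, img), mask2, 1L)
  excl <- vapply(prof2, `[[`, logical(1), "excluded")
  expect_identical(which(excl), 1L)        # the angle-0 ray
  expect_equal(prof2[[1]]$reason, "adjacent-bead")
  # bead fully ringed by neighbors: all rays excluded, bead reported empty
  mask3 <- diskMask(120, 120, cx = 60, cy = 60, r = 8)
  for (i in 0:7) {
    a <- 2 * pi * i / 8
    mask3 <- diskMask(120, 120, cx = 60 + 16 * cos(a), cy = 60 + 16 * sin(a),
                      r = 8, label = i + 2L, mask = mask3)
  }
  roi3 <- fitCircularROI(mask3, 1L)
  prof3 <- excludeAdjacent(drawProfiles(roi3, matrix(0, 120, 120)), mask3, 1L)
  expect_true(all(vapply(prof3, `[[`, logical(1), "excluded")))
  row <- summarizeBead(prof3, beadId = 1L)
  expect_equal(row$n_profiles_retained, 0L)
  expect_equal(row$exclusion_reason, "no-retained-profiles")
  expect_error(excludeAdjacent(prof3, mask3, 99L), "99")
})

test_that("profile scores match the brute-force rasterized-ray oracle", {
  expect_equal(scoreProfile(structure(list(samples = c(5, 5, 5),
    excluded = FALSE), class = "LineProfile")), 0)
  expect_equal(scoreProfile(structure(list(samples = c(10, 80, 30),
    excluded = FALSE), class = "LineProfile")), 70)
  expect_error(scoreProfile(structure(list(samples = 1:3, excluded = TRUE,
    reason = "adjacent-bead"), class = "LineProfile")), "excluded")
  # noisy synthetic scene: pipeline scores equal the oracle to 1e-9
  sim <- simulateBeadScene(makeBeadScene(3, 1, noiseSd = 4, seed = 7L,
                                         background = 20))
  img <- getChannel(sim$scene, "EGFP")
  meas <- quantifyBeads(sim$scene, "EGFP")
  profs <- attr(meas, "profiles")
  checked <- 0L
  for (bead in profs) for (p in bead) {
    if (p$excluded) next
    expect_equal(scoreProfile(p),
                 oracleProfileScore(img, p$originX, p$originY, p$angle,
                                    p$distances),
                 tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("noise-free coated beads score exactly the rim intensity", {
  sim <- simulateBeadScene(makeBeadScene(4, 0, rim = 100, noiseSd = 0))
  meas <- quantifyBeads(sim$scene, "EGFP")
  expect_equal(nrow(meas), 4L)
  for (bead in attr(meas, "profiles")) for (p in bead)
    if (!p$excluded) expect_equal(scoreProfile(p), 100)
  expect_true(all(meas$mean_score == 100))
  expect_true(all(meas$sd_score == 0))
})

test_that("scores are shift invariant and gain equivariant", {
  sim <- simulateBeadScene(makeBeadScene(2, 0, noiseSd = 3, seed = 3L,
                                         background = 15))
  base <- quantifyBeads(sim$scene, "EGFP")
  mask <- detectBeads(getChannel(sim$scene, "EGFP"))
  shifted <- ImageScene(list(EGFP = getChannel(sim$scene, "EGFP") + 37))
  gained <- ImageScene(list(EGFP = getChannel(sim$scene, "EGFP") * 2.5))
  sMeas <- quantifyBeads(shifted, "EGFP", mask = mask)
  gMeas <- quantifyBeads(gained, "EGFP", mask = mask)
  expect_equal(sMeas$mean_score, base$mean_score, tolerance = 1e-12)
  expect_equal(gMeas$mean_score, 2.5 * base$mean_score, tolerance = 1e-12)
})

test_that("bead summaries match independent mean/sd arithmetic", {
  mk <- function(scores) lapply(scores, function(s)
    structure(list(samples = c(0, s), excluded = FALSE),
              class = "LineProfile"))
  row <- summarizeBead(mk(c(10, 10, 10, 10)), beadId = 1L)
  expect_equal(row$mean_score, 10)
  expect_equal(row$sd_score, 0)
  expect_true(row$qc_pass)
  # boundary: sd exactly half the mean fails QC ("equal or greater")
  scores <- c(50, 150)                     # mean 100, sd ~70.7 -> fail
  row2 <- summarizeBead(mk(scores), beadId = 2L)
  expect_false(row2$qc_pass)
  # single retained profile: sd 0 by convention
  expect_equal(summarizeBead(mk(42), beadId = 3L)$sd_score, 0)
  # random scores vs brute-force recomputation
  set.seed(8)
  rnd <- runif(11, 0, 200)
  row3 <- summarizeBead(mk(rnd), beadId = 4L)
  expect_equal(row3$mean_score, sum(rnd) / length(rnd), tolerance = 1e-12)
  expect_equal(row3$sd_score,
               sqrt(sum((rnd - mean(rnd))^2) / (length(rnd) - 1)),
               tolerance = 1e-12)
})

test_that("QC filter applies the sd >= mean/2 exclusion rule exactly", {
  tab <- data.frame(bead_id = 1:3, well_id = "W1", replicate_id = "R1",
                    condition = "c", n_profiles_retained = 8L,
                    mean_score = 100, sd_score = c(49.9, 50, 50.1),
                    qc_pass = NA, exclusion_reason = "none")
  out <- qcFilter(tab)
  expect_equal(out$retained$bead_id, 1L)
  expect_equal(sort(out$excluded$bead_id), c(2L, 3L))
  expect_equal(out$excluded$ratio, c(0.5, 0.501))
  # mean 0 (sd 0) is excluded by the same rule
  tab0 <- tab[1, ]; tab0$mean_score <- 0; tab0$sd_score <- 0
  expect_equal(nrow(qcFilter(tab0)$retained), 0L)
  # a mixed table equals brute-force application of the rule
  set.seed(5)
  big <- data.frame(bead_id = 1:20, well_id = "W1", replicate_id = "R1",
                    condition = "c", n_profiles_retained = 8L,
                    mean_score = runif(20, 0, 200),
                    sd_score = runif(20, 0, 120),
                    qc_pass = NA, exclusion_reason = "none")
  out2 <- qcFilter(big)
  expect_setequal(out2$retained$bead_id,
                  big$bead_id[big$sd_score < big$mean_score / 2])
  # idempotence
  out3 <- qcFilter(out2$retained)
  expect_equal(out3$retained$bead_id, out2$retained$bead_id)
  expect_equal(nrow(out3$excluded), 0L)
})
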