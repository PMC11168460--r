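# Independent brute-force oracles, written deliberately naively (scalar
# loops, direct formulas) so they share no code path with the package.

# Bilinear lookup at a single 0-based point, from first principles.
oracleBilinear <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  v <- 0
  for (dy in 0:1) for (dx in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy
    if (xi > ncol(img) - 1) { if (fx > 0) return(NA_real_); next }
    if (yi > nrow(img) - 1) { if (fy > 0) return(NA_real_); next }
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    v <- v + w * img[yi + 1, xi + 1]
  }
  v
}

# Rasterize one ray at the same grid points and scan min/max.
oracleProfileScore <- function(img, cx, cy, angle, dists) {
  lo <- Inf; hi <- -Inf
  for (d in dists) {
    v <- oracleBilinear(img, cx + d * cos(angle), cy + d * sin(angle))
    if (v < lo) lo <- v
    if (v > hi) hi <- v
  }
  hi - lo
}

# Rolling-ball background by direct evaluation of the ball opening,
# nearest-edge padding, O(n * k^2).
oracleRollingBall <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  r <- floor(radius)
  at <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  ero <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    lo <- Inf
    for (dy in -r:r) for (dx in -r:r) {
      d2 <- dx^2 + dy^2
      if (d2 > radius^2) next
      v <- at(img, i + dy, j + dx) - sqrt(radius^2 - d2)
      if (v < lo) lo <- v
    }
    ero[i, j] <- lo
  }
  bg <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    hi <- -Inf
    for (dy in -r:r) for (dx in -r:r) {
      d2 <- dx^2 + dy^2
      if (d2 > radius^2) next
      v <- at(ero, i + dy, j + dx) + sqrt(radius^2 - d2)
      if (v > hi) hi <- v
    }
    bg[i, j] <- hi
  }
  res <- img - bg
  res[res < 0] <- 0
  res
}

# Type II sums of squares from residual-sum-of-squares differences of
# explicitly fitted sub-models.
oracleTypeII <- function(df, response, A, B) {
  rss <- function(f) sum(resid(lm(f, data = df))^2)
  f <- function(s) as.formula(paste(response, "~", s))
  ssA <- rss(f(B)) - rss(f(paste(A, "+", B)))
  ssB <- rss(f(A)) - rss(f(paste(A, "+", B)))
  ssAB <- rss(f(paste(A, "+", B))) - rss(f(paste(A, "*", B)))
  ssRes <- rss(f(paste(A, "*", B)))
  list(A = ssA, B = ssB, AB = ssAB, res = ssRes)
}

# A disk-shaped label mask drawn directly.
diskMask <- function(nr, nc, cx, cy, r, label = 1L, mask = NULL) {
  if (is.null(mask)) mask <- matrix(0L, nr, nc)
  for (i in 1:nr) for (j in 1:nc)
    if ((j - 1 - cx)^2 + (i - 1 - cy)^2 <= r^2) mask[i, j] <- label
  mask
}

# Default acceptance-scale bead scene: coated and empty beads on a grid.
# The mCherry channel carries the bead coat (all beads visible, used for
# detection); EGFP is the probe/measurement channel where only coated beads
# have a bright rim — the two-channel layout of the real assay.
makeBeadScene <- function(nCoated, nEmpty, rim = 100, noiseSd = 0,
                          seed = 1L, radius = 16, thickness = 6,
                          background = 0, core = 0, twoChannel = FALSE) {
  n <- nCoated + nEmpty
  perRow <- ceiling(sqrt(n))
  pitch <- 2 * radius + 14
  margin <- radius + 7
  idx <- seq_len(n) - 1
  shape <- c(margin * 2 + (ceiling(n / perRow) - 1) * pitch,
             margin * 2 + (perRow - 1) * pitch)
  egfpRim <- c(rep(rim, nCoated), rep(0, nEmpty))
  beadSceneSpec(
    imageShape = pmax(shape, 2 * margin + 1),
    beads = data.frame(x = margin + (idx %% perRow) * pitch,
                       y = margin + (idx %/% perRow) * pitch,
                       radius = radius, rim_thickness = thickness),
    rimIntensity = if (twoChannel) cbind(EGFP = egfpRim, mCherry = 120)
                   else egfpRim,
    coreIntensity = core,
    backgroundLevel = if (twoChannel) c(EGFP = background,
                                        mCherry = background)
                      else c(EGFP = background),
    noiseSd = noiseSd, seed = seed)
}

# Match measured beads to truth records by centroid proximity; returns the
# truth row index for each measurement row (NA if nothing within maxDist).
matchBeadsToTruth <- function(meas, mask, truth, maxDist = 3) {
  vapply(meas$bead_id, function(l) {
    px <- which(mask == l, arr.ind = TRUE)
    cx <- mean(px[, 2] - 1); cy <- mean(px[, 1] - 1)
    d <- sqrt((truth$x - cx)^2 + (truth$y - cy)^2)
    if (min(d) <= maxDist) which.min(d) else NA_integer_
  }, integer(1))
}
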