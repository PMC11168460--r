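## Synthetic scene, trace and table generators with machine-readable ground
## truth. Every generator is driven by a single top-level seed; sub-draws
## consume the stream in documented order so identical spec + seed gives
## bitwise-identical output.

#' Specification of a synthetic bead scene
#'
#' Describes a field of agarose-type beads imaged in one or more fluorescence
#' channels: each bead is rendered as a bright annulus (the protein-coated
#' rim) of programmable intensity over a darker core, on a noisy background.
#' Hard-edged rendering (no point-spread blur) is the default so that
#' programmed intensities are exactly recoverable; optional Gaussian blur is
#' available via \code{blurSigma}.
#'
#' @param imageShape integer c(rows, cols) in px.
#' @param beads data.frame with one row per bead: columns \code{x}, \code{y}
#'   (center, 0-based px), \code{radius}, \code{rim_thickness} (px).
#' @param rimIntensity,coreIntensity numeric matrices (n_beads x n_channels,
#'   columns named by channel) or vectors recycled across beads; gray values.
#' @param backgroundLevel named numeric, background gray value per channel.
#' @param noiseSd additive Gaussian noise SD (gray values); clipped at 0.
#' @param blurSigma optional Gaussian blur sigma in px (0 = hard edges).
#' @param allowAdjacent logical; permit overlapping/touching beads (used to
#'   construct adjacency test scenes). Otherwise overlap is an error.
#' @param seed integer seed.
#' @return an object of class \code{BeadSceneSpec}.
#' @examples
#' spec <- beadSceneSpec(c(64, 64),
#'   beads = data.frame(x = 30, y = 30, radius = 12, rim_thickness = 4),
#'   rimIntensity = 100, coreIntensity = 0,
#'   backgroundLevel = c(mCherry = 0))
#' @export
beadSceneSpec <- function(imageShape, beads, rimIntensity, coreIntensity,
                          backgroundLevel, noiseSd = 0, blurSigma = 0,
                          allowAdjacent = FALSE, seed = 1L) {
  channels <- names(backgroundLevel)
  if (is.null(channels)) stop("backgroundLevel must be named by channel")
  n <- nrow(beads)
  asMat <- function(v, what) {
    if (is.matrix(v)) {
      if (is.null(colnames(v))) colnames(v) <- channels
      if (nrow(v) == 1L && n > 1L)
        v <- v[rep(1L, n), , drop = FALSE]
      if (nrow(v) != n)
        stop("intensity matrix must have one row per bead")
      v
    } else {
      matrix(rep(v, length.out = n * length(channels)), nrow = n,
             ncol = length(channels), dimnames = list(NULL, channels))
    }
  }
  spec <- structure(list(
    imageShape = as.integer(imageShape), beads = beads,
    rimIntensity = asMat(rimIntensity), coreIntensity = asMat(coreIntensity),
    backgroundLevel = backgroundLevel, noiseSd = noiseSd,
    blurSigma = blurSigma, allowAdjacent = isTRUE(allowAdjacent),
    seed = as.integer(seed)), class = "BeadSceneSpec")
  validateBeadSceneSpec(spec)
  spec
}

validateBeadSceneSpec <- function(spec) {
  b <- spec$beads
  if (nrow(b) > 0L) {
    if (any(b$rim_thickness < 1)) stop("invariant violated: rim_thickness >= 1")
    if (any(b$radius <= b$rim_thickness))
      stop("invariant violated: radius > rim_thickness")
    if (any(b$x < 0 | b$x > spec$imageShape[2] - 1 |
            b$y < 0 | b$y > spec$imageShape[1] - 1))
      stop("invariant violated: centers inside image")
  }
  if (any(spec$rimIntensity < 0) || any(spec$coreIntensity < 0) ||
      any(spec$backgroundLevel < 0))
    stop("invariant violated: all intensities >= 0")
  if (spec$noiseSd < 0) stop("invariant violated: noise_sd >= 0")
  if (!spec$allowAdjacent && nrow(b) > 1L) {
    d <- as.matrix(stats::dist(cbind(b$x, b$y)))
    rs <- outer(b$radius, b$radius, "+")
    diag(d) <- Inf
    if (any(d <= rs))
      stop("beads overlap; set allowAdjacent = TRUE for adjacency scenes")
  }
  invisible(TRUE)
}

#' Render a synthetic bead scene
#'
#' Each bead is drawn as an annulus of \code{rimIntensity} (pixels whose
#' center lies within \code{rim_thickness} of the bead radius) over a core of
#' \code{coreIntensity}, added on top of the channel background; Gaussian
#' noise of SD \code{noiseSd} is then added and the image clipped at 0.
#' Noise is drawn once per channel, in channel order.
#'
#' @param spec a [beadSceneSpec()].
#' @return list with elements \code{scene} ([ImageScene-class]) and
#'   \code{truth} ([SceneTruth-class]).
#' @examples
#' spec <- beadSceneSpec(c(64, 64),
#'   beads = data.frame(x = 30, y = 30, radius = 12, rim_thickness = 4),
#'   rimIntensity = 100, coreIntensity = 0,
#'   backgroundLevel = c(mCherry = 0))
#' out <- simulateBeadScene(spec)
#' max(getChannel(out$scene, "mCherry"))  # 100
#' @export
simulateBeadScene <- function(spec) {
  stopifnot(inherits(spec, "BeadSceneSpec"))
  validateBeadSceneSpec(spec)
  nr <- spec$imageShape[1]; nc <- spec$imageShape[2]
  channels <- names(spec$backgroundLevel)
  b <- spec$beads
  ## pixel-center coordinate grids (0-based)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  imgs <- withr::with_seed(spec$seed, {
    lapply(channels, function(ch) {
      img <- matrix(spec$backgroundLevel[[ch]], nr, nc)
      if (nrow(b) > 0L) for (i in seq_len(nrow(b))) {
        d2 <- (xs - b$x[i])^2 + (ys - b$y[i])^2
        r <- b$radius[i]; t <- b$rim_thickness[i]
        core <- d2 <= (r - t)^2
        rim <- d2 <= r^2 & !core
        img[core] <- spec$coreIntensity[i, ch]
        img[rim] <- spec$rimIntensity[i, ch]
      }
      if (spec$blurSigma > 0)
        img <- gaussianBlur(img, spec$blurSigma)
      if (spec$noiseSd > 0)
        img <- pmax(img + matrix(stats::rnorm(nr * nc, 0, spec$noiseSd),
                                 nr, nc), 0)
      img
    })
  })
  names(imgs) <- channels
  obj <- if (nrow(b) > 0L) {
    cbind(data.frame(object_id = seq_len(nrow(b)), kind = "bead",
                     x = b$x, y = b$y, radius = b$radius,
                     rim_thickness = b$rim_thickness),
          as.data.frame(`colnames<-`(spec$rimIntensity,
                                     paste0("rim_", channels))),
          as.data.frame(`colnames<-`(spec$coreIntensity,
                                     paste0("core_", channels))))
  } else {
    data.frame(object_id = integer(0), kind = character(0),
               x = numeric(0), y = numeric(0))
  }
  list(scene = ImageScene(imgs, meta = list(kind = "beads", seed = spec$seed)),
       truth = new("SceneTruth", objects = obj,
                   background = spec$backgroundLevel,
                   noiseSd = spec$noiseSd, seed = spec$seed))
}

## separable Gaussian blur with nearest-edge padding
gaussianBlur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      idx <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Specification of a synthetic condensate time series
#'
#' Diffraction-limited condensates are modeled as symmetric 2-D Gaussian
#' blobs (truncated at 4 sigma) placed at random non-overlapping positions in
#' a reference channel; each spot additionally carries probe-channel signal
#' with probability \code{colocFraction}, emulating partial colocalization of
#' a second receptor with reference-channel condensates.
#'
#' @param imageShape c(rows, cols) px.
#' @param nSpots integer vector, number of spots at each time point.
#' @param timePoints strictly increasing acquisition times (minutes).
#' @param refChannel,probeChannel channel names.
#' @param peakIntensity named numeric, peak blob intensity per channel (gray
#'   values above background).
#' @param sigma named numeric, blob sigma per channel (px).
#' @param colocFraction probability in [0, 1] that a reference spot also
#'   carries probe signal.
#' @param backgroundLevel named numeric background per channel.
#' @param noiseSd Gaussian noise SD.
#' @param seed integer seed.
#' @return an object of class \code{CondensateSceneSpec}.
#' @export
condensateSceneSpec <- function(imageShape, nSpots, timePoints,
                                refChannel = "mCherry",
                                probeChannel = "EGFP",
                                peakIntensity = c(mCherry = 200, EGFP = 200),
                                sigma = c(mCherry = 1.5, EGFP = 1.5),
                                colocFraction = 1,
                                backgroundLevel = c(mCherry = 10, EGFP = 10),
                                noiseSd = 0, seed = 1L) {
  spec <- structure(list(
    imageShape = as.integer(imageShape), nSpots = as.integer(nSpots),
    timePoints = as.numeric(timePoints), refChannel = refChannel,
    probeChannel = probeChannel, peakIntensity = peakIntensity,
    sigma = sigma, colocFraction = colocFraction,
    backgroundLevel = backgroundLevel, noiseSd = noiseSd,
    seed = as.integer(seed)), class = "CondensateSceneSpec")
  if (colocFraction < 0 || colocFraction > 1)
    stop("invariant violated: 0 <= coloc_fraction <= 1")
  if (any(spec$nSpots < 0)) stop("invariant violated: n_spots >= 0")
  if (length(spec$nSpots) != length(spec$timePoints))
    stop("nSpots must have one entry per time point")
  if (length(spec$timePoints) > 1L && any(diff(spec$timePoints) <= 0))
    stop("invariant violated: time_points strictly increasing")
  if (noiseSd < 0) stop("invariant violated: noise_sd >= 0")
  spec
}

#' Render a synthetic condensate time series
#'
#' One scene per time point. Per time point the draw order is: spot x
#' positions, spot y positions (jointly by rejection against overlap), then
#' the Bernoulli colocalization flags, then noise per channel in
#' (reference, probe) order.
#'
#' @param spec a [condensateSceneSpec()].
#' @return list with \code{scenes} (list of [ImageScene-class], one per time
#'   point) and \code{truth} ([SceneTruth-class] whose objects table has one
#'   row per spot with its \code{time} and \code{coloc} flag).
#' @export
simulateCondensateSeries <- function(spec) {
  stopifnot(inherits(spec, "CondensateSceneSpec"))
  nr <- spec$imageShape[1]; nc <- spec$imageShape[2]
  chans <- c(spec$refChannel, spec$probeChannel)
  ext <- ceiling(4 * max(spec$sigma))          # truncation radius
  minSep <- 2 * ext                            # non-overlap separation
  out <- withr::with_seed(spec$seed, {
    truthRows <- list(); scenes <- list(); oid <- 0L
    for (ti in seq_along(spec$timePoints)) {
      n <- spec$nSpots[ti]
      pos <- placeSpots(n, nr, nc, margin = ext, minSep = minSep)
      coloc <- if (n > 0L) stats::runif(n) < spec$colocFraction else logical(0)
      imgs <- lapply(chans, function(ch) {
        img <- matrix(spec$backgroundLevel[[ch]], nr, nc)
        draw <- if (ch == spec$refChannel) seq_len(n) else which(coloc)
        for (i in draw)
          img <- addGaussianSpot(img, pos$x[i], pos$y[i],
                                 spec$peakIntensity[[ch]], spec$sigma[[ch]])
        if (spec$noiseSd > 0)
          img <- pmax(img + matrix(stats::rnorm(nr * nc, 0, spec$noiseSd),
                                   nr, nc), 0)
        img
      })
      names(imgs) <- chans
      scenes[[ti]] <- ImageScene(imgs, meta = list(
        kind = "condensates", time = spec$timePoints[ti], seed = spec$seed))
      if (n > 0L)
        truthRows[[ti]] <- data.frame(
          object_id = oid + seq_len(n), kind = "spot",
          time = spec$timePoints[ti], x = pos$x, y = pos$y,
          sigma = spec$sigma[[spec$refChannel]], coloc = coloc)
      oid <- oid + n
    }
    list(scenes = scenes, truthRows = truthRows)
  })
  obj <- if (length(out$truthRows)) do.call(rbind, out$truthRows) else
    data.frame(object_id = integer(0), kind = character(0),
               time = numeric(0), x = numeric(0), y = numeric(0),
               sigma = numeric(0), coloc = logical(0))
  list(scenes = out$scenes,
       truth = new("SceneTruth", objects = obj,
                   background = spec$backgroundLevel,
                   noiseSd = spec$noiseSd, seed = spec$seed))
}

## rejection-sample n non-overlapping positions; error when capacity exceeded
placeSpots <- function(n, nr, nc, margin, minSep, maxTries = 200L) {
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  cap <- floor((nr - 2 * margin) * (nc - 2 * margin) / (minSep^2))
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(maxTries)) {
      x <- stats::runif(1, margin, nc - 1 - margin)
      y <- stats::runif(1, margin, nr - 1 - margin)
      if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= minSep^2)) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("cannot place ", n, " non-overlapping spots; approximate capacity ",
           cap, " at separation ", minSep, " px")
  }
  list(x = xs, y = ys)
}

addGaussianSpot <- function(img, x, y, peak, sigma) {
  ext <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  c0 <- max(0L, floor(x) - ext); c1 <- min(nc - 1L, ceiling(x) + ext)
  r0 <- max(0L, floor(y) - ext); r1 <- min(nr - 1L, ceiling(y) + ext)
  cx <- c0:c1; ry <- r0:r1
  d2 <- outer((ry - y)^2, (cx - x)^2, "+")
  blob <- peak * exp(-d2 / (2 * sigma^2))
  blob[d2 > (4 * sigma)^2] <- 0           # truncate at 4 sigma
  img[ry + 1L, cx + 1L] <- img[ry + 1L, cx + 1L] + blob
  img
}

#' Specification of a synthetic FRAP trace
#'
#' Single-exponential recovery model: after an instantaneous bleach to
#' \code{pre - bleachDepth}, intensity recovers as
#' \deqn{I(t) = I_{post} + m (I_{pre} - I_{post}) (1 - e^{-kt})}
#' where \eqn{m} is the mobile fraction and \eqn{k} the recovery rate.
#'
#' @param pre pre-bleach intensity level (gray values).
#' @param bleachDepth drop at the bleach frame (gray values).
#' @param mobileFraction m in [0, 1].
#' @param rate recovery rate k (1/s), >= 0.
#' @param frameInterval frame spacing (s); the assay default is 1 image/s.
#' @param duration post-bleach observation time (s); default 30 s.
#' @param nPreBleach number of pre-bleach frames.
#' @param noiseSd Gaussian noise SD (gray values) on every frame.
#' @param seed integer seed.
#' @return an object of class \code{FrapSpec}.
#' @export
frapSpec <- function(pre = 100, bleachDepth = 80, mobileFraction = 0.5,
                     rate = 0.5, frameInterval = 1, duration = 30,
                     nPreBleach = 5L, noiseSd = 0, seed = 1L) {
  if (mobileFraction < 0 || mobileFraction > 1)
    stop("invariant violated: 0 <= m <= 1")
  if (rate < 0) stop("invariant violated: k >= 0")
  if (duration <= 0) stop("invariant violated: duration > 0")
  if (duration < frameInterval)
    stop("duration shorter than one frame interval")
  if (bleachDepth <= 0 || bleachDepth > pre)
    stop("bleachDepth must be in (0, pre]")
  structure(list(pre = pre, bleachDepth = bleachDepth,
                 mobileFraction = mobileFraction, rate = rate,
                 frameInterval = frameInterval, duration = duration,
                 nPreBleach = as.integer(nPreBleach), noiseSd = noiseSd,
                 seed = as.integer(seed)), class = "FrapSpec")
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach frames sit at the pre-bleach level; the bleach frame (t = 0) at
#' \code{pre - bleachDepth}; post-bleach frames follow the single-exponential
#' recovery of the spec, with optional Gaussian noise on every frame (drawn
#' in frame order).
#'
#' @param spec a [frapSpec()].
#' @return a [FrapTrace-class].
#' @export
generateFrapTrace <- function(spec) {
  stopifnot(inherits(spec, "FrapSpec"))
  post <- spec$pre - spec$bleachDepth
  tPost <- seq(0, spec$duration, by = spec$frameInterval)
  tPre <- -(spec$nPreBleach:1) * spec$frameInterval
  times <- c(tPre, tPost)
  ideal <- c(rep(spec$pre, spec$nPreBleach),
             post + spec$mobileFraction * (spec$pre - post) *
               (1 - exp(-spec$rate * tPost)))
  vals <- withr::with_seed(spec$seed, {
    if (spec$noiseSd > 0) ideal + stats::rnorm(length(ideal), 0, spec$noiseSd)
    else ideal
  })
  FrapTrace(times, vals, preBleachIndices = seq_len(spec$nPreBleach),
            bleachIndex = spec$nPreBleach + 1L)
}

#' Specification of a synthetic nested bead table
#'
#' Emulates the hierarchical structure of the bead assay: beads nested in
#' wells nested in experiment replicates, with a fixed condition effect and
#' Gaussian random intercepts for replicate and well plus residual noise:
#' \deqn{y_{crwb} = \mu + \delta_c + u_r + v_{rw} + e_{crwb}}
#'
#' Each replicate contains \code{nWells} wells per condition; well labels
#' repeat across replicates (as they do on real plates), so analysis code
#' must disambiguate them.
#'
#' @param conditionEffects named numeric, fixed effect per condition (gray
#'   values added to \code{baseline}).
#' @param baseline grand mean response (gray values).
#' @param nReplicates,nWells,nBeads replicates, wells per condition per
#'   replicate, and beads per well.
#' @param replicateSd,wellSd,residualSd random-intercept and residual SDs.
#' @param seed integer seed.
#' @return an object of class \code{BeadTableSpec}.
#' @export
beadTableSpec <- function(conditionEffects = c(empty = 0, coated = 50),
                          baseline = 100, nReplicates = 3L, nWells = 4L,
                          nBeads = 30L, replicateSd = 10, wellSd = 10,
                          residualSd = 20, seed = 1L) {
  if (is.null(names(conditionEffects)))
    stop("conditionEffects must be named by condition")
  if (any(c(replicateSd, wellSd, residualSd) < 0))
    stop("invariant violated: all SDs >= 0")
  if (any(c(nReplicates, nWells, nBeads) < 1))
    stop("invariant violated: counts >= 1")
  structure(list(conditionEffects = conditionEffects, baseline = baseline,
                 nReplicates = as.integer(nReplicates),
                 nWells = as.integer(nWells), nBeads = as.integer(nBeads),
                 replicateSd = replicateSd, wellSd = wellSd,
                 residualSd = residualSd, seed = as.integer(seed)),
            class = "BeadTableSpec")
}

#' Simulate a per-bead summary table with nested random effects
#'
#' Draw order: replicate intercepts, then well intercepts (replicate-major,
#' condition-major within replicate), then residuals bead by bead.
#'
#' @param spec a [beadTableSpec()].
#' @return data.frame with columns \code{bead_id}, \code{replicate_id},
#'   \code{well_id}, \code{condition}, \code{mean_score}. Attribute
#'   \code{"truth"} carries the programmed effects and SDs.
#' @export
simulateBeadTable <- function(spec) {
  stopifnot(inherits(spec, "BeadTableSpec"))
  conds <- names(spec$conditionEffects)
  nC <- length(conds); nR <- spec$nReplicates
  nW <- spec$nWells; nB <- spec$nBeads
  tab <- withr::with_seed(spec$seed, {
    u <- stats::rnorm(nR, 0, spec$replicateSd)
    v <- stats::rnorm(nR * nC * nW, 0, spec$wellSd)
    rows <- vector("list", nR * nC * nW)
    wi <- 0L
    for (r in seq_len(nR)) for (ci in seq_len(nC)) for (w in seq_len(nW)) {
      wi <- wi + 1L
      wellLabel <- paste0("W", (ci - 1L) * nW + w)   # repeats across reps
      e <- stats::rnorm(nB, 0, spec$residualSd)
      rows[[wi]] <- data.frame(
        replicate_id = paste0("R", r), well_id = wellLabel,
        condition = conds[ci],
        mean_score = spec$baseline + spec$conditionEffects[[ci]] +
          u[r] + v[wi] + e)
    }
    do.call(rbind, rows)
  })
  tab <- cbind(bead_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "truth") <- list(effects = spec$conditionEffects,
                             baseline = spec$baseline,
                             replicateSd = spec$replicateSd,
                             wellSd = spec$wellSd,
                             residualSd = spec$residualSd)
  tab
}

#' Simulate a paired targeted-MS peptide intensity table
#'
#' Generates long-format PRM-style intensity records for sample pairs (one
#' wild-type DUB treated, one catalytically dead), with five unmodified
#' reference peptides and a set of GG-remnant modified peptides whose
#' wild-type abundance is depleted by programmed log2 fold changes. Each
#' sample carries a lognormal global intensity factor, which the
#' reference-sum normalization must cancel.
#'
#' @param sites character vector of site labels for modified peptides.
#' @param log2fc named or unnamed numeric, programmed log2 change (wt over
#'   control) per site.
#' @param nPairs number of sample pairs.
#' @param refIds ids of the five unmodified reference peptides.
#' @param baseIntensity median raw intensity scale.
#' @param cvNoise lognormal measurement noise CV on each intensity.
#' @param seed integer seed.
#' @return data.frame with columns \code{peptide_id}, \code{site},
#'   \code{modified}, \code{sample_id}, \code{pair_id}, \code{condition},
#'   \code{intensity}; attribute \code{"truth"} holds the programmed log2
#'   fold changes.
#' @export
simulatePrmTable <- function(sites = c("K254", "K267", "K311", "K317",
                                       "K321", "K353", "K369"),
                             log2fc = rep(0, length(sites)),
                             nPairs = 3L,
                             refIds = paste0("ref", 1:5),
                             baseIntensity = 1e6, cvNoise = 0.05,
                             seed = 1L) {
  stopifnot(length(log2fc) == length(sites), length(refIds) == 5L)
  modIds <- paste0("GG_", sites)
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(nPairs)) for (cond in c("wt", "C221A")) {
      sampleId <- paste0("pair", p, "_", cond)
      sf <- stats::rlnorm(1, 0, 0.3)          # per-sample global factor
      noise <- function(n) stats::rlnorm(n, 0, sqrt(log(1 + cvNoise^2)))
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = refIds, site = NA_character_, modified = FALSE,
        sample_id = sampleId, pair_id = paste0("pair", p), condition = cond,
        intensity = baseIntensity * sf * noise(5))
      fold <- if (cond == "wt") 2^log2fc else rep(1, length(sites))
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = modIds, site = sites, modified = TRUE,
        sample_id = sampleId, pair_id = paste0("pair", p), condition = cond,
        intensity = 0.2 * baseIntensity * sf * fold * noise(length(sites)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(sites = sites, log2fc = log2fc)
    out
  })
}
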