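## Condensate counting, rolling-ball background correction, formation
## kinetics and cross-channel colocalization fractions.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (non-flat, hemispherical) structuring element of the given
#' radius — the classical rolling-ball construction: the background at each
#' pixel is the highest position of the ball rolled under the intensity
#' surface. The estimate is subtracted and the result clipped at 0. Edges
#' are handled by nearest-pixel replication, so a constant image maps
#' exactly to 0.
#'
#' Typical radii for diffraction-limited condensates are 1-2 px; features
#' narrower than the ball are preserved essentially unchanged.
#'
#' @param channel numeric matrix (gray values).
#' @param radius ball radius in px, >= 1.
#' @return background-subtracted matrix, clipped at 0.
#' @examples
#' rollingBallSubtract(matrix(7, 16, 16), 2)  # all zeros
#' @export
rollingBallSubtract <- function(channel, radius) {
  stopifnot(radius >= 1)
  if (radius > min(dim(channel)) / 2)
    warning("rolling-ball radius ", radius,
            " exceeds half the image side; proceeding")
  off <- ballOffsets(radius)
  eroded <- morphBall(channel, off, erode = TRUE)
  bg <- morphBall(eroded, off, erode = FALSE)
  pmax(channel - bg, 0)
}

## offsets (dx, dy, height) of the ball structuring element
ballOffsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 <= radius^2
  list(dx = g$dx[keep], dy = g$dy[keep],
       h = sqrt(radius^2 - d2[keep]))
}

## non-flat grayscale erosion/dilation via shifted copies with
## nearest-edge padding
morphBall <- function(img, off, erode) {
  nr <- nrow(img); nc <- ncol(img)
  acc <- NULL
  for (i in seq_along(off$dx)) {
    ridx <- pmin(pmax(seq_len(nr) + off$dy[i], 1L), nr)
    cidx <- pmin(pmax(seq_len(nc) + off$dx[i], 1L), nc)
    shifted <- img[ridx, cidx, drop = FALSE]
    term <- if (erode) shifted - off$h[i] else shifted + off$h[i]
    acc <- if (is.null(acc)) term
           else if (erode) pmin(acc, term) else pmax(acc, term)
  }
  acc
}

#' Count condensates in one channel
#'
#' Thresholds the channel, labels connected components and discards those
#' below the minimum area. Threshold policies: \code{"otsu"} (Otsu's method
#' on the channel histogram), \code{"fixed:<value>"} (absolute gray value),
#' or \code{"bg:<k>"} (robust background statistics: median + k MAD-based
#' SDs).
#'
#' @param channel numeric matrix, typically background-corrected first.
#' @param scene optional [ImageScene-class]; when given, per-channel mean
#'   intensities inside each spot mask are reported for every channel.
#' @param thresholdPolicy \code{"otsu"}, \code{"fixed:<v>"} or
#'   \code{"bg:<k>"}.
#' @param minArea minimum spot area in px (default 4).
#' @param imageId identifier stored in the result.
#' @param time acquisition time stored in the result (minutes).
#' @return a [CondensateSet-class].
#' @export
countCondensates <- function(channel, scene = NULL,
                             thresholdPolicy = "otsu", minArea = 4,
                             imageId = "image", time = NA_real_) {
  rng <- range(channel)
  if (rng[1] == rng[2]) {
    return(new("CondensateSet", imageId = imageId, time = time,
               spots = emptySpotTable(scene),
               labels = matrix(0L, nrow(channel), ncol(channel)),
               threshold = rng[2], minArea = minArea))
  }
  thr <- resolveThreshold(channel, thresholdPolicy)
  bw <- channel > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  nr <- nrow(channel)
  idx <- which(lab > 0)
  byLabel <- split(idx, lab[idx])
  out <- matrix(0L, nr, ncol(channel))
  rows <- list()
  nid <- 0L
  for (px in byLabel) {
    if (length(px) < minArea) next
    nid <- nid + 1L
    out[px] <- nid
    col <- (px - 1L) %/% nr; row0 <- (px - 1L) %% nr
    row <- data.frame(spot_id = nid, x = mean(col), y = mean(row0),
                      area = length(px))
    if (!is.null(scene)) {
      for (ch in channelNames(scene))
        row[[paste0("mean_", ch)]] <- mean(getChannel(scene, ch)[px])
    } else {
      row$mean_intensity <- mean(channel[px])
    }
    rows[[nid]] <- row
  }
  spots <- if (nid > 0L) do.call(rbind, rows) else emptySpotTable(scene)
  new("CondensateSet", imageId = imageId, time = time, spots = spots,
      labels = out, threshold = thr, minArea = minArea)
}

emptySpotTable <- function(scene = NULL) {
  df <- data.frame(spot_id = integer(0), x = numeric(0), y = numeric(0),
                   area = numeric(0))
  if (!is.null(scene))
    for (ch in channelNames(scene)) df[[paste0("mean_", ch)]] <- numeric(0)
  else df$mean_intensity <- numeric(0)
  df
}

resolveThreshold <- function(channel, policy) {
  if (identical(policy, "otsu")) {
    rng <- range(channel)
    scaled <- (channel - rng[1]) / (rng[2] - rng[1])
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
      (rng[2] - rng[1]) + rng[1]
  } else if (startsWith(policy, "fixed:")) {
    as.numeric(sub("^fixed:", "", policy))
  } else if (startsWith(policy, "bg:")) {
    k <- as.numeric(sub("^bg:", "", policy))
    stats::median(channel) + k * stats::mad(channel)
  } else stop("unknown threshold policy '", policy, "'")
}

#' Condensate formation kinetics over a time series
#'
#' Applies [countCondensates()] with fixed parameters to every scene of a
#' series and returns the (time, count) table used for formation-kinetics
#' plots.
#'
#' @param scenes list of [ImageScene-class] sharing shape and channel
#'   layout, with \code{time} in their metadata (minutes).
#' @param channel channel to count in.
#' @param thresholdPolicy,minArea passed to [countCondensates()].
#' @param rollingBallRadius optional radius; when given, each channel is
#'   background-corrected before counting.
#' @return data.frame with columns \code{time}, \code{count}.
#' @export
condensateKinetics <- function(scenes, channel, thresholdPolicy = "bg:5",
                               minArea = 4, rollingBallRadius = NULL) {
  if (length(scenes) == 0L)
    return(data.frame(time = numeric(0), count = integer(0)))
  d <- sceneDim(scenes[[1]])
  for (s in scenes) {
    if (!identical(sceneDim(s), d))
      stop("scenes in a series must share the same shape")
    if (!channel %in% channelNames(s))
      stop("channel '", channel, "' missing from a scene in the series")
  }
  rows <- lapply(scenes, function(s) {
    img <- getChannel(s, channel)
    if (!is.null(rollingBallRadius))
      img <- rollingBallSubtract(img, rollingBallRadius)
    cs <- countCondensates(img, thresholdPolicy = thresholdPolicy,
                           minArea = minArea,
                           time = sceneMeta(s)$time %||% NA_real_)
    data.frame(time = cs@time, count = nSpots(cs))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Colocalization fraction of reference condensates in a probe channel
#'
#' A reference condensate is scored positive when its mean probe intensity
#' within the spot mask exceeds the probe background mean by more than
#' \code{k} background SDs, where background statistics are taken over all
#' probe pixels outside every spot mask (mask overlap, not centroid
#' distance, defines "contained"). The fraction of positive reference spots
#' is the colocalization score.
#'
#' @param ref a [CondensateSet-class] from the reference channel.
#' @param probeChannel numeric matrix, same shape as the reference image.
#' @param k positivity stringency in background SDs (default 3).
#' @return list of class \code{ColocResult}: \code{nRef}, \code{nPositive},
#'   \code{fraction}, \code{k}, \code{bgMean}, \code{bgSd}, \code{flagged}
#'   (TRUE when there were no reference spots and the fraction defaults
#'   to 0).
#' @export
colocalizationFraction <- function(ref, probeChannel, k = 3) {
  if (!identical(dim(probeChannel), dim(spotLabels(ref))))
    stop("probe channel shape does not match the reference image")
  lab <- spotLabels(ref)
  bgPix <- probeChannel[lab == 0]
  bgMean <- mean(bgPix)
  bgSd <- stats::sd(bgPix)
  n <- nSpots(ref)
  if (n == 0L)
    return(structure(list(nRef = 0L, nPositive = 0L, fraction = 0,
                          k = k, bgMean = bgMean, bgSd = bgSd,
                          flagged = TRUE), class = "ColocResult"))
  idx <- which(lab > 0)
  spotMeans <- vapply(split(probeChannel[idx], lab[idx]), mean, numeric(1))
  pos <- spotMeans[as.character(seq_len(n))] > bgMean + k * bgSd
  structure(list(nRef = n, nPositive = sum(pos),
                 fraction = sum(pos) / n, k = k, bgMean = bgMean,
                 bgSd = bgSd, flagged = FALSE), class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("Colocalization: %d / %d reference spots positive (%.1f%%), k = %g%s\n",
              x$nPositive, x$nRef, 100 * x$fraction, x$k,
              if (x$flagged) " [no reference spots]" else ""))
  invisible(x)
}
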