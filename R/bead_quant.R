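## Bead pull-down quantification: detection, circular ROI fitting, radial
## line profiles, adjacency exclusion, min-max scoring, per-bead summaries
## and the dispersion-based QC filter.

#' Detect beads in a single channel
#'
#' The built-in \code{"reference"} backend thresholds at the image median
#' plus \code{k} robust SDs (MAD-based), fills holes (bead cores are dark),
#' labels connected components, and discards components that are too small or
#' insufficiently circular — the fill fraction of a component against the
#' circle of its maximal centroid-to-pixel radius must reach
#' \code{minFill}, which deterministically rejects merged bead doublets.
#' External segmenters (e.g. an AI model) can be plugged in by passing a
#' function as \code{backend}; it must return an integer label matrix of the
#' same shape (0 = background).
#'
#' @param channel numeric matrix, one image channel (gray values).
#' @param backend \code{"reference"} or a \code{function(channel, params)}
#'   returning a label matrix.
#' @param params list of reference-backend parameters: \code{k} (default 5,
#'   threshold in MADs above the median), \code{minArea} (default 100 px),
#'   \code{minFill} (default 0.6).
#' @param imageId identifier used in backend error messages.
#' @return integer label matrix with labels compacted to 1..n; attribute
#'   \code{"discarded"} is a data.frame logging each rejected component with
#'   its reason.
#' @examples
#' spec <- beadSceneSpec(c(80, 80),
#'   beads = data.frame(x = 40, y = 40, radius = 14, rim_thickness = 4),
#'   rimIntensity = 100, coreIntensity = 60,
#'   backgroundLevel = c(mCherry = 5))
#' m <- detectBeads(getChannel(simulateBeadScene(spec)$scene, "mCherry"))
#' max(m)  # 1 bead
#' @export
detectBeads <- function(channel, backend = "reference", params = list(),
                        imageId = "image") {
  if (is.function(backend)) {
    mask <- tryCatch(backend(channel, params), error = function(e)
      stop("segmentation backend failed on '", imageId, "': ",
           conditionMessage(e), call. = FALSE))
    if (!is.matrix(mask) || !identical(dim(mask), dim(channel)))
      stop("backend returned an invalid mask for '", imageId, "'")
    return(compactLabels(mask))
  }
  if (!identical(backend, "reference"))
    stop("unknown backend; use \"reference\" or a function")
  p <- utils::modifyList(list(k = 5, minArea = 100, minFill = 0.6), params)
  discarded <- data.frame(component = integer(0), area = numeric(0),
                          reason = character(0))
  med <- stats::median(channel)
  madSd <- stats::mad(channel)
  thr <- med + p$k * madSd
  bw <- channel > thr
  if (!any(bw)) {
    out <- matrix(0L, nrow(channel), ncol(channel))
    attr(out, "discarded") <- discarded
    return(out)
  }
  bw <- EBImage::fillHull(EBImage::Image(bw))
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  nr <- nrow(channel)
  idx <- which(lab > 0)
  byLabel <- split(idx, lab[idx])
  out <- matrix(0L, nr, ncol(channel))
  nid <- 0L
  for (l in names(byLabel)) {
    px <- byLabel[[l]]
    area <- length(px)
    if (area < p$minArea) {
      discarded <- rbind(discarded, data.frame(
        component = as.integer(l), area = area, reason = "below-min-area"))
      next
    }
    ## fill fraction against the enclosing circle centered at the centroid
    col <- (px - 1L) %/% nr; row <- (px - 1L) %% nr
    cx <- mean(col); cy <- mean(row)
    rmax <- sqrt(max((col - cx)^2 + (row - cy)^2)) + 0.5
    fill <- area / (pi * rmax^2)
    if (fill < p$minFill) {
      discarded <- rbind(discarded, data.frame(
        component = as.integer(l), area = area,
        reason = "low-fill-fraction"))
      next
    }
    nid <- nid + 1L
    out[px] <- nid
  }
  attr(out, "discarded") <- discarded
  out
}

compactLabels <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_along(labs)) out[mask == labs[i]] <- i
  out
}

#' Fit a circular ROI to one labeled bead
#'
#' Center is the centroid of the labeled pixels; radius the equivalent-area
#' circle radius \code{sqrt(area / pi)}. Exact for disk-shaped masks and
#' parameter-free.
#'
#' @param mask integer label matrix.
#' @param label which bead label to fit.
#' @param minRadius beads with smaller fitted radius are flagged (not
#'   errors); default 3 px.
#' @return a \code{BeadROI}: list with \code{beadId}, \code{x}, \code{y}
#'   (0-based px), \code{radius}, \code{ok}, \code{reason}.
#' @export
fitCircularROI <- function(mask, label, minRadius = 3) {
  px <- which(mask == label, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("label ", label, " not present in mask")
  x <- mean(px[, 2] - 1); y <- mean(px[, 1] - 1)
  radius <- sqrt(nrow(px) / pi)
  ok <- radius >= minRadius
  structure(list(beadId = as.integer(label), x = x, y = y, radius = radius,
                 ok = ok,
                 reason = if (ok) "none" else "below-min-radius"),
            class = "BeadROI")
}

#' Draw radial line profiles from a bead ROI center
#'
#' \code{nLines} rays at equally spaced angles starting at 0 rad are sampled
#' by bilinear interpolation at distances 0, \code{step}, ... up to
#' \code{(1 + extensionFrac) * radius} (final grid point at or below that
#' length), so each profile runs from the bead center out past the rim into
#' the local background. Profiles with any sample outside the image are
#' flagged excluded with reason \code{"out-of-bounds"}.
#'
#' @param roi a \code{BeadROI} from [fitCircularROI()].
#' @param channel numeric matrix to sample.
#' @param nLines number of rays (default 8).
#' @param extensionFrac extension beyond the fitted radius as a fraction of
#'   the radius (default 0.2).
#' @param step sample spacing in px (default 1).
#' @return list of \code{LineProfile}: each a list with \code{beadId},
#'   \code{angle}, \code{distances}, \code{samples}, \code{excluded},
#'   \code{reason}.
#' @export
drawProfiles <- function(roi, channel, nLines = 8L, extensionFrac = 0.2,
                         step = 1) {
  stopifnot(nLines >= 1L, extensionFrac >= 0, step > 0)
  angles <- 2 * pi * (seq_len(nLines) - 1L) / nLines
  len <- (1 + extensionFrac) * roi$radius
  dists <- seq(0, len, by = step)
  nr <- nrow(channel); nc <- ncol(channel)
  lapply(angles, function(a) {
    xs <- roi$x + dists * cos(a)
    ys <- roi$y + dists * sin(a)
    oob <- xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1
    if (any(oob)) {
      samples <- rep(NA_real_, length(dists))
      samples[!oob] <- bilinearSample(channel, xs[!oob], ys[!oob])
      structure(list(beadId = roi$beadId, originX = roi$x, originY = roi$y,
                     angle = a, distances = dists, samples = samples,
                     excluded = TRUE, reason = "out-of-bounds"),
                class = "LineProfile")
    } else {
      structure(list(beadId = roi$beadId, originX = roi$x, originY = roi$y,
                     angle = a, distances = dists,
                     samples = bilinearSample(channel, xs, ys),
                     excluded = FALSE, reason = "none"),
                class = "LineProfile")
    }
  })
}

## bilinear interpolation at 0-based (x, y); callers guarantee in-bounds
bilinearSample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Exclude profiles protruding into adjacent beads
#'
#' Using the combined label mask of all detected beads, a profile is excluded
#' (reason \code{"adjacent-bead"}) if and only if any of its sample points
#' falls on a pixel labeled with a bead other than its own. Already-excluded
#' profiles keep their flags.
#'
#' @param profiles list of \code{LineProfile} from [drawProfiles()].
#' @param mask combined integer label mask of all beads.
#' @param ownLabel label of the bead the profiles belong to.
#' @return the profile list with updated exclusion flags.
#' @export
excludeAdjacent <- function(profiles, mask, ownLabel) {
  if (!any(mask == ownLabel))
    stop("own label ", ownLabel, " not present in combined mask")
  nr <- nrow(mask); nc <- ncol(mask)
  lapply(profiles, function(p) {
    if (p$excluded) return(p)
    xs <- round(p$originX + p$distances * cos(p$angle))
    ys <- round(p$originY + p$distances * sin(p$angle))
    inb <- xs >= 0 & xs <= nc - 1 & ys >= 0 & ys <= nr - 1
    labs <- mask[cbind(ys[inb] + 1, xs[inb] + 1)]
    if (any(labs != 0 & labs != ownLabel)) {
      p$excluded <- TRUE
      p$reason <- "adjacent-bead"
    }
    p
  })
}

#' Score one line profile by its min-max gray-value difference
#'
#' @param profile a retained \code{LineProfile}.
#' @return numeric score \code{max(samples) - min(samples)}, always >= 0.
#' @examples
#' p <- structure(list(samples = c(10, 80, 30), excluded = FALSE),
#'                class = "LineProfile")
#' scoreProfile(p)  # 70
#' @export
scoreProfile <- function(profile) {
  if (isTRUE(profile$excluded))
    stop("cannot score an excluded profile (reason: ", profile$reason, ")")
  s <- profile$samples
  max(s) - min(s)
}

#' Summarize one bead from its scored profiles
#'
#' Mean and sample SD (n-1 denominator; a single profile gives SD 0 by
#' convention) over the retained profiles' scores, with the dispersion QC
#' verdict: a bead passes when its score SD is strictly below half its mean
#' score.
#'
#' @param profiles list of \code{LineProfile} (excluded ones are skipped).
#' @param beadId,wellId,replicateId,condition grouping labels.
#' @return one-row data.frame with columns \code{bead_id}, \code{well_id},
#'   \code{replicate_id}, \code{condition}, \code{n_profiles_retained},
#'   \code{mean_score}, \code{sd_score}, \code{qc_pass},
#'   \code{exclusion_reason}. Beads with no retained profiles are reported
#'   with \code{exclusion_reason = "no-retained-profiles"} and NA summaries.
#' @export
summarizeBead <- function(profiles, beadId, wellId = "W1",
                          replicateId = "R1", condition = "cond") {
  stopifnot(length(beadId) == 1L, length(wellId) == 1L,
            length(replicateId) == 1L, length(condition) == 1L)
  kept <- Filter(function(p) !p$excluded, profiles)
  if (length(kept) == 0L)
    return(data.frame(bead_id = beadId, well_id = wellId,
                      replicate_id = replicateId, condition = condition,
                      n_profiles_retained = 0L, mean_score = NA_real_,
                      sd_score = NA_real_, qc_pass = FALSE,
                      exclusion_reason = "no-retained-profiles"))
  scores <- vapply(kept, scoreProfile, numeric(1))
  m <- mean(scores)
  s <- if (length(scores) > 1L) stats::sd(scores) else 0
  data.frame(bead_id = beadId, well_id = wellId, replicate_id = replicateId,
             condition = condition, n_profiles_retained = length(scores),
             mean_score = m, sd_score = s, qc_pass = s < m / 2,
             exclusion_reason = "none")
}

#' Dispersion QC filter over a bead measurement table
#'
#' Retains exactly the beads whose score SD is strictly below half their mean
#' score; beads with SD equal to or greater than mean/2 are excluded (the
#' boundary case SD = mean/2 is excluded, as is mean 0 with SD 0). Beads with
#' no retained profiles are excluded as well.
#'
#' @param measurements data.frame of [summarizeBead()] rows.
#' @return list with \code{retained} (the passing subset) and
#'   \code{excluded} (a report with \code{mean_score}, \code{sd_score},
#'   \code{ratio} = sd/mean and the reason).
#' @export
qcFilter <- function(measurements) {
  stopifnot(all(c("mean_score", "sd_score") %in% names(measurements)))
  noProf <- measurements$n_profiles_retained == 0L
  pass <- !noProf & measurements$sd_score < measurements$mean_score / 2
  excluded <- measurements[!pass, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$ratio <- excluded$sd_score / excluded$mean_score
    excluded$reason <- ifelse(noProf[!pass], "no-retained-profiles",
                              "sd-ge-half-mean")
  } else {
    excluded$ratio <- numeric(0)
    excluded$reason <- character(0)
  }
  ret <- measurements[pass, , drop = FALSE]
  if (nrow(ret)) ret$qc_pass <- TRUE
  list(retained = ret, excluded = excluded)
}

#' Quantify all beads in one scene channel
#'
#' End-to-end per-image bead quantification: detect (or take a precomputed
#' mask), fit circular ROIs, draw radial profiles on the measurement channel,
#' exclude profiles protruding into adjacent beads, score by min-max
#' difference, and summarize per bead. ROIs below the minimum radius and
#' beads without retained profiles appear in the output with their exclusion
#' reason rather than being silently dropped.
#'
#' @param scene an [ImageScene-class].
#' @param channel name of the measurement channel to score.
#' @param detectChannel channel used for detection (default: same).
#' @param mask optional precomputed label mask (skips detection).
#' @param wellId,replicateId,condition grouping labels for all beads in the
#'   scene.
#' @param nLines,extensionFrac,step profile parameters, see [drawProfiles()].
#' @param minRadius minimum fitted ROI radius (px).
#' @param detectParams parameters for [detectBeads()].
#' @return data.frame of per-bead measurements (one row per detected bead);
#'   attribute \code{"profiles"} holds the per-bead profile lists.
#' @export
quantifyBeads <- function(scene, channel, detectChannel = channel,
                          mask = NULL, wellId = "W1", replicateId = "R1",
                          condition = "cond", nLines = 8L,
                          extensionFrac = 0.2, step = 1, minRadius = 3,
                          detectParams = list()) {
  img <- getChannel(scene, channel)
  if (is.null(mask))
    mask <- detectBeads(getChannel(scene, detectChannel),
                        params = detectParams)
  n <- max(mask)
  rows <- vector("list", n)
  allProfiles <- vector("list", n)
  for (l in seq_len(n)) {
    roi <- fitCircularROI(mask, l, minRadius = minRadius)
    if (!roi$ok) {
      rows[[l]] <- data.frame(bead_id = l, well_id = wellId,
                              replicate_id = replicateId,
                              condition = condition,
                              n_profiles_retained = 0L,
                              mean_score = NA_real_, sd_score = NA_real_,
                              qc_pass = FALSE, exclusion_reason = roi$reason)
      next
    }
    prof <- drawProfiles(roi, img, nLines = nLines,
                         extensionFrac = extensionFrac, step = step)
    prof <- excludeAdjacent(prof, mask, roi$beadId)
    allProfiles[[l]] <- prof
    rows[[l]] <- summarizeBead(prof, beadId = l, wellId = wellId,
                               replicateId = replicateId,
                               condition = condition)
  }
  out <- if (n > 0L) do.call(rbind, rows) else
    data.frame(bead_id = integer(0), well_id = character(0),
               replicate_id = character(0), condition = character(0),
               n_profiles_retained = integer(0), mean_score = numeric(0),
               sd_score = numeric(0), qc_pass = logical(0),
               exclusion_reason = character(0))
  rownames(out) <- NULL
  attr(out, "profiles") <- allProfiles
  out
}
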