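#' @import methods
NULL

#' Multi-channel fluorescence image scene
#'
#' An \code{ImageScene} holds one acquisition position: a set of named
#' single-channel 2-D intensity arrays of equal shape (gray values, row =
#' image y, column = image x) plus free-form acquisition metadata (time point,
#' position index, pixel size, ...).
#'
#' Coordinates used throughout the package are 0-based with \code{x} along
#' columns, \code{y} along rows, and pixel centers at integer coordinates.
#' Angles are measured from the +x axis, counterclockwise.
#'
#' @slot channels named list of numeric matrices, one per channel.
#' @slot meta named list of acquisition metadata.
#'
#' @seealso [ImageScene()], [getChannel()], [simulateBeadScene()]
#' @export
setClass("ImageScene",
  representation(channels = "list", meta = "list"),
  prototype(channels = list(), meta = list()))

setValidity("ImageScene", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("scene has no channels")
  if (is.null(names(ch)) || anyNA(names(ch)) || any(names(ch) == ""))
    return("all channels must be named")
  if (anyDuplicated(names(ch))) return("channel names must be unique")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("each channel must be a 2-D matrix")
  d <- dim(ch[[1]])
  if (!all(vapply(ch, function(m) identical(dim(m), d), logical(1))))
    return("all channels must share the same shape")
  TRUE
})

#' Construct an ImageScene
#'
#' @param channels named list of numeric matrices (gray values), all of the
#'   same shape.
#' @param meta optional named list of metadata (e.g. \code{time},
#'   \code{position}).
#' @return an [ImageScene-class] object.
#' @examples
#' sc <- ImageScene(list(mCherry = matrix(0, 8, 8)))
#' channelNames(sc)
#' @export
ImageScene <- function(channels, meta = list()) {
  new("ImageScene", channels = channels, meta = meta)
}

#' @describeIn ImageScene channel names of a scene.
#' @param x,object an \code{ImageScene}.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn ImageScene extract one channel as a matrix.
#' @param channel channel name.
#' @export
getChannel <- function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("unknown channel '", channel, "'; scene has: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[channel]]
}

#' @describeIn ImageScene image shape as c(rows, cols).
#' @export
sceneDim <- function(x) dim(x@channels[[1]])

#' @describeIn ImageScene acquisition metadata list.
#' @export
sceneMeta <- function(x) x@meta

setMethod("show", "ImageScene", function(object) {
  d <- sceneDim(object)
  cat("ImageScene:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  if (!is.null(object@meta$time))
    cat("  time:", object@meta$time, "\n")
  invisible(NULL)
})

#' Ground truth for a synthetic scene
#'
#' Per-object records (beads or spots) with the programmed geometry and
#' intensities, plus the scene-level background, noise level and seed, so that
#' every downstream measurement can be checked against what was rendered.
#'
#' @slot objects data.frame with one row per rendered object. Columns include
#'   \code{object_id}, \code{kind} ("bead" or "spot"), \code{x}, \code{y} and,
#'   depending on kind, \code{radius}/\code{rim_thickness} or \code{sigma},
#'   per-channel programmed intensities, a \code{coloc} flag for spots, and
#'   \code{time} for time-resolved series.
#' @slot background named numeric, programmed background per channel.
#' @slot noiseSd numeric, programmed Gaussian noise SD.
#' @slot seed integer seed that produced the scene.
#' @export
setClass("SceneTruth",
  representation(objects = "data.frame", background = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SceneTruth", function(object) {
  df <- object@objects
  if (nrow(df) > 0L && anyDuplicated(df$object_id))
    return("object_ids must be unique")
  TRUE
})

#' @describeIn SceneTruth the per-object truth table.
#' @param x a \code{SceneTruth}.
#' @export
truthObjects <- function(x) x@objects

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", nrow(object@objects), "object(s), seed",
      object@seed, "\n")
  invisible(NULL)
})

#' Labeled condensates for one image
#'
#' Result of thresholding and connected-component labeling of a (typically
#' background-corrected) channel: per-spot centroids, areas and per-channel
#' mean intensities, plus the label matrix that defines each spot mask.
#'
#' @slot imageId character image identifier.
#' @slot time numeric acquisition time (minutes; NA if unknown).
#' @slot spots data.frame with columns \code{spot_id}, \code{x}, \code{y},
#'   \code{area}, and one \code{mean_<channel>} column per measured channel.
#' @slot labels integer matrix, 0 = background, k > 0 = spot k.
#' @slot threshold numeric threshold applied.
#' @slot minArea numeric minimum spot area in px.
#' @export
setClass("CondensateSet",
  representation(imageId = "character", time = "numeric",
                 spots = "data.frame", labels = "matrix",
                 threshold = "numeric", minArea = "numeric"))

setValidity("CondensateSet", function(object) {
  df <- object@spots
  if (nrow(df) > 0L) {
    if (anyDuplicated(df$spot_id)) return("spot_ids must be unique")
    if (any(df$area < object@minArea)) return("all areas must be >= minArea")
  }
  TRUE
})

#' @describeIn CondensateSet number of condensates.
#' @param x a \code{CondensateSet}.
#' @export
nSpots <- function(x) nrow(x@spots)

#' @describeIn CondensateSet per-spot measurement table.
#' @export
spotTable <- function(x) x@spots

#' @describeIn CondensateSet the integer label matrix.
#' @export
spotLabels <- function(x) x@labels

setMethod("show", "CondensateSet", function(object) {
  cat("CondensateSet '", object@imageId, "': ", nrow(object@spots),
      " spot(s), threshold ", signif(object@threshold, 4),
      ", min area ", object@minArea, " px\n", sep = "")
  invisible(NULL)
})

#' A FRAP bleach-and-recovery trace
#'
#' Intensity time series for a bleached region of interest, with the
#' pre-bleach frames and the bleach frame recorded as anchors for
#' normalization. \code{normalized} and \code{mobileFraction} are filled by
#' [normalizeFrap()] and [mobileFraction()].
#'
#' @slot times numeric, acquisition times in seconds (bleach frame at 0).
#' @slot intensities numeric, raw ROI mean gray values.
#' @slot preBleachIndices integer indices of pre-bleach frames.
#' @slot bleachIndex integer index of the bleach frame.
#' @slot normalized numeric, normalized intensities (length 0 until
#'   normalization).
#' @slot mobileFraction numeric, estimated mobile fraction in [0, 1]
#'   (NA until estimated).
#' @export
setClass("FrapTrace",
  representation(times = "numeric", intensities = "numeric",
                 preBleachIndices = "integer", bleachIndex = "integer",
                 normalized = "numeric", mobileFraction = "numeric"),
  prototype(normalized = numeric(0), mobileFraction = NA_real_))

setValidity("FrapTrace", function(object) {
  if (length(object@times) != length(object@intensities))
    return("times and intensities must have equal length")
  if (length(object@preBleachIndices) < 1L)
    return("at least one pre-bleach frame is required")
  if (object@bleachIndex <= max(object@preBleachIndices))
    return("bleach frame must come after all pre-bleach frames")
  if (length(object@normalized) &&
      length(object@normalized) != length(object@times))
    return("normalized values must match trace length")
  TRUE
})

#' Construct a FrapTrace
#'
#' @param times acquisition times (s); the bleach frame should be at t = 0.
#' @param intensities raw ROI intensities (gray values).
#' @param preBleachIndices indices of pre-bleach frames.
#' @param bleachIndex index of the bleach frame.
#' @return a [FrapTrace-class] object.
#' @export
FrapTrace <- function(times, intensities, preBleachIndices, bleachIndex) {
  new("FrapTrace", times = as.numeric(times),
      intensities = as.numeric(intensities),
      preBleachIndices = as.integer(preBleachIndices),
      bleachIndex = as.integer(bleachIndex))
}

#' @describeIn FrapTrace acquisition times.
#' @param x a \code{FrapTrace}.
#' @export
frapTimes <- function(x) x@times

#' @describeIn FrapTrace raw intensities.
#' @export
frapIntensities <- function(x) x@intensities

#' @describeIn FrapTrace normalized intensities (errors if not yet
#'   normalized).
#' @export
frapNormalized <- function(x) {
  if (!length(x@normalized)) stop("trace has not been normalized yet")
  x@normalized
}

setMethod("show", "FrapTrace", function(object) {
  cat("FrapTrace:", length(object@times), "frames,",
      length(object@preBleachIndices), "pre-bleach;")
  if (length(object@normalized)) cat(" normalized;")
  if (!is.na(object@mobileFraction))
    cat(" mobile fraction", round(object@mobileFraction, 3))
  cat("\n")
  invisible(NULL)
})

#' Linear mixed model result for bead tables
#'
#' Fixed-effect condition contrasts with standard errors and p-values,
#' variance components for the replicate and well random intercepts and the
#' residual, group sizes and a singularity flag.
#'
#' @slot fixedEffects data.frame: term, estimate, se, df, statistic, p_value.
#' @slot varComp data.frame: group, sd, variance.
#' @slot groupSizes data.frame: condition, n_beads, n_wells, n_replicates.
#' @slot singular logical, TRUE if the fit was singular (a variance component
#'   on the boundary).
#' @slot pMethod character, p-value method used ("satterthwaite" or "wald").
#' @slot model the underlying lmerMod fit.
#' @export
setClass("MixedModelResult",
  representation(fixedEffects = "data.frame", varComp = "data.frame",
                 groupSizes = "data.frame", singular = "logical",
                 pMethod = "character", model = "ANY"))

setValidity("MixedModelResult", function(object) {
  if (any(object@varComp$variance < 0)) return("variance components must be >= 0")
  p <- object@fixedEffects$p_value
  if (any(p <= 0 | p > 1)) return("p-values must lie in (0, 1]")
  TRUE
})

#' @describeIn MixedModelResult fixed-effect contrast table.
#' @param x a \code{MixedModelResult}.
#' @export
fixedEffects <- function(x) x@fixedEffects

#' @describeIn MixedModelResult variance component table.
#' @export
varianceComponents <- function(x) x@varComp

#' @describeIn MixedModelResult TRUE for a singular fit.
#' @export
isSingularFit <- function(x) x@singular

setMethod("show", "MixedModelResult", function(object) {
  cat("Linear mixed model (REML), p-values:", object@pMethod,
      if (object@singular) "[singular fit]" else "", "\n")
  cat("Fixed effects:\n")
  print(object@fixedEffects, row.names = FALSE, digits = 4)
  cat("Variance components:\n")
  print(object@varComp, row.names = FALSE, digits = 4)
  invisible(NULL)
})
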