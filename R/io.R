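## Shared I/O (TIFF scenes, label masks, CSV tables), run configuration and
## the two end-to-end pipelines (bead assay; condensate assay).

#' Write an ImageScene as a multi-channel TIFF
#'
#' Channels are stored as TIFF pages in channel order, as 16-bit integer
#' gray values (0..65535, camera counts); non-integer intensities are
#' rounded and clipped to that range at write time, so the read/write round
#' trip is bit-exact for integer-valued scenes. Channel names and metadata
#' are recorded in a JSON sidecar (\code{<path>.json}).
#'
#' @param scene an [ImageScene-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeScene <- function(scene, path) {
  chans <- lapply(scene@channels, function(m)
    pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(chans, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(channels = channelNames(scene), meta = scene@meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF as an ImageScene
#'
#' Pages are mapped to channel names from the JSON sidecar written by
#' [writeScene()], or from \code{channels} when given (which must then match
#' the page count).
#'
#' @param path TIFF path.
#' @param channels optional channel names overriding the sidecar.
#' @return an [ImageScene-class] with integer gray values in 0..65535.
#' @export
readScene <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (is.null(channels) && file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channels <- info$channels
    meta <- as.list(info$meta)
  }
  if (is.null(channels))
    channels <- paste0("ch", seq_along(pages))
  if (length(channels) != length(pages))
    stop("channel map names ", length(channels), " channel(s) (",
         paste(channels, collapse = ", "), ") but file '", path, "' has ",
         length(pages), " page(s); missing channel(s): ",
         paste(channels[seq_along(channels) > length(pages)],
               collapse = ", "))
  names(pages) <- channels
  ImageScene(pages, meta = meta)
}

#' Write / read a label mask as 16-bit integer TIFF
#'
#' @param mask integer matrix (0 = background).
#' @param path TIFF path.
#' @return \code{path} (write) or the integer matrix (read).
#' @export
writeMask <- function(mask, path) {
  if (max(mask) > 65535L) stop("label values exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Read / write measurement tables as CSV
#'
#' Fixed dialect: comma-separated, UTF-8, header row, '.' decimal — chosen
#' so round trips are reproducible byte for byte across platforms.
#'
#' @param table data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or a data.frame (read).
#' @export
writeTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}

## ---- run configuration -------------------------------------------------

beadConfigKeys <- c("mode", "seed", "channel", "out", "wells",
                    "image_shape", "n_lines", "extension_frac", "step",
                    "min_radius", "detect_k", "min_area", "min_fill",
                    "noise_sd", "background", "bead_radius",
                    "rim_thickness", "beads_per_well", "core_intensity",
                    "rim_intensity")
condConfigKeys <- c("mode", "seed", "channel", "probe_channel", "out",
                    "image_shape", "n_spots", "time_points",
                    "coloc_fraction", "peak_intensity", "sigma",
                    "background", "noise_sd", "rolling_ball_radius",
                    "threshold_policy", "min_area", "coloc_k")

#' Build and validate a pipeline run configuration
#'
#' All stage parameters default to the package defaults; unknown keys are
#' rejected so that typos cannot silently fall back to defaults. The fully
#' resolved configuration is written next to every run's outputs.
#'
#' @param mode \code{"beads"} or \code{"condensates"}.
#' @param ... configuration keys overriding the defaults (see the vignette
#'   for the full key list).
#' @return a named list of class \code{RunConfig}.
#' @export
runConfig <- function(mode = c("beads", "condensates"), ...) {
  mode <- match.arg(mode)
  user <- list(...)
  defaults <- if (mode == "beads") {
    list(mode = mode, seed = 1L, channel = "EGFP", image_shape = c(220, 220),
         wells = list(list(well = "W1", replicate = "R1",
                           condition = "coated", rim = 100),
                      list(well = "W2", replicate = "R1",
                           condition = "empty", rim = 0),
                      list(well = "W1", replicate = "R2",
                           condition = "coated", rim = 100),
                      list(well = "W2", replicate = "R2",
                           condition = "empty", rim = 0)),
         n_lines = 8L, extension_frac = 0.2, step = 1, min_radius = 3,
         detect_k = 5, min_area = 100, min_fill = 0.6, noise_sd = 2,
         background = 10, bead_radius = 14, rim_thickness = 4,
         beads_per_well = 6L, core_intensity = 0, rim_intensity = 100)
  } else {
    list(mode = mode, seed = 1L, channel = "mCherry",
         probe_channel = "EGFP", image_shape = c(256, 256),
         n_spots = c(0L, 20L, 40L), time_points = c(0, 60, 120),
         coloc_fraction = 1, peak_intensity = 200, sigma = 1.5,
         background = 10, noise_sd = 2, rolling_ball_radius = 2,
         threshold_policy = "bg:5", min_area = 4, coloc_k = 3)
  }
  known <- if (mode == "beads") beadConfigKeys else condConfigKeys
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(user)] <- user                # plain replacement, no recursion
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with a \code{mode} key plus overrides.
#' @return a validated \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$mode)) stop("config must name a mode (beads|condensates)")
  do.call(runConfig, y)
}

## ---- pipelines ---------------------------------------------------------

#' Run an end-to-end pipeline from a configuration
#'
#' Bead mode: simulate one scene per configured well, detect beads, draw
#' and score radial profiles, apply the dispersion QC filter, and (with
#' >= 2 conditions) fit the mixed model; writes \code{beads.csv},
#' \code{beads_excluded.csv}, \code{stats.csv}. Condensate mode: simulate
#' the time series, rolling-ball correct, count per time point and score
#' colocalization at the final time point; writes \code{kinetics.csv} and
#' \code{coloc.csv}. Every run writes the resolved configuration
#' (\code{config.yaml}) and a log of parameters and exclusions
#' (\code{run.log}) next to its outputs; identical configurations reproduce
#' identical outputs.
#'
#' @param config a [runConfig()] (or path handled by [readRunConfig()]).
#' @param outDir output directory (created if needed).
#' @return \code{outDir}, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
  log <- c(paste0("mode: ", config$mode), paste0("seed: ", config$seed))
  if (config$mode == "beads") {
    if (is.null(config$wells) || !length(config$wells))
      stop("bead config has no wells to process")
    rows <- list()
    for (i in seq_along(config$wells)) {
      w <- config$wells[[i]]
      spec <- beadWellSpec(config, w, seedOffset = i)
      sim <- simulateBeadScene(spec)
      meas <- quantifyBeads(sim$scene, config$channel,
                            wellId = w$well, replicateId = w$replicate,
                            condition = w$condition,
                            nLines = config$n_lines,
                            extensionFrac = config$extension_frac,
                            step = config$step,
                            minRadius = config$min_radius,
                            detectParams = list(k = config$detect_k,
                                                minArea = config$min_area,
                                                minFill = config$min_fill))
      log <- c(log, sprintf("well %s/%s: %d beads detected",
                            w$replicate, w$well, nrow(meas)))
      rows[[i]] <- meas
    }
    all <- do.call(rbind, rows)
    all$bead_id <- seq_len(nrow(all))
    qc <- qcFilter(all)
    writeTable(qc$retained, file.path(outDir, "beads.csv"))
    writeTable(qc$excluded, file.path(outDir, "beads_excluded.csv"))
    log <- c(log, sprintf("QC: %d retained, %d excluded",
                          nrow(qc$retained), nrow(qc$excluded)))
    if (length(unique(qc$retained$condition)) >= 2L &&
        all(table(qc$retained$condition) >= 2L)) {
      mm <- fitBeadMixedModel(qc$retained)
      writeTable(fixedEffects(mm), file.path(outDir, "stats.csv"))
      log <- c(log, sprintf("mixed model: %s p-values%s", mm@pMethod,
                            if (isSingularFit(mm)) " (singular fit)" else ""))
    }
  } else {
    spec <- condensateSceneSpec(
      imageShape = config$image_shape, nSpots = config$n_spots,
      timePoints = config$time_points, refChannel = config$channel,
      probeChannel = config$probe_channel,
      peakIntensity = stats::setNames(rep(config$peak_intensity, 2),
                                      c(config$channel,
                                        config$probe_channel)),
      sigma = stats::setNames(rep(config$sigma, 2),
                              c(config$channel, config$probe_channel)),
      colocFraction = config$coloc_fraction,
      backgroundLevel = stats::setNames(rep(config$background, 2),
                                        c(config$channel,
                                          config$probe_channel)),
      noiseSd = config$noise_sd, seed = config$seed)
    sim <- simulateCondensateSeries(spec)
    kin <- condensateKinetics(sim$scenes, config$channel,
                              thresholdPolicy = config$threshold_policy,
                              minArea = config$min_area,
                              rollingBallRadius = config$rolling_ball_radius)
    writeTable(kin, file.path(outDir, "kinetics.csv"))
    last <- sim$scenes[[length(sim$scenes)]]
    ref <- countCondensates(
      rollingBallSubtract(getChannel(last, config$channel),
                          config$rolling_ball_radius),
      thresholdPolicy = config$threshold_policy,
      minArea = config$min_area, time = sceneMeta(last)$time)
    cl <- colocalizationFraction(ref,
                                 getChannel(last, config$probe_channel),
                                 k = config$coloc_k)
    writeTable(data.frame(n_ref = cl$nRef, n_positive = cl$nPositive,
                          fraction = cl$fraction, k = cl$k),
               file.path(outDir, "coloc.csv"))
    log <- c(log, sprintf("kinetics: %d time points; coloc %d/%d",
                          nrow(kin), cl$nPositive, cl$nRef))
  }
  writeLines(log, file.path(outDir, "run.log"))
  invisible(outDir)
}

## place beads_per_well beads on a grid with jitter-free spacing
beadWellSpec <- function(config, w, seedOffset) {
  n <- config$beads_per_well
  r <- config$bead_radius
  shape <- config$image_shape
  perRow <- ceiling(sqrt(n))
  pitch <- floor(min(shape - 2 * (r + 8)) / max(perRow - 1, 1))
  pitch <- max(pitch, 2 * r + 10)
  idx <- seq_len(n) - 1L
  beadSceneSpec(
    imageShape = shape,
    beads = data.frame(
      x = r + 8 + (idx %% perRow) * pitch,
      y = r + 8 + (idx %/% perRow) * pitch,
      radius = r, rim_thickness = config$rim_thickness),
    rimIntensity = w$rim, coreIntensity = config$core_intensity,
    backgroundLevel = stats::setNames(config$background, config$channel),
    noiseSd = config$noise_sd, seed = config$seed + seedOffset)
}
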