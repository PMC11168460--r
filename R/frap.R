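## FRAP trace normalization and mobile-fraction estimation.

#' Normalize a FRAP trace to its pre-bleach and bleach anchors
#'
#' Double normalization against the trace's own anchors:
#' \deqn{N(t) = (I(t) - I_{bleach}) / (I_{pre} - I_{bleach})}
#' with \eqn{I_{pre}} the mean over the pre-bleach frames. The pre-bleach
#' mean maps to 1 and the bleach frame to 0, so the normalized curve reads
#' directly as the recovered fraction of the bleached signal.
#'
#' @param trace a [FrapTrace-class].
#' @return the trace with its \code{normalized} slot filled.
#' @examples
#' tr <- generateFrapTrace(frapSpec(mobileFraction = 0.4, noiseSd = 0))
#' tail(frapNormalized(normalizeFrap(tr)), 1)
#' @export
normalizeFrap <- function(trace) {
  stopifnot(is(trace, "FrapTrace"))
  iPre <- mean(trace@intensities[trace@preBleachIndices])
  iBleach <- trace@intensities[trace@bleachIndex]
  if (iPre == iBleach)
    stop("degenerate trace: pre-bleach level equals bleach level")
  trace@normalized <- (trace@intensities - iBleach) / (iPre - iBleach)
  trace
}

#' Estimate the mobile fraction from a normalized trace
#'
#' The recovery plateau is estimated as the mean of the last
#' \code{tailFrames} normalized values and clamped to [0, 1]. The tail mean
#' is assumption-light and matches the assay's qualitative mobile/immobile
#' readout; for a model-based estimate see [fitFrapRecovery()].
#'
#' @param trace a normalized [FrapTrace-class].
#' @param tailFrames number of final frames to average (default 5).
#' @return the estimated mobile fraction (numeric in [0, 1]); also stored in
#'   the trace returned as attribute \code{"trace"}.
#' @export
mobileFraction <- function(trace, tailFrames = 5L) {
  stopifnot(is(trace, "FrapTrace"))
  if (!length(trace@normalized))
    stop("normalize the trace first (see normalizeFrap)")
  nPost <- length(trace@times) - trace@bleachIndex
  if (tailFrames < 1L || tailFrames > nPost)
    stop("tailFrames must be between 1 and the number of post-bleach frames (",
         nPost, ")")
  n <- length(trace@normalized)
  est <- mean(trace@normalized[(n - tailFrames + 1L):n])
  est <- min(max(est, 0), 1)
  trace@mobileFraction <- est
  structure(est, trace = trace)
}

#' Fit a single-exponential recovery model to a normalized trace
#'
#' Secondary, model-based estimator: fits
#' \eqn{N(t) = m (1 - e^{-kt})} to the post-bleach part of the normalized
#' trace by Levenberg-Marquardt least squares.
#'
#' @param trace a normalized [FrapTrace-class].
#' @return list with \code{mobileFraction}, \code{rate}, and the
#'   \code{fit} object.
#' @export
fitFrapRecovery <- function(trace) {
  stopifnot(is(trace, "FrapTrace"))
  if (!length(trace@normalized))
    stop("normalize the trace first (see normalizeFrap)")
  post <- trace@bleachIndex:length(trace@times)
  df <- data.frame(t = trace@times[post], y = trace@normalized[post])
  mStart <- min(max(mean(utils::tail(df$y, 3)), 0.05), 1)
  fit <- minpack.lm::nlsLM(y ~ m * (1 - exp(-k * t)), data = df,
                           start = list(m = mStart, k = 0.2),
                           lower = c(0, 0), upper = c(1.5, Inf))
  co <- stats::coef(fit)
  list(mobileFraction = min(max(unname(co["m"]), 0), 1),
       rate = unname(co["k"]), fit = fit)
}
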