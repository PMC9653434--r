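# Constructors, accessors and show methods.

#' Create a parameter set for the bulb circuit model
#'
#' @param I odor input to the MC/TC population (rate units).
#' @param wMcGc reciprocal MC/TC-GC coupling strength.
#' @param wSacGc dSAC-to-GC inhibition strength.
#' @param wFbMc cortical feedback strength onto MC/TC (onto GC it is
#'   \code{2 * wFbMc}).
#' @param feedbackOn whether feedback stimulation is active.
#' @return A [NetworkParams-class] object.
#' @examples
#' p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
#' solveFixedPoint(p)
#' @export
networkParams <- function(I = 10, wMcGc = 0.3, wSacGc = 1, wFbMc = 0,
                          feedbackOn = FALSE) {
  new("NetworkParams", I = as.numeric(I), wMcGc = as.numeric(wMcGc),
      wSacGc = as.numeric(wSacGc), wFbMc = as.numeric(wFbMc),
      feedbackOn = isTRUE(feedbackOn))
}

#' dSAC drive under shunting by cortical feedback
#'
#' The dSAC input onto GCs is 1 without feedback and \code{0.1 / wFbMc}
#' with feedback: stronger feedback shunts more of the dSAC inhibition.
#'
#' @param params a [NetworkParams-class].
#' @return scalar dSAC drive.
#' @export
sacDrive <- function(params) {
  stopifnot(is(params, "NetworkParams"))
  if (params@feedbackOn) 0.1 / params@wFbMc else 1
}

#' @describeIn networkParams indicator FB: 1 when feedback is on, 0 otherwise.
#' @param params a [NetworkParams-class].
#' @export
feedbackIndicator <- function(params) {
  stopifnot(is(params, "NetworkParams"))
  as.numeric(params@feedbackOn)
}

setMethod("show", "NetworkParams", function(object) {
  cat("NetworkParams: I =", object@I,
      " wMcGc =", object@wMcGc,
      " wSacGc =", object@wSacGc,
      " wFbMc =", object@wFbMc,
      " feedback", if (object@feedbackOn) "ON" else "off",
      " (SAC drive =", format(sacDrive(object), digits = 4), ")\n")
})

#' @describeIn solveFixedPoint MC/TC rate of a fixed point.
#' @export
mcRate <- function(fp) { stopifnot(is(fp, "FixedPoint")); fp@mc }

#' @describeIn solveFixedPoint GC rate of a fixed point.
#' @export
gcRate <- function(fp) { stopifnot(is(fp, "FixedPoint")); fp@gc }

#' @describeIn solveFixedPoint whether the GC >= 0 constraint is active.
#' @export
isRectified <- function(fp) { stopifnot(is(fp, "FixedPoint")); fp@rectified }

setMethod("show", "FixedPoint", function(object) {
  cat(sprintf("FixedPoint: MC = %.6g, GC = %.6g%s\n", object@mc, object@gc,
              if (object@rectified) " (GC rectified)" else ""))
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult:", length(object@wMcGcAxis), "coupling x",
      length(object@wFbAxis), "feedback strengths\n")
  cat("  delta MC range:",
      paste(format(range(object@deltaMc), digits = 4), collapse = " .. "),
      "\n  delta GC range:",
      paste(format(range(object@deltaGc), digits = 4), collapse = " .. "),
      "\n")
})

# ---- imaging -------------------------------------------------------------

#' Construct a calcium movie
#'
#' @param frames numeric array, time x height x width.
#' @param frameRate frames per second.
#' @param keptFrames optional logical per-frame QC mask (default all kept).
#' @param pixelSize micrometres per pixel (optional metadata).
#' @return A [CalciumMovie-class].
#' @export
calciumMovie <- function(frames, frameRate = 15,
                         keptFrames = rep(TRUE, dim(frames)[1]),
                         pixelSize = NA_real_) {
  new("CalciumMovie", frames = frames, frameRate = as.numeric(frameRate),
      keptFrames = keptFrames, pixelSize = as.numeric(pixelSize))
}

#' @describeIn calciumMovie number of frames.
#' @param movie a [CalciumMovie-class].
#' @export
nFrames <- function(movie) dim(movie@frames)[1]

#' @describeIn calciumMovie per-frame QC mask.
#' @export
keptFrames <- function(movie) movie@keptFrames

#' @describeIn calciumMovie frame array accessor.
#' @export
movieFrames <- function(movie) movie@frames

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CalciumMovie: %d frames of %d x %d px at %g Hz (%d kept)\n",
              d[1], d[2], d[3], object@frameRate, sum(object@keptFrames)))
})

setMethod("dim", "CalciumMovie", function(x) dim(x@frames))

#' Construct an ROI set from a labeled mask
#'
#' @param masks integer matrix, 0 background, k = ROI k (contiguous 1..K).
#' @param provenance per-ROI provenance, "manual" (default) or "refined".
#' @return A [RoiSet-class].
#' @export
roiSet <- function(masks, provenance = NULL) {
  storage.mode(masks) <- "integer"
  k <- max(masks)
  if (is.null(provenance)) provenance <- rep("manual", k)
  new("RoiSet", masks = masks, provenance = provenance)
}

#' @describeIn roiSet number of ROIs.
#' @param rois a [RoiSet-class].
#' @export
nRois <- function(rois) max(rois@masks)

#' @describeIn roiSet labeled mask accessor.
#' @export
roiMasks <- function(rois) rois@masks

#' @describeIn roiSet per-ROI provenance accessor.
#' @export
roiProvenance <- function(rois) rois@provenance

setMethod("show", "RoiSet", function(object) {
  k <- max(object@masks)
  cat(sprintf("RoiSet: %d ROIs (%d refined) on a %d x %d mask\n", k,
              sum(object@provenance == "refined"),
              nrow(object@masks), ncol(object@masks)))
})

#' Construct a trace set
#'
#' @param traces numeric matrix, cells x time.
#' @param frameRate sampling rate in Hz.
#' @return A [TraceSet-class].
#' @export
traceSet <- function(traces, frameRate) {
  new("TraceSet", traces = as.matrix(traces), frameRate = frameRate)
}

#' @describeIn traceSet trace matrix accessor (cells x time).
#' @param x a [TraceSet-class].
#' @export
traceMatrix <- function(x) x@traces

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet: %d cells x %d samples at %g Hz\n",
              nrow(object@traces), ncol(object@traces), object@frameRate))
})

#' Construct a trial table
#'
#' @param trials data.frame with columns \code{onset_s}, \code{stimulus},
#'   \code{block}; window anchors \code{shutter_close_s} /
#'   \code{shutter_open_s} default to stimulus onset/onset (i.e. baseline
#'   ends and response starts at onset) when absent.
#' @param stimDuration_s used to fill a missing \code{shutter_open_s} as
#'   onset + duration.
#' @return A [TrialTable-class].
#' @export
trialTable <- function(trials, stimDuration_s = 2) {
  if (is.null(trials$shutter_close_s)) trials$shutter_close_s <- trials$onset_s
  if (is.null(trials$shutter_open_s))
    trials$shutter_open_s <- trials$onset_s + stimDuration_s
  new("TrialTable", trials = trials)
}

#' @describeIn trialTable the underlying data.frame.
#' @param x a [TrialTable-class].
#' @export
trials <- function(x) x@trials

#' @describeIn trialTable number of trials.
#' @export
nTrials <- function(x) nrow(x@trials)

setMethod("show", "TrialTable", function(object) {
  df <- object@trials
  cat(sprintf("TrialTable: %d trials, %d blocks; stimuli: %s\n", nrow(df),
              length(unique(df$block)),
              paste(unique(df$stimulus), collapse = ", ")))
})

setMethod("show", "ResponseStat", function(object) {
  cat(sprintf(
    "ResponseStat: z = %.4g (mu_resp %.4g, mu_base %.4g, n = %d)%s%s\n",
    object@z, object@muResp, object@muBaseline, object@n,
    if (!is.na(object@pValue)) sprintf(", p = %.3g", object@pValue) else "",
    if (nzchar(object@label)) paste0(", ", object@label) else ""))
})

# ---- photometry ----------------------------------------------------------

#' Construct a photometry session
#'
#' @param fluorescence fluorescence channel (numeric vector).
#' @param reflection reflected-excitation channel (same length, or NULL).
#' @param rate sampling rate in Hz.
#' @param trials a [TrialTable-class].
#' @return A [PhotometrySession-class].
#' @export
photometrySession <- function(fluorescence, reflection = NULL, rate, trials) {
  new("PhotometrySession", fluorescence = as.numeric(fluorescence),
      reflection = if (is.null(reflection)) numeric(0)
                   else as.numeric(reflection),
      rate = as.numeric(rate), trials = trials)
}

setMethod("show", "PhotometrySession", function(object) {
  cat(sprintf(
    "PhotometrySession: %.1f s at %g Hz (%s reflection channel), %d trials\n",
    length(object@fluorescence) / object@rate, object@rate,
    if (length(object@reflection)) "with" else "no",
    nrow(object@trials@trials)))
})

setMethod("show", "TrialMatrix", function(object) {
  cat(sprintf("TrialMatrix: %d trials x %d samples at %g Hz, conditions: %s\n",
              nrow(object@dff), ncol(object@dff), object@rate,
              paste(unique(object@condition), collapse = ", ")))
})

#' @describeIn trialDff per-trial dF/F matrix accessor.
#' @param tm a [TrialMatrix-class].
#' @export
dffMatrix <- function(tm) tm@dff

#' @describeIn trialDff per-trial condition labels.
#' @export
trialConditions <- function(tm) tm@condition

setMethod("show", "SubtractionFit", function(object) {
  cat(sprintf(
    paste0("SubtractionFit (n = %d): slope %.3f [%.3f, %.3f], ",
           "intercept %.3f [%.3f, %.3f]\n",
           "  light-effect vs odor-response correlation r = %.3f (p = %.3g)\n"),
    object@n, object@slope, object@slopeCI[1], object@slopeCI[2],
    object@intercept, object@interceptCI[1], object@interceptCI[2],
    object@diffCor, object@diffCorP))
})
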