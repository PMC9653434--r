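#' @import methods
NULL

# ---------------------------------------------------------------------------
# Circuit model classes
# ---------------------------------------------------------------------------

#' Parameters of the two-population olfactory-bulb rate model
#'
#' Holds the parameters of the mitral/tufted-cell (MC/TC) and granule-cell
#' (GC) firing-rate circuit: the odor drive onto MC/TC, the reciprocal
#' MC/TC-GC coupling, the deep short-axon cell (dSAC) inhibition of GCs, and
#' the strength of the long-range cortical GABAergic feedback. The feedback
#' inhibits MC/TC with weight \code{wFbMc} and GCs with weight
#' \code{2 * wFbMc} (the feedback is about twice as strong on GCs); it also
#' shunts the dSAC drive onto GCs, modeled as a dSAC drive of
#' \code{0.1 / wFbMc} when feedback is on and 1 otherwise.
#'
#' @slot I nonnegative odor input (rate units) to the MC/TC population.
#' @slot wMcGc nonnegative reciprocal MC/TC-GC coupling strength.
#' @slot wSacGc nonnegative dSAC-to-GC inhibition strength.
#' @slot wFbMc nonnegative feedback-to-MC/TC strength (feedback onto GC is
#'   always twice this, never an independent parameter).
#' @slot feedbackOn logical; whether cortical feedback stimulation is active.
#'
#' @seealso [networkParams()], [solveFixedPoint()], [sacDrive()]
#' @export
setClass("NetworkParams",
  representation(
    I = "numeric",
    wMcGc = "numeric",
    wSacGc = "numeric",
    wFbMc = "numeric",
    feedbackOn = "logical"
  )
)

setValidity("NetworkParams", function(object) {
  v <- c(I = object@I, wMcGc = object@wMcGc, wSacGc = object@wSacGc,
         wFbMc = object@wFbMc)
  if (length(object@I) != 1L || length(object@wMcGc) != 1L ||
      length(object@wSacGc) != 1L || length(object@wFbMc) != 1L ||
      length(object@feedbackOn) != 1L)
    return("all parameters must be scalars")
  if (any(!is.finite(v)))
    return("non-finite parameter")
  if (any(v < 0))
    return("all weights and the odor input must be >= 0")
  if (object@feedbackOn && object@wFbMc <= 0)
    return("feedbackOn requires wFbMc > 0 (dSAC drive 0.1/wFbMc undefined)")
  TRUE
})

#' Fixed point of the rate model
#'
#' The steady state (MC/TC, GC) of the circuit. When the unconstrained GC
#' solution is negative the GC rate is rectified to 0 and
#' \code{rectified} is \code{TRUE}.
#'
#' @slot mc MC/TC steady-state rate.
#' @slot gc GC steady-state rate (always >= 0).
#' @slot rectified logical; whether the GC >= 0 constraint is active.
#' @slot converged logical; whether the solution satisfies both nullclines.
#' @export
setClass("FixedPoint",
  representation(mc = "numeric", gc = "numeric", rectified = "logical",
                 converged = "logical")
)

setValidity("FixedPoint", function(object) {
  if (object@gc < -1e-12) return("gc must be >= 0 after rectification")
  TRUE
})

#' Parameter-grid sweep of feedback-induced rate changes
#'
#' Fixed-point rates without feedback (baseline) and the change upon
#' feedback stimulation, over a grid of MC/TC-GC coupling strengths
#' (rows) by feedback strengths (columns).
#'
#' @slot wMcGcAxis ordered grid of coupling strengths (rows).
#' @slot wFbAxis ordered grid of feedback strengths (columns).
#' @slot baselineMc,baselineGc matrices of no-feedback fixed-point rates
#'   (constant along the feedback axis).
#' @slot deltaMc,deltaGc matrices of (with-feedback minus without) rates.
#' @export
setClass("SweepResult",
  representation(wMcGcAxis = "numeric", wFbAxis = "numeric",
                 baselineMc = "matrix", baselineGc = "matrix",
                 deltaMc = "matrix", deltaGc = "matrix")
)

setValidity("SweepResult", function(object) {
  dm <- c(length(object@wMcGcAxis), length(object@wFbAxis))
  for (s in c("baselineMc", "baselineGc", "deltaMc", "deltaGc"))
    if (!identical(dim(slot(object, s)), as.integer(dm)))
      return(sprintf("%s must be a %d x %d matrix", s, dm[1], dm[2]))
  if (is.unsorted(object@wMcGcAxis, strictly = TRUE) ||
      is.unsorted(object@wFbAxis, strictly = TRUE))
    return("axes must be strictly increasing")
  TRUE
})

# ---------------------------------------------------------------------------
# Imaging classes
# ---------------------------------------------------------------------------

#' A trial-structured calcium-imaging movie
#'
#' A grayscale image stack (time x height x width) with per-frame
#' quality-control flags. Frames flagged not-kept (e.g. out-of-plane
#' z-movements, excessive motion) stay in the stack but are excluded from
#' reference images and decompositions.
#'
#' @slot frames numeric array, time x height x width, finite intensities.
#' @slot frameRate acquisition rate in Hz.
#' @slot keptFrames logical vector, one flag per frame.
#' @slot pixelSize micrometres per pixel (NA if unknown).
#' @export
setClass("CalciumMovie",
  representation(frames = "array", frameRate = "numeric",
                 keptFrames = "logical", pixelSize = "numeric")
)

setValidity("CalciumMovie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-D array (time x h x w)")
  if (length(object@keptFrames) != d[1])
    return("keptFrames length must equal the frame count")
  if (anyNA(object@frames) || any(!is.finite(object@frames)))
    return("intensities must be finite")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    return("frameRate must be a positive scalar (Hz)")
  TRUE
})

#' A set of labeled regions of interest
#'
#' A labeled mask image (0 = background, k = ROI k) over the movie's field
#' of view, with per-ROI provenance: \code{"manual"} for hand-drawn masks,
#' \code{"refined"} after within-ROI PCA boundary refinement.
#'
#' @slot masks integer matrix of labels; labels are contiguous 1..K.
#' @slot provenance character vector of length K, "manual" or "refined".
#' @export
setClass("RoiSet",
  representation(masks = "matrix", provenance = "character")
)

setValidity("RoiSet", function(object) {
  lab <- sort(unique(as.integer(object@masks[object@masks > 0])))
  k <- length(lab)
  if (k == 0L) return("RoiSet must contain at least one ROI")
  if (!identical(lab, seq_len(k)))
    return("ROI labels must be contiguous positive integers 1..K")
  if (length(object@provenance) != k)
    return("provenance must have one entry per ROI")
  if (!all(object@provenance %in% c("manual", "refined")))
    return("provenance entries must be 'manual' or 'refined'")
  TRUE
})

#' Per-cell fluorescence traces aligned to a movie
#'
#' @slot traces numeric matrix, cells x time.
#' @slot frameRate sampling rate in Hz.
#' @export
setClass("TraceSet",
  representation(traces = "matrix", frameRate = "numeric")
)

setValidity("TraceSet", function(object) {
  if (!is.numeric(object@traces)) return("traces must be numeric")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a positive scalar")
  TRUE
})

#' A trial/stimulus schedule
#'
#' One row per trial with stimulus onset (s), stimulus label, block index,
#' and the analysis window anchors: \code{shutter_close_s} (baseline window
#' is the 1 s before it) and \code{shutter_open_s} (response window is the
#' 1 s after it). For trials without a photomultiplier shutter the anchors
#' default to stimulus onset and offset. Photometry schedules additionally
#' carry \code{light_on_s} (in-trial light onset, NA when no light).
#'
#' @slot trials data.frame with at least columns \code{onset_s},
#'   \code{stimulus}, \code{block}, \code{shutter_close_s},
#'   \code{shutter_open_s}.
#' @export
setClass("TrialTable", representation(trials = "data.frame"))

setValidity("TrialTable", function(object) {
  df <- object@trials
  need <- c("onset_s", "stimulus", "block", "shutter_close_s",
            "shutter_open_s")
  if (!all(need %in% names(df)))
    return(paste("trials must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return("empty trial table")
  if (is.unsorted(df$onset_s, strictly = TRUE))
    return("trial onsets must be strictly increasing")
  TRUE
})

#' Per cell-stimulus response statistics
#'
#' The z statistic comparing response- and baseline-window trial means,
#' z = (mu_resp - mu_base) / sqrt(sd_resp^2/n - sd_base^2/n) with sample
#' standard deviations, the windows' means/SDs, the paired-test p-value and
#' the response label. When the radicand of z is non-positive the statistic
#' is undefined (NaN) and \code{zFallback}, the conventional pooled form
#' with a plus sign, is reported alongside.
#'
#' @slot z the response z statistic (NaN when the radicand is <= 0).
#' @slot zFallback same statistic with + in the radicand (always defined
#'   for non-identical windows).
#' @slot muResp,muBaseline window means across trials.
#' @slot sigmaResp,sigmaBaseline across-trial sample standard deviations.
#' @slot n number of trials.
#' @slot pValue two-sided paired t-test p-value (NA until classified).
#' @slot label "excited", "inhibited", "nonresponsive", or "" (unclassified).
#' @export
setClass("ResponseStat",
  representation(z = "numeric", zFallback = "numeric",
                 muResp = "numeric", muBaseline = "numeric",
                 sigmaResp = "numeric", sigmaBaseline = "numeric",
                 n = "integer", pValue = "numeric", label = "character")
)

setValidity("ResponseStat", function(object) {
  if (object@n < 2L) return("need n >= 2 trials")
  TRUE
})

# ---------------------------------------------------------------------------
# Photometry classes
# ---------------------------------------------------------------------------

#' A fiber-photometry recording session
#'
#' Two co-recorded channels at the acquisition rate: bulk GCaMP
#' fluorescence and the reflected excitation light (used for quality
#' control, not correction), plus the session's trial schedule.
#'
#' @slot fluorescence numeric vector, the fluorescence channel.
#' @slot reflection numeric vector, the reflected-excitation channel
#'   (length 0 if not recorded).
#' @slot rate sampling rate in Hz.
#' @slot trials a [TrialTable-class].
#' @export
setClass("PhotometrySession",
  representation(fluorescence = "numeric", reflection = "numeric",
                 rate = "numeric", trials = "TrialTable")
)

setValidity("PhotometrySession", function(object) {
  if (length(object@reflection) &&
      length(object@reflection) != length(object@fluorescence))
    return("fluorescence and reflection must have the same length")
  if (object@rate <= 0) return("rate must be positive")
  tr <- object@trials@trials
  span <- length(object@fluorescence) / object@rate
  if (any(tr$onset_s < 0) || any(tr$onset_s > span))
    return("trial onsets must lie within the recording span")
  TRUE
})

#' Trial-aligned delta-F-over-F matrix
#'
#' One row per trial, aligned to trial onset, normalized to the trial's
#' baseline fluorescence F0 (mean over the 2 s preceding onset by default).
#'
#' @slot dff numeric matrix, trials x aligned samples.
#' @slot time numeric vector of sample times relative to onset (s).
#' @slot condition character vector of per-trial condition labels.
#' @slot lightOn numeric vector of per-trial light onsets relative to trial
#'   onset (NA for no-light trials).
#' @slot rate sampling rate of the aligned rows (Hz).
#' @export
setClass("TrialMatrix",
  representation(dff = "matrix", time = "numeric", condition = "character",
                 lightOn = "numeric", rate = "numeric")
)

setValidity("TrialMatrix", function(object) {
  if (ncol(object@dff) != length(object@time))
    return("time axis must match the aligned length")
  if (nrow(object@dff) != length(object@condition) ||
      nrow(object@dff) != length(object@lightOn))
    return("condition and lightOn must have one entry per trial")
  TRUE
})

# ---------------------------------------------------------------------------
# Population statistics classes
# ---------------------------------------------------------------------------

#' Linear-subtraction characterization of light effects on odor responses
#'
#' Ordinary least-squares fit of the odor+light response against the
#' odor-only response over responsive cell-odor pairs, with 95% confidence
#' intervals, plus the correlation between the light effect
#' (odor+light minus odor) and the odor-response magnitude. A slope of 1
#' with a negative intercept and no difference-response correlation is the
#' signature of a subtractive (rather than divisive) light effect.
#'
#' @slot slope,intercept OLS coefficients.
#' @slot slopeCI,interceptCI 95% confidence intervals (length-2).
#' @slot diffCor Pearson correlation of (odor+light - odor) vs odor.
#' @slot diffCorP p-value of that correlation.
#' @slot n number of cell-odor pairs.
#' @export
setClass("SubtractionFit",
  representation(slope = "numeric", intercept = "numeric",
                 slopeCI = "numeric", interceptCI = "numeric",
                 diffCor = "numeric", diffCorP = "numeric", n = "integer")
)
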