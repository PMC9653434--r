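# Trace extraction, smoothing, window statistics, z-scores and response
# classification.

# Centered moving average with shrinking windows at the edges.
.movingAverage <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract per-ROI fluorescence traces
#'
#' Each trace sample is the mean intensity over the ROI's pixels in that
#' frame. Not-kept frames are filled by linear interpolation between the
#' neighboring kept frames (constant extrapolation at the ends), so trial
#' windows keep a fixed sample count.
#'
#' @param movie a [CalciumMovie-class].
#' @param rois a [RoiSet-class] over the movie's field of view.
#' @return A [TraceSet-class], one row per ROI label.
#' @export
extractTraces <- function(movie, rois) {
  stopifnot(is(movie, "CalciumMovie"), is(rois, "RoiSet"))
  n <- nFrames(movie)
  k <- nRois(rois)
  flat <- matrix(movie@frames, nrow = n)   # time x pixels, column-major
  out <- matrix(NA_real_, k, n)
  kept <- which(movie@keptFrames)
  for (j in seq_len(k)) {
    idx <- which(rois@masks == j)
    if (!length(idx)) stop(sprintf("ROI %d has an empty mask", j))
    tr <- rowMeans(flat[, idx, drop = FALSE])
    if (length(kept) < n) {
      if (!length(kept)) stop("no kept frames to interpolate from")
      tr <- stats::approx(kept, tr[kept], xout = seq_len(n), rule = 2)$y
      message(sprintf("ROI %d: %d not-kept frame(s) linearly interpolated",
                      j, n - length(kept)))
    }
    out[j, ] <- tr
  }
  rownames(out) <- paste0("roi", seq_len(k))
  traceSet(out, movie@frameRate)
}

#' Smooth traces with a centered moving average
#'
#' @param traces a [TraceSet-class].
#' @param window odd window length in frames (default 5). Edges use
#'   shrinking windows; \code{window = 1} is the identity.
#' @return The smoothed [TraceSet-class].
#' @export
smoothTraces <- function(traces, window = 5) {
  stopifnot(is(traces, "TraceSet"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > ncol(traces@traces))
    stop("invalid parameter: window exceeds trace length")
  traces@traces <- t(apply(traces@traces, 1, .movingAverage,
                           window = as.integer(window)))
  traces
}

#' Delta-F-over-F normalization
#'
#' (F - F0) / F0 with F0 the mean over the baseline window.
#'
#' @param trace numeric time series.
#' @param f0Window integer indices of the baseline window within the trace.
#' @return numeric dF/F series of the same length.
#' @export
computeDff <- function(trace, f0Window) {
  if (any(f0Window < 1) || any(f0Window > length(trace)))
    stop("f0Window must lie inside the trace")
  f0 <- mean(trace[f0Window])
  if (!is.finite(f0) || f0 <= 0)
    stop(sprintf("baseline error: F0 = %g is not positive (pathological trace)", f0))
  (trace - f0) / f0
}

#' Per-trial baseline and response window means
#'
#' For every cell and trial, averages the trace over the 1-s baseline
#' window ending at \code{shutter_close_s} and the 1-s response window
#' starting at \code{shutter_open_s} (50 ms after light offset when a
#' shutter was used; stimulus onset/offset otherwise). Windows are
#' half-open \code{[start, start + width)}; frame i covers time
#' \code{(i - 0.5) / rate}.
#'
#' @param traces a [TraceSet-class].
#' @param trialTable a [TrialTable-class].
#' @param width window width in seconds (default 1).
#' @return list with matrices \code{base} and \code{resp}
#'   (cells x trials) and the trial data.frame \code{trials}.
#' @export
trialWindowMeans <- function(traces, trialTable, width = 1) {
  stopifnot(is(traces, "TraceSet"), is(trialTable, "TrialTable"))
  df <- trialTable@trials
  rate <- traces@frameRate
  nT <- ncol(traces@traces)
  tcenters <- (seq_len(nT) - 0.5) / rate
  winIdx <- function(start) {
    idx <- which(tcenters >= start & tcenters < start + width)
    if (!length(idx))
      stop(sprintf("window [%g, %g) contains no frames", start, start + width))
    idx
  }
  nTr <- nrow(df)
  k <- nrow(traces@traces)
  base <- resp <- matrix(NA_real_, k, nTr)
  for (i in seq_len(nTr)) {
    bi <- winIdx(df$shutter_close_s[i] - width)
    ri <- winIdx(df$shutter_open_s[i])
    base[, i] <- rowMeans(traces@traces[, bi, drop = FALSE])
    resp[, i] <- rowMeans(traces@traces[, ri, drop = FALSE])
  }
  list(base = base, resp = resp, trials = df)
}

#' Response z-score from paired per-trial window means
#'
#' Computes z = (mu_resp - mu_base) / sqrt(sd_resp^2/n - sd_base^2/n) with
#' sample (n-1 denominator) standard deviations, exactly in this form. The
#' statistic is affine-invariant: scaling both windows by c > 0 and adding
#' a common constant leaves z unchanged. When the numerator is 0 the score
#' is 0 by convention; when the radicand is non-positive (baseline more
#' variable than the response) z is undefined (NaN) and the conventional
#' pooled form with a plus sign is available as \code{zFallback}.
#'
#' @param respMeans per-trial response-window means.
#' @param baseMeans per-trial baseline-window means (paired, same length).
#' @return A [ResponseStat-class] (p-value and label unset; see
#'   [classifyResponse()]).
#' @examples
#' computeZScore(c(2, 3, 2, 3), c(1, 1, 1, 1))   # z = 5.196
#' @export
computeZScore <- function(respMeans, baseMeans) {
  if (length(respMeans) != length(baseMeans))
    stop("pairing error: respMeans and baseMeans differ in length")
  n <- length(respMeans)
  if (n < 2L) stop("need at least 2 trials")
  mr <- mean(respMeans); mb <- mean(baseMeans)
  sr <- stats::sd(respMeans); sb <- stats::sd(baseMeans)
  num <- mr - mb
  radicand <- sr^2 / n - sb^2 / n
  zplus <- if (sr^2 + sb^2 > 0) num / sqrt(sr^2 / n + sb^2 / n) else 0
  z <- if (num == 0) 0
       else if (radicand > 0) num / sqrt(radicand)
       else NaN
  new("ResponseStat", z = z, zFallback = zplus, muResp = mr,
      muBaseline = mb, sigmaResp = sr, sigmaBaseline = sb,
      n = as.integer(n), pValue = NA_real_, label = "")
}

#' Classify a cell's response by a paired t-test
#'
#' Two-sided paired t-test on per-trial (response - baseline) differences.
#' A significant positive mean difference labels the cell "excited", a
#' significant negative one "inhibited", otherwise "nonresponsive". With
#' zero-variance differences the test degenerates: identical windows give
#' p = 1, a constant nonzero difference is treated as p = 0 (logged).
#'
#' @param respMeans per-trial response-window means.
#' @param baseMeans per-trial baseline-window means (paired).
#' @param alpha significance level (0.01 for light responses, 0.05 for
#'   odor responsiveness).
#' @return list with \code{label}, \code{pValue} and \code{meanDiff}.
#' @export
classifyResponse <- function(respMeans, baseMeans, alpha = 0.01) {
  if (length(respMeans) != length(baseMeans))
    stop("pairing error: respMeans and baseMeans differ in length")
  if (length(respMeans) < 2L) stop("need at least 2 paired trials")
  d <- respMeans - baseMeans
  md <- mean(d)
  if (stats::sd(d) == 0) {
    if (md == 0) {
      p <- 1
    } else {
      message("zero-variance differences with nonzero mean; p treated as 0")
      p <- 0
    }
  } else {
    p <- stats::t.test(d)$p.value
  }
  label <- if (p < alpha && md > 0) "excited"
           else if (p < alpha && md < 0) "inhibited"
           else "nonresponsive"
  list(label = label, pValue = p, meanDiff = md)
}

#' Per-cell response table for one stimulus condition
#'
#' Convenience wrapper: selects the trials of a stimulus, computes each
#' cell's per-trial window means, z-score and paired-test classification.
#'
#' @param traces a [TraceSet-class].
#' @param trialTable a [TrialTable-class].
#' @param stimulus stimulus label(s) selecting the trials.
#' @param alpha significance level for classification.
#' @return data.frame with one row per cell: z, zFallback, muResp,
#'   muBaseline, pValue, label, n.
#' @export
responseStats <- function(traces, trialTable, stimulus, alpha = 0.01) {
  df <- trialTable@trials
  sel <- df$stimulus %in% stimulus
  if (!any(sel)) stop(sprintf("no trials with stimulus %s",
                              paste(stimulus, collapse = "/")))
  sub <- new("TrialTable", trials = df[sel, , drop = FALSE])
  wm <- trialWindowMeans(traces, sub)
  k <- nrow(wm$resp)
  out <- data.frame(cell = seq_len(k), z = NA_real_, zFallback = NA_real_,
                    muResp = NA_real_, muBaseline = NA_real_,
                    pValue = NA_real_, label = "", n = ncol(wm$resp))
  for (i in seq_len(k)) {
    zs <- computeZScore(wm$resp[i, ], wm$base[i, ])
    cl <- classifyResponse(wm$resp[i, ], wm$base[i, ], alpha)
    out$z[i] <- zs@z; out$zFallback[i] <- zs@zFallback
    out$muResp[i] <- zs@muResp; out$muBaseline[i] <- zs@muBaseline
    out$pValue[i] <- cl$pValue; out$label[i] <- cl$label
  }
  out
}
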