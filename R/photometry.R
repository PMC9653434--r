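# Fiber-photometry preprocessing, QC and trial analysis.

#' Smooth and downsample a photometry signal
#'
#' Moving-average smoothing over a fixed time window (0.02 s by default)
#' followed by decimation to the target rate by averaging over each
#' decimation bin. The boxcar provides the anti-aliasing; no further filter
#' is applied. A non-integer rate ratio is handled by averaging over
#' non-integer bins with a note.
#'
#' @param raw numeric signal at the acquisition rate.
#' @param rate acquisition rate in Hz (must be >= \code{targetRate}).
#' @param smoothWindow smoothing window in seconds (default 0.02).
#' @param targetRate output rate in Hz (default 500).
#' @return numeric signal at \code{targetRate}.
#' @export
preprocessSignal <- function(raw, rate, smoothWindow = 0.02,
                             targetRate = 500) {
  if (rate < targetRate) stop("rate must be >= targetRate")
  w <- max(1L, round(smoothWindow * rate))
  if (w %% 2L == 0L) w <- w + 1L                     # centered window
  sm <- .movingAverage(raw, w)
  factor <- rate / targetRate
  n <- length(sm)
  if (abs(factor - round(factor)) < 1e-9) {
    factor <- round(factor)
    m <- n %/% factor
    colMeans(matrix(sm[seq_len(m * factor)], nrow = factor))
  } else {
    message(sprintf(
      "rate %g is not an integer multiple of %g; averaging over non-integer bins",
      rate, targetRate))
    bin <- floor((seq_len(n) - 1L) * targetRate / rate)
    as.numeric(tapply(sm, bin, mean))
  }
}

#' Per-trial delta-F-over-F matrix
#'
#' Crops each trial from the session, normalizes to the trial's baseline
#' F0 (mean fluorescence over the \code{pre} seconds before onset) and
#' aligns the rows to trial onset. Trials with non-positive F0 are dropped
#' with a message. The result is invariant to any positive gain applied to
#' the raw fluorescence.
#'
#' @param session a [PhotometrySession-class] (typically already passed
#'   through [preprocessSignal()]).
#' @param pre baseline seconds before onset used for F0 and included in
#'   the aligned rows (default 2).
#' @param post seconds after onset to include (default 8).
#' @param channel "fluorescence" (default) or "reflection" (for QC).
#' @return A [TrialMatrix-class].
#' @export
trialDff <- function(session, pre = 2, post = 8, channel = "fluorescence") {
  stopifnot(is(session, "PhotometrySession"))
  x <- slot(session, match.arg(channel, c("fluorescence", "reflection")))
  if (!length(x)) stop("QC inapplicable: channel not recorded")
  rate <- session@rate
  df <- session@trials@trials
  nPre <- round(pre * rate); nPost <- round(post * rate)
  time <- (seq_len(nPre + nPost) - nPre - 0.5) / rate
  rows <- list(); cond <- character(); lightOn <- numeric()
  for (i in seq_len(nrow(df))) {
    on <- round(df$onset_s[i] * rate)
    idx <- (on - nPre + 1L):(on + nPost)
    if (idx[1] < 1L || idx[length(idx)] > length(x))
      stop(sprintf("trial %d window extends outside the recording", i))
    seg <- x[idx]
    f0 <- mean(seg[seq_len(nPre)])
    if (!is.finite(f0) || f0 <= 0) {
      message(sprintf("trial %d dropped: F0 = %g not positive", i, f0))
      next
    }
    rows[[length(rows) + 1L]] <- (seg - f0) / f0
    cond <- c(cond, df$stimulus[i])
    lightOn <- c(lightOn, if (!is.null(df$light_on_s))
      df$light_on_s[i] - df$onset_s[i] else NA_real_)
  }
  if (!length(rows)) stop("no trial with a usable baseline")
  new("TrialMatrix", dff = do.call(rbind, rows), time = time,
      condition = cond, lightOn = lightOn, rate = rate)
}

#' Net impact of light on the photometry signal
#'
#' For each trial, the difference between the mean dF/F during the light
#' window and the mean dF/F in the window of the same width immediately
#' before light onset. Computed at the same latencies on no-light trials
#' for comparison. Negative values indicate light-evoked suppression.
#'
#' @param trialMatrix a [TrialMatrix-class].
#' @param lightOnset light onset relative to trial onset in seconds
#'   (default 3.5; trials carrying their own \code{lightOn} use it).
#' @param window window width in seconds (default 1).
#' @return list with \code{perTrial} (data.frame: trial, condition,
#'   impact) and \code{byCondition} (named mean impact per condition).
#' @export
netLightImpact <- function(trialMatrix, lightOnset = 3.5, window = 1) {
  stopifnot(is(trialMatrix, "TrialMatrix"))
  tm <- trialMatrix
  n <- nrow(tm@dff)
  impact <- numeric(n)
  for (i in seq_len(n)) {
    on <- if (is.finite(tm@lightOn[i])) tm@lightOn[i] else lightOnset
    during <- tm@time >= on & tm@time < on + window
    before <- tm@time >= on - window & tm@time < on
    if (!any(during) || !any(before))
      stop(sprintf("alignment error: light window [%g, %g) outside trial %d",
                   on, on + window, i))
    impact[i] <- mean(tm@dff[i, during]) - mean(tm@dff[i, before])
  }
  perTrial <- data.frame(trial = seq_len(n), condition = tm@condition,
                         impact = impact)
  list(perTrial = perTrial,
       byCondition = tapply(impact, tm@condition, mean))
}

#' Reflected-light session quality control
#'
#' Sessions whose reflected-excitation channel shows a mean absolute dF/F
#' change above 1% during the stimulation windows are discarded: a change
#' in reflected light indicates an optical artifact (fiber coupling,
#' movement) rather than a calcium signal. The comparison is strict
#' (exactly 1% keeps the session). Sessions without a reflection channel
#' are marked unverified.
#'
#' @param session a [PhotometrySession-class].
#' @param lightOnset,window stimulation window relative to trial onset
#'   (seconds), as in [netLightImpact()].
#' @param threshold dF/F discard threshold (default 0.01, i.e. 1%).
#' @param pre baseline seconds for the reflection dF/F (default 2).
#' @return list with \code{decision} ("keep", "discard" or "unverified")
#'   and \code{meanAbsChange}.
#' @export
qcReflection <- function(session, lightOnset = 3.5, window = 1,
                         threshold = 0.01, pre = 2) {
  stopifnot(is(session, "PhotometrySession"))
  if (!length(session@reflection)) {
    message("no reflection channel; session marked unverified")
    return(list(decision = "unverified", meanAbsChange = NA_real_))
  }
  tm <- trialDff(session, pre = pre, channel = "reflection")
  lit <- is.finite(tm@lightOn)
  if (!any(lit)) lit <- rep(TRUE, nrow(tm@dff))   # fall back to all trials
  changes <- vapply(which(lit), function(i) {
    on <- if (is.finite(tm@lightOn[i])) tm@lightOn[i] else lightOnset
    during <- tm@time >= on & tm@time < on + window
    before <- tm@time >= on - window & tm@time < on
    mean(tm@dff[i, during]) - mean(tm@dff[i, before])
  }, numeric(1))
  m <- mean(abs(changes))
  # strict > with a guard against floating-point representation at the
  # boundary (an artifact of exactly 1% keeps the session)
  list(decision = if (m > threshold * (1 + 1e-9)) "discard" else "keep",
       meanAbsChange = m)
}
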