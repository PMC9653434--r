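# Seeded synthetic-data generation: trial protocols, ground-truth-labeled
# calcium movies, trace sets, and photometry sessions.

#' Stimulation protocol specification
#'
#' Timing template for generated trial schedules. The two-photon preset
#' follows the in vivo protocol: 8 s baseline, 2 s stimulation, 10 s
#' inter-trial interval, blocks of 20 trials (10 trials of each odorant,
#' delivered randomly within a block), 15 Hz acquisition. The photometry
#' preset: 5-s odors every 60 s, a 1-s light pulse 3.5 s after odor onset
#' (and a spontaneous-activity light pulse 30 s after the odor), 10
#' repetitions per condition, 5 kHz acquisition.
#'
#' @slot modality "twophoton" or "photometry".
#' @slot timing named numeric vector of timing constants (seconds/Hz).
#' @slot conditions character vector of block/cycle condition types.
#' @slot odors odorant labels used in odor-containing conditions.
#' @export
setClass("ProtocolSpec",
  representation(modality = "character", timing = "numeric",
                 conditions = "character", odors = "character")
)

setValidity("ProtocolSpec", function(object) {
  if (!object@modality %in% c("twophoton", "photometry"))
    return("modality must be 'twophoton' or 'photometry'")
  if (any(!is.finite(object@timing)) || any(object@timing < 0))
    return("timing constants must be finite and nonnegative")
  need <- if (object@modality == "twophoton")
    c("baseline_s", "stim_s", "iti_s", "trialsPerBlock", "frameRate")
  else c("odor_s", "period_s", "light_s", "lightDelay_s",
         "spontLightDelay_s", "repsPerCondition", "rate")
  if (!all(need %in% names(object@timing)))
    return(paste("timing must include:", paste(need, collapse = ", ")))
  if (object@modality == "twophoton" &&
      object@timing[["trialsPerBlock"]] %% length(object@odors) != 0)
    return("trialsPerBlock must be a multiple of the number of odors")
  TRUE
})

setMethod("show", "ProtocolSpec", function(object) {
  cat(sprintf("ProtocolSpec (%s): %s\n  conditions: %s\n", object@modality,
              paste(names(object@timing), object@timing, sep = "=",
                    collapse = ", "),
              paste(object@conditions, collapse = ", ")))
})

#' @describeIn ProtocolSpec two-photon protocol preset (defaults follow
#'   the in vivo recordings).
#' @param baseline_s,stim_s,iti_s trial phases in seconds.
#' @param trialsPerBlock trials per block.
#' @param frameRate acquisition rate, Hz.
#' @param conditions block stimulus types.
#' @param odors odorant labels.
#' @export
twophotonProtocol <- function(baseline_s = 8, stim_s = 2, iti_s = 10,
                              trialsPerBlock = 20, frameRate = 15,
                              conditions = c("odor", "light", "odor+light"),
                              odors = c("odor_a", "odor_b")) {
  new("ProtocolSpec", modality = "twophoton",
      timing = c(baseline_s = baseline_s, stim_s = stim_s, iti_s = iti_s,
                 trialsPerBlock = trialsPerBlock, frameRate = frameRate,
                 shutterPad_s = 0.05),
      conditions = conditions, odors = odors)
}

#' @describeIn ProtocolSpec fiber-photometry protocol preset.
#' @param odor_s odor duration, s.
#' @param period_s trial spacing, s.
#' @param light_s light-pulse duration, s.
#' @param lightDelay_s in-trial light onset after odor onset, s.
#' @param spontLightDelay_s spontaneous-activity light pulse after the
#'   odor, s.
#' @param repsPerCondition repetitions of each condition.
#' @param rate acquisition rate, Hz.
#' @export
photometryProtocol <- function(odor_s = 5, period_s = 60, light_s = 1,
                               lightDelay_s = 3.5, spontLightDelay_s = 30,
                               repsPerCondition = 10, rate = 5000,
                               conditions = c("odor", "light",
                                              "odor+light")) {
  new("ProtocolSpec", modality = "photometry",
      timing = c(odor_s = odor_s, period_s = period_s, light_s = light_s,
                 lightDelay_s = lightDelay_s,
                 spontLightDelay_s = spontLightDelay_s,
                 repsPerCondition = repsPerCondition, rate = rate),
      conditions = conditions, odors = "odor")
}

#' Generate a randomized trial schedule
#'
#' Two-photon: for each condition type, \code{nBlocks} blocks of
#' \code{trialsPerBlock} trials; odor identity is randomized within each
#' block (equal counts per odorant). Light-containing trials carry shutter
#' close/open times padded 50 ms around the stimulation; odor-only trials
#' anchor their analysis windows at stimulus onset/offset. Photometry:
#' cycles of one trial per condition at the stated spacing, with the
#' in-trial and post-odor light onsets recorded.
#'
#' @param spec a [ProtocolSpec-class].
#' @param nBlocks blocks per condition (two-photon) — ignored for
#'   photometry, where \code{repsPerCondition} rules.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A [TrialTable-class].
#' @export
generateProtocol <- function(spec, nBlocks = 1, seed = 0) {
  stopifnot(is(spec, "ProtocolSpec"))
  validObject(spec)
  if (nBlocks < 1) stop("nBlocks must be >= 1")
  set.seed(seed)
  tm <- spec@timing
  if (spec@modality == "twophoton") {
    trialDur <- tm[["baseline_s"]] + tm[["stim_s"]] + tm[["iti_s"]]
    perBlock <- as.integer(tm[["trialsPerBlock"]])
    pad <- tm[["shutterPad_s"]]
    rows <- list(); cursor <- 0; blockId <- 0L
    for (type in spec@conditions) {
      for (b in seq_len(nBlocks)) {
        blockId <- blockId + 1L
        hasOdor <- grepl("odor", type)
        hasLight <- grepl("light", type) || type == "shutter-control"
        stim <- if (hasOdor) {
          lab <- sample(rep(spec@odors, perBlock / length(spec@odors)))
          if (grepl("light", type)) paste0(lab, "+light") else lab
        } else rep(type, perBlock)
        onset <- cursor + seq(0, by = trialDur,
                              length.out = perBlock) + tm[["baseline_s"]]
        rows[[blockId]] <- data.frame(
          onset_s = onset, stimulus = stim, block = blockId,
          shutter_close_s = if (hasLight) onset - pad else onset,
          shutter_open_s = if (hasLight) onset + tm[["stim_s"]] + pad
                           else onset + tm[["stim_s"]])
        cursor <- cursor + perBlock * trialDur
      }
    }
    df <- do.call(rbind, rows)
  } else {
    reps <- as.integer(tm[["repsPerCondition"]])
    period <- tm[["period_s"]]
    rows <- list(); i <- 0L
    for (r in seq_len(reps)) {
      for (type in spec@conditions) {
        i <- i + 1L
        onset <- (i - 1) * period + period / 2
        hasLight <- grepl("light", type)
        rows[[i]] <- data.frame(
          onset_s = onset, stimulus = type, block = r,
          shutter_close_s = onset, shutter_open_s = onset + tm[["odor_s"]],
          light_on_s = if (hasLight) onset + tm[["lightDelay_s"]]
                       else NA_real_,
          spont_light_on_s = if (hasLight)
            onset + tm[["spontLightDelay_s"]] else NA_real_)
      }
    }
    df <- do.call(rbind, rows)
  }
  new("TrialTable", trials = df)
}

# slow-indicator impulse response, unit peak
.indicatorKernel <- function(rate, rise_s, decay_s, span_s = 6 * decay_s) {
  t <- seq(0, span_s, by = 1 / rate)
  k <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  k / max(k)
}

#' Ground-truth parameters for a synthetic movie
#'
#' Defaults emulate a desk-scale recording: 128 x 128 px (a scaled-down
#' field of view), 30 Gaussian-disc cells, slow-indicator kinetics (0.2 s
#' rise, 1 s decay, literature-informed for a slow GCaMP), Poisson events
#' whose rates are modulated by each cell's condition effect during
#' stimulation, additive background and Gaussian noise.
#'
#' @param nCells number of cells.
#' @param width,height field of view in pixels.
#' @param background baseline intensity.
#' @param baselineLevel static per-cell baseline brightness (the resting
#'   indicator fluorescence that makes the anatomy visible in every
#'   in-plane frame).
#' @param noiseSigma additive Gaussian noise SD.
#' @param amp fluorescence amplitude per event.
#' @param radiusRange cell radius range in px (Gaussian sigma).
#' @param fracExcited,fracInhibited condition-effect fractions (the rest
#'   are null cells).
#' @param spontRate,stimRate event rates (Hz) of excited cells outside /
#'   during stimulation.
#' @param tonicRate event rate of inhibited and null cells outside
#'   stimulation; inhibited cells are suppressed to (almost) zero during
#'   stimulation.
#' @param rise_s,decay_s indicator kinetics (s).
#' @param driftFrames,driftShift frames to displace and the (dy, dx)
#'   displacement in px (for registration ground truth).
#' @param zFrames frames replaced by out-of-plane (noise-only) images.
#' @return list of ground-truth parameters.
#' @export
movieTruthParams <- function(nCells = 30, width = 128, height = 128,
                             background = 100, baselineLevel = 20,
                             noiseSigma = 2, amp = 30,
                             radiusRange = c(2.5, 4), fracExcited = 0.3,
                             fracInhibited = 0.3, spontRate = 0.05,
                             stimRate = 1.5, tonicRate = 0.4,
                             rise_s = 0.2, decay_s = 1,
                             driftFrames = integer(0),
                             driftShift = c(0, 0), zFrames = integer(0)) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  list(nCells = nCells, width = width, height = height,
       background = background, baselineLevel = baselineLevel,
       noiseSigma = noiseSigma, amp = amp,
       radiusRange = radiusRange, fracExcited = fracExcited,
       fracInhibited = fracInhibited, spontRate = spontRate,
       stimRate = stimRate, tonicRate = tonicRate, rise_s = rise_s,
       decay_s = decay_s, driftFrames = driftFrames,
       driftShift = driftShift, zFrames = zFrames)
}

# place non-overlapping cells; returns positions (y, x) and radii
.placeCells <- function(n, h, w, radiusRange) {
  pos <- matrix(NA_real_, n, 2)
  rad <- stats::runif(n, radiusRange[1], radiusRange[2])
  margin <- 2 * max(radiusRange) + 1
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      y <- stats::runif(1, margin, h - margin)
      x <- stats::runif(1, margin, w - margin)
      if (i == 1 || all(sqrt((pos[seq_len(i - 1), 1] - y)^2 +
                             (pos[seq_len(i - 1), 2] - x)^2) >
                        2.2 * (rad[seq_len(i - 1)] + rad[i]))) {
        pos[i, ] <- c(y, x); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place non-overlapping cells; lower nCells")
  }
  list(pos = pos, rad = rad)
}

#' Generate a ground-truth-labeled calcium movie
#'
#' Builds a synthetic trial-structured movie: Gaussian-disc cells with
#' condition-dependent Poisson event rates convolved with a slow-indicator
#' kernel, on a noisy background, with optional injected lateral drift and
#' out-of-plane frames. Everything injected is recorded in the returned
#' ground truth. Identical seeds give identical output.
#'
#' @param protocol a [TrialTable-class] (the stimulation windows modulate
#'   event rates).
#' @param params ground-truth parameters from [movieTruthParams()].
#' @param frameRate acquisition rate, Hz (default 15).
#' @param seed RNG seed.
#' @param stimDuration_s stimulation duration used for the modulation
#'   windows (default 2).
#' @return list with \code{movie} ([CalciumMovie-class]), \code{rois}
#'   (ground-truth [RoiSet-class]) and \code{truth} (positions, radii,
#'   labels, per-cell fluorescence, injected shifts and z-frames, seed).
#' @export
generateMovie <- function(protocol, params = movieTruthParams(),
                          frameRate = 15, seed = 0, stimDuration_s = 2) {
  stopifnot(is(protocol, "TrialTable"))
  set.seed(seed)
  df <- protocol@trials
  tEnd <- max(df$onset_s) + stimDuration_s + 4
  nT <- ceiling(tEnd * frameRate)
  tcenters <- (seq_len(nT) - 0.5) / frameRate
  h <- params$height; w <- params$width
  k <- params$nCells
  place <- .placeCells(k, h, w, params$radiusRange)
  nEx <- round(params$fracExcited * k)
  nIn <- round(params$fracInhibited * k)
  labels <- sample(c(rep("excited", nEx), rep("inhibited", nIn),
                     rep("null", k - nEx - nIn)))
  inStim <- rep(FALSE, nT)
  for (i in seq_len(nrow(df)))
    inStim <- inStim | (tcenters >= df$onset_s[i] &
                        tcenters < df$onset_s[i] + stimDuration_s)
  kern <- .indicatorKernel(frameRate, params$rise_s, params$decay_s)
  fluor <- matrix(0, nT, k)
  events <- vector("list", k)
  for (j in seq_len(k)) {
    rate <- switch(labels[j],
      excited = ifelse(inStim, params$stimRate, params$spontRate),
      inhibited = ifelse(inStim, 0.02 * params$tonicRate,
                         params$tonicRate),
      null = rep(params$tonicRate, nT))
    ev <- stats::rpois(nT, rate / frameRate)
    events[[j]] <- which(ev > 0)
    f <- stats::convolve(ev, rev(kern), type = "open")[seq_len(nT)]
    fluor[, j] <- params$amp * f
  }
  # footprints: k x pixels (column-major over h x w)
  fp <- matrix(0, k, h * w)
  masks <- matrix(0L, h, w)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (j in seq_len(k)) {
    d2 <- (yy - place$pos[j, 1])^2 + (xx - place$pos[j, 2])^2
    g <- exp(-d2 / (2 * place$rad[j]^2))
    g[d2 > (3 * place$rad[j])^2] <- 0
    fp[j, ] <- as.vector(g)
    masks[d2 <= (1.5 * place$rad[j])^2] <- j
  }
  # static anatomy (resting indicator brightness) + activity + noise
  anatomy <- params$baselineLevel * colSums(fp)
  flat <- fluor %*% fp +
    matrix(anatomy, nT, h * w, byrow = TRUE) +
    params$background +
    stats::rnorm(nT * h * w, 0, params$noiseSigma)
  frames <- array(flat, c(nT, h, w))
  shifts <- matrix(0, nT, 2, dimnames = list(NULL, c("dy", "dx")))
  for (i in params$driftFrames) {
    frames[i, , ] <- .shiftMatrix(frames[i, , ], params$driftShift[1],
                                  params$driftShift[2],
                                  fill = params$background)
    shifts[i, ] <- params$driftShift
  }
  for (i in params$zFrames)
    frames[i, , ] <- params$background +
      stats::rnorm(h * w, 0, max(params$noiseSigma, 1))
  list(movie = calciumMovie(frames, frameRate),
       rois = roiSet(masks),
       truth = list(positions = place$pos, radii = place$rad,
                    labels = labels, fluor = fluor, events = events,
                    shifts = shifts, zFrames = params$zFrames,
                    noiseSigma = params$noiseSigma, seed = seed))
}

#' Generate per-trial window means with known effects
#'
#' Direct fixture for the z-score statistic and classification
#' calibration: per-trial baseline and response window means are drawn
#' independently from normal distributions with SD \code{noiseSigma}; each
#' cell's response mean is shifted by its entry in \code{effects} (0 for
#' null cells). The documented default effect size for responsive cells is
#' +/- 1.5 with \code{noiseSigma = 1} and 20 trials.
#'
#' @param nCells number of cells.
#' @param nTrials trials per cell (>= 2).
#' @param effects numeric vector (length \code{nCells}, recycled) of
#'   response-window mean shifts.
#' @param noiseSigma window-mean SD (>= 0).
#' @param mu0 common baseline mean.
#' @param seed RNG seed.
#' @return list with matrices \code{resp}, \code{base} (cells x trials),
#'   \code{labels} ("excited"/"inhibited"/"null" from the effect sign) and
#'   \code{effects}.
#' @export
generateTraceSet <- function(nCells, nTrials = 20, effects = 0,
                             noiseSigma = 1, mu0 = 0, seed = 0) {
  if (nTrials < 2) stop("nTrials must be >= 2")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  set.seed(seed)
  effects <- rep_len(effects, nCells)
  base <- matrix(stats::rnorm(nCells * nTrials, mu0, noiseSigma), nCells)
  resp <- matrix(stats::rnorm(nCells * nTrials, mu0, noiseSigma), nCells) +
    effects
  labels <- ifelse(effects > 0, "excited",
                   ifelse(effects < 0, "inhibited", "null"))
  list(resp = resp, base = base, labels = labels, effects = effects)
}

#' Generate a ground-truth photometry session
#'
#' Slow odor-evoked dF/F transients (exponential rise to a plateau during
#' the odor, exponential decay after) with multiplicative suppression of
#' the evoked component during the in-trial light windows, plus Gaussian
#' noise. The reflection channel is flat except for an optional injected
#' artifact of \code{artifactPercent} percent during light windows (for QC
#' tests). Suppression levels are assigned to light-containing trials in
#' order of appearance (recycled) and recorded in the ground truth.
#'
#' @param protocol a photometry [TrialTable-class] (see
#'   [generateProtocol()]).
#' @param suppression suppression levels in [0, 1].
#' @param artifactPercent reflected-light artifact amplitude (percent of
#'   the reflection baseline).
#' @param rate sampling rate, Hz (default 5000).
#' @param amp plateau odor-response amplitude in dF/F units (default 0.2).
#' @param noiseSigma fluorescence noise SD (default 0.002).
#' @param seed RNG seed.
#' @return list with \code{session} ([PhotometrySession-class]) and
#'   \code{truth} (per-trial suppression, artifact, amplitude, seed).
#' @export
generatePhotometrySession <- function(protocol, suppression = 0,
                                      artifactPercent = 0, rate = 5000,
                                      amp = 0.2, noiseSigma = 0.002,
                                      seed = 0) {
  stopifnot(is(protocol, "TrialTable"))
  if (any(suppression < 0 | suppression > 1))
    stop("suppression levels must lie in [0, 1]")
  set.seed(seed)
  df <- protocol@trials
  odorDur <- unique(df$shutter_open_s - df$onset_s)[1]
  lightDur <- 1
  tEnd <- max(df$onset_s) + odorDur + 20
  n <- ceiling(tEnd * rate)
  tt <- (seq_len(n) - 0.5) / rate
  evoked <- numeric(n)
  lit <- grepl("light", df$stimulus)
  odorLit <- lit & grepl("odor", df$stimulus)
  suppPerTrial <- rep(NA_real_, nrow(df))
  suppPerTrial[odorLit] <- rep_len(suppression, sum(odorLit))
  for (i in seq_len(nrow(df))) {
    if (!grepl("odor", df$stimulus[i])) next
    on <- df$onset_s[i]
    during <- tt >= on & tt < on + odorDur
    after <- tt >= on + odorDur
    shape <- numeric(n)
    shape[during] <- 1 - exp(-(tt[during] - on) / 0.3)
    endVal <- 1 - exp(-odorDur / 0.3)
    shape[after] <- endVal * exp(-(tt[after] - on - odorDur) / 1)
    if (odorLit[i] && is.finite(df$light_on_s[i])) {
      lw <- tt >= df$light_on_s[i] & tt < df$light_on_s[i] + lightDur
      shape[lw] <- shape[lw] * (1 - suppPerTrial[i])
    }
    evoked <- evoked + shape
  }
  f0 <- 1
  fluor <- f0 * (1 + amp * evoked) + stats::rnorm(n, 0, noiseSigma)
  refl <- rep(1, n)
  for (i in which(lit)) {
    if (!is.finite(df$light_on_s[i])) next
    lw <- tt >= df$light_on_s[i] & tt < df$light_on_s[i] + lightDur
    refl[lw] <- refl[lw] + artifactPercent / 100
  }
  session <- photometrySession(fluor, refl, rate, protocol)
  list(session = session,
       truth = list(suppression = suppPerTrial,
                    artifactPercent = artifactPercent, amp = amp,
                    seed = seed))
}
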