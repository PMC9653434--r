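# Frame QC, translational motion correction and PCA-assisted reconstruction
# of calcium movies.

# Non-circular integer shift of a matrix: out[y, x] = m[y - dy, x - dx],
# zero fill outside.
.shiftMatrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- intersect(seq_len(h), seq_len(h) + dy)   # destination rows
  xs <- intersect(seq_len(w), seq_len(w) + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Displacement d = (dy, dx) such that frame[y, x] ~ ref[y-dy, x-dx],
# estimated from the peak of the circular FFT cross-correlation of the
# mean-subtracted images, refined to subpixel precision by a 3-point
# parabolic fit along each axis.
.estimateShift <- function(ref, frame) {
  a <- ref - mean(ref)
  b <- frame - mean(frame)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  h <- nrow(ref); w <- ncol(ref)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sub <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (den < 0) 0.5 * (cm1 - cp1) / den else 0
  }
  dy <- peak[1] - 1 + sub(cc[wrap(peak[1] - 1, h), peak[2]],
                          cc[peak[1], peak[2]],
                          cc[wrap(peak[1] + 1, h), peak[2]])
  dx <- peak[2] - 1 + sub(cc[peak[1], wrap(peak[2] - 1, w)],
                          cc[peak[1], peak[2]],
                          cc[peak[1], wrap(peak[2] + 1, w)])
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dy = dy, dx = dx)
}

#' Flag out-of-plane (z-movement) frames
#'
#' Computes each frame's Pearson correlation with the average projection of
#' the entire stack (computed once, from all frames) and flags frames whose
#' correlation falls to or below the threshold as out-of-plane. Frames with
#' zero variance (constant images) have undefined correlation and are
#' flagged with a message.
#'
#' @param movie a [CalciumMovie-class] with at least 2 frames.
#' @param rThreshold correlation threshold in [-1, 1]; frames with
#'   r <= rThreshold are flagged (default 0.65).
#' @return The movie with \code{keptFrames} updated (flags combine with any
#'   existing flags by logical AND).
#' @export
flagZFrames <- function(movie, rThreshold = 0.65) {
  stopifnot(is(movie, "CalciumMovie"))
  n <- nFrames(movie)
  if (n < 2L) stop("need at least 2 frames")
  avg <- apply(movie@frames, c(2, 3), mean)
  av <- as.vector(avg)
  keep <- logical(n)
  for (i in seq_len(n)) {
    fv <- as.vector(movie@frames[i, , ])
    if (stats::sd(fv) == 0 || stats::sd(av) == 0) {
      message(sprintf("frame %d has zero variance; correlation undefined, frame flagged", i))
      keep[i] <- FALSE
    } else {
      keep[i] <- stats::cor(fv, av) > rThreshold
    }
  }
  movie@keptFrames <- movie@keptFrames & keep
  validObject(movie)
  movie
}

#' Correct translational (lateral) motion
#'
#' Estimates per-frame translations by FFT cross-correlation in two
#' stages: a first pass against the plain average of the kept frames, then
#' a second pass against a reference rebuilt from the frames sharing the
#' modal first-pass shift (a mutually aligned subset, so the reference is
#' a single sharp copy of the anatomy even when a large fraction of frames
#' drifted). The inverse of the rounded estimate is applied to the pixels
#' (zero fill at the edges); the returned shifts carry subpixel precision.
#' Frames whose displacement exceeds \code{maxShiftFrac} of the frame size
#' are flagged not-kept instead of being shifted; frames already flagged
#' (e.g. out-of-plane) are skipped and report NA shifts.
#'
#' @param movie a [CalciumMovie-class].
#' @param maxShiftFrac maximum tolerated shift as a fraction of the frame
#'   dimensions (default 0.1).
#' @return list with \code{movie} (registered) and \code{shifts}, an
#'   n x 2 matrix of estimated (dy, dx) displacements in pixels.
#' @export
correctLateralMotion <- function(movie, maxShiftFrac = 0.1) {
  stopifnot(is(movie, "CalciumMovie"))
  if (!any(movie@keptFrames)) stop("no kept frames to register to")
  d <- dim(movie@frames)
  shifts <- matrix(NA_real_, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  if (d[1] == 1L) {
    shifts[1, ] <- 0
    return(list(movie = movie, shifts = shifts))
  }
  maxShift <- c(maxShiftFrac * d[2], maxShiftFrac * d[3])
  kept <- which(movie@keptFrames)
  ref <- apply(movie@frames[kept, , , drop = FALSE], c(2, 3), mean)
  est1 <- t(vapply(kept, function(i)
    round(.estimateShift(ref, movie@frames[i, , ])), numeric(2)))
  key <- paste(est1[, 1], est1[, 2])
  modal <- kept[key == names(sort(table(key), decreasing = TRUE))[1]]
  ref2 <- apply(movie@frames[modal, , , drop = FALSE], c(2, 3), mean)
  for (i in seq_len(d[1])) {
    if (!movie@keptFrames[i]) next
    s <- .estimateShift(ref2, movie@frames[i, , ])
    shifts[i, ] <- s
    if (abs(s[1]) > maxShift[1] || abs(s[2]) > maxShift[2]) {
      movie@keptFrames[i] <- FALSE
      message(sprintf(
        "frame %d: shift (%g, %g) exceeds guard; frame flagged not-kept",
        i, s[1], s[2]))
      next
    }
    si <- round(s)
    if (any(si != 0))
      movie@frames[i, , ] <- .shiftMatrix(movie@frames[i, , ], -si[1],
                                          -si[2])
  }
  list(movie = movie, shifts = shifts)
}

#' PCA-assisted movie reconstruction
#'
#' Reshapes the kept frames to a time x pixels matrix, centers each pixel's
#' time course, and reconstructs the movie from the leading
#' \code{nComponents} principal components (scores times coefficients plus
#' the pixel means). Inactive pixels and shot noise carry little temporal
#' variance and are suppressed; with \code{nComponents} at or above the
#' movie's intrinsic rank the reconstruction is exact. Not-kept frames pass
#' through unchanged. The projection is idempotent: reconstructing a
#' reconstruction with the same number of components returns it unchanged.
#'
#' @param movie a [CalciumMovie-class]; kept-frame count must exceed
#'   \code{nComponents}.
#' @param nComponents number of principal components (default 10).
#' @return The reconstructed [CalciumMovie-class].
#' @export
pcaReconstruct <- function(movie, nComponents = 10) {
  stopifnot(is(movie, "CalciumMovie"))
  kept <- which(movie@keptFrames)
  t <- length(kept)
  if (nComponents <= 0) stop("invalid parameter: nComponents must be positive")
  if (t <= nComponents)
    stop("invalid parameter: kept-frame count must exceed nComponents")
  d <- dim(movie@frames)
  x <- matrix(movie@frames[kept, , ], nrow = t)     # time x pixels
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  # top-k left singular subspace via the t x t Gram matrix (t << pixels)
  g <- tcrossprod(xc)
  eg <- eigen(g, symmetric = TRUE)
  u <- eg$vectors[, seq_len(nComponents), drop = FALSE]
  xhat <- u %*% crossprod(u, xc)
  xhat <- sweep(xhat, 2, mu, "+")
  movie@frames[kept, , ] <- array(xhat, c(t, d[2], d[3]))
  movie
}

#' Refine ROI boundaries by within-ROI PCA
#'
#' For each ROI, performs a PCA of the ROI's pixel time courses and removes
#' pixels whose combined loading magnitude on the first
#' \code{nComponents} components (amplitude-weighted) falls below
#' \code{coefficientThreshold} times the ROI's maximum. This trims
#' neuropil/background pixels at the rim that do not share the cell's
#' temporal signal; fluorescence values are never modified. ROIs whose
#' leading components explain less than \code{minVarExplained} of the
#' temporal variance (no coherent signal) or that would shrink below 3
#' pixels keep their original mask with a warning.
#'
#' @param movie a [CalciumMovie-class] (typically motion-corrected raw
#'   data; reconstruction is not required since intensities are untouched).
#' @param rois a [RoiSet-class]; each ROI needs more pixels than
#'   \code{nComponents}.
#' @param nComponents number of leading components used (default 3).
#' @param coefficientThreshold fraction of the ROI's maximum loading below
#'   which pixels are removed (default 0.25).
#' @param minVarExplained minimum fraction of within-ROI temporal variance
#'   the leading components must explain for refinement to proceed
#'   (default 0.2).
#' @return A [RoiSet-class] with refined masks (provenance updated).
#' @export
refineRois <- function(movie, rois, nComponents = 3,
                       coefficientThreshold = 0.25, minVarExplained = 0.2) {
  stopifnot(is(movie, "CalciumMovie"), is(rois, "RoiSet"))
  kept <- which(movie@keptFrames)
  masks <- rois@masks
  prov <- rois@provenance
  for (k in seq_len(nRois(rois))) {
    idx <- which(masks == k)                     # column-major pixel indices
    if (length(idx) <= nComponents)
      stop(sprintf("ROI %d has %d pixels; need more than nComponents = %d",
                   k, length(idx), nComponents))
    # pixel time courses: time x pixels
    y <- matrix(movie@frames[kept, , ], nrow = length(kept))[, idx,
                                                             drop = FALSE]
    yc <- sweep(y, 2, colMeans(y))
    cm <- crossprod(yc)                          # pixels x pixels
    eg <- eigen(cm, symmetric = TRUE)
    tot <- sum(pmax(eg$values, 0))
    ncomp <- min(nComponents, length(eg$values))
    ve <- sum(pmax(eg$values[seq_len(ncomp)], 0)) / max(tot, .Machine$double.eps)
    if (tot <= 0 || ve < minVarExplained) {
      warning(sprintf(
        "ROI %d: leading components explain %.1f%% of variance (no coherent signal); mask kept",
        k, 100 * ve))
      next
    }
    v <- eg$vectors[, seq_len(ncomp), drop = FALSE]
    amp <- sqrt(pmax(eg$values[seq_len(ncomp)], 0))
    load <- sqrt(rowSums(sweep(v, 2, amp, "*")^2))
    keepPx <- load >= coefficientThreshold * max(load)
    if (sum(keepPx) < 3L) {
      warning(sprintf("ROI %d would shrink below 3 pixels; mask kept", k))
      next
    }
    masks[idx[!keepPx]] <- 0L
    prov[k] <- "refined"
  }
  new("RoiSet", masks = masks, provenance = prov)
}
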