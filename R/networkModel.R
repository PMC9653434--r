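# Two-population MC/TC-GC rate model with cortical GABAergic feedback.
#
# dMC/dt = -MC + I - wMcGc * GC - wFbMc * FB
# dGC/dt = -GC + wMcGc * MC - wSacGc * SAC - 2 * wFbMc * FB,  GC >= 0
#
# FB is 1 with feedback stimulation and 0 otherwise; the dSAC drive SAC is
# 0.1 / wFbMc with feedback (the feedback shunts dSAC input to GCs) and 1
# otherwise. Time constants are 1 for both populations. The Jacobian of the
# linear branch is [[-1, -w], [w, -1]] with eigenvalues -1 +/- i*w, so every
# parameter set with finite weights is stable; forward Euler is stable for
# dt < 2 / (1 + w^2).

.modelDrift <- function(mc, gc, I, w, wsac, wfb, FB, SAC) {
  c(-mc + I - w * gc - wfb * FB,
    -gc + w * mc - wsac * SAC - 2 * wfb * FB)
}

#' Integrate the circuit dynamics
#'
#' Forward-Euler integration of the MC/TC-GC rate equations, clamping the
#' GC rate at zero after every step (rectification). The linear system is
#' unconditionally stable (Jacobian eigenvalues -1 +/- i * wMcGc), so the
#' trajectory converges to the fixed point returned by
#' [solveFixedPoint()].
#'
#' @param params a [NetworkParams-class].
#' @param init initial state, numeric \code{c(mc, gc)}.
#' @param dt Euler time step (model time units; default 0.01).
#' @param tEnd integration horizon (default 100).
#' @param bound divergence guard: an error is raised if any rate exceeds
#'   this magnitude (default 1e6).
#' @return data.frame with columns \code{time}, \code{mc}, \code{gc}.
#' @examples
#' p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
#' tail(integrateDynamics(p), 1)
#' @export
integrateDynamics <- function(params, init = c(0, 0), dt = 0.01, tEnd = 100,
                              bound = 1e6) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number")
  if (tEnd < dt) stop("tEnd must be >= dt")
  I <- params@I; w <- params@wMcGc; wsac <- params@wSacGc
  wfb <- params@wFbMc; FB <- feedbackIndicator(params)
  SAC <- sacDrive(params)
  n <- floor(tEnd / dt)
  mc <- numeric(n + 1); gc <- numeric(n + 1)
  mc[1] <- init[1]; gc[1] <- max(0, init[2])
  warnedNeg <- FALSE
  for (i in seq_len(n)) {
    d <- .modelDrift(mc[i], gc[i], I, w, wsac, wfb, FB, SAC)
    mc[i + 1] <- mc[i] + dt * d[1]
    gc[i + 1] <- max(0, gc[i] + dt * d[2])
    if (abs(mc[i + 1]) > bound || gc[i + 1] > bound)
      stop(sprintf(
        "divergence: rates exceeded %g at t = %g (unstable regime: dt too large for wMcGc = %g?)",
        bound, i * dt, w))
    if (!warnedNeg && mc[i + 1] < 0) {
      warning("MC/TC rate went negative (MC is not rectified)")
      warnedNeg <- TRUE
    }
  }
  data.frame(time = seq(0, by = dt, length.out = n + 1), mc = mc, gc = gc)
}

#' MC/TC nullcline
#'
#' The locus dMC/dt = 0 expressed as GC as a function of MC:
#' GC = (I - MC - wFbMc * FB) / wMcGc.
#'
#' @param params a [NetworkParams-class].
#' @param mcValues rate grid at which to evaluate the nullcline.
#' @return numeric vector of GC values.
#' @export
mcNullcline <- function(params, mcValues) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  if (params@wMcGc == 0)
    stop("degenerate nullcline: wMcGc = 0 gives a vertical line; GC is not a function of MC")
  (params@I - mcValues - params@wFbMc * feedbackIndicator(params)) /
    params@wMcGc
}

#' GC nullcline
#'
#' The locus dGC/dt = 0 under rectification:
#' GC = max(0, wMcGc * MC - wSacGc * SAC - 2 * wFbMc * FB). The sign of the
#' MC term is the one implied by the GC rate equation (the GC nullcline
#' rises with MC).
#'
#' @inheritParams mcNullcline
#' @return numeric vector of GC values (rectified at 0).
#' @export
gcNullcline <- function(params, mcValues) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  pmax(0, params@wMcGc * mcValues -
          params@wSacGc * sacDrive(params) -
          2 * params@wFbMc * feedbackIndicator(params))
}

#' Solve the circuit fixed point
#'
#' Closed-form steady state of the two-population system. Substituting the
#' MC/TC nullcline into the GC equation gives
#' GC = (w*I - w*wFb*FB - wSac*SAC - 2*wFb*FB) / (1 + w^2); when this is
#' negative the rectified branch applies: GC = 0, MC = I - wFb*FB.
#'
#' @param params a [NetworkParams-class].
#' @return A [FixedPoint-class].
#' @examples
#' solveFixedPoint(networkParams(I = 10, wMcGc = 0.3, wSacGc = 1))
#' @export
solveFixedPoint <- function(params) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  I <- params@I; w <- params@wMcGc
  wfb <- params@wFbMc; FB <- feedbackIndicator(params)
  inh <- params@wSacGc * sacDrive(params) + 2 * wfb * FB
  gc <- (w * I - w * wfb * FB - inh) / (1 + w^2)
  rectified <- gc <= 0      # boundary: both branches coincide at GC = 0
  if (rectified) {
    gc <- 0
    mc <- I - wfb * FB
  } else {
    mc <- I - w * gc - wfb * FB
  }
  d <- .modelDrift(mc, gc, I, w, params@wSacGc, wfb, FB, sacDrive(params))
  # on the rectified branch dGC/dt may be negative; rectification pins GC at 0
  conv <- abs(d[1]) < 1e-9 && (if (rectified) d[2] <= 1e-9 else abs(d[2]) < 1e-9)
  new("FixedPoint", mc = mc, gc = gc, rectified = rectified, converged = conv)
}

#' Rate change caused by cortical GABAergic feedback
#'
#' Fixed-point rates with feedback at strength \code{wFbMc} minus the
#' no-feedback fixed point. In the regime reproducing the in vivo data both
#' changes are negative: feedback produces a net ("paradoxical") inhibition
#' of the recurrently coupled excitatory and inhibitory populations alike.
#' At \code{wFbMc = 0} the change is (0, 0) by convention (the shunted dSAC
#' drive 0.1/wFbMc is undefined there).
#'
#' @param params a [NetworkParams-class] with \code{feedbackOn = FALSE},
#'   describing the unstimulated circuit.
#' @param wFbMc feedback strength at which to stimulate.
#' @return named numeric \code{c(deltaMc, deltaGc)}.
#' @examples
#' feedbackDelta(networkParams(I = 10, wMcGc = 0.3, wSacGc = 1), wFbMc = 1)
#' @export
feedbackDelta <- function(params, wFbMc) {
  stopifnot(is(params, "NetworkParams"))
  if (params@feedbackOn)
    stop("params must describe the unstimulated circuit (feedbackOn = FALSE)")
  if (wFbMc == 0) return(c(deltaMc = 0, deltaGc = 0))
  if (!is.finite(wFbMc) || wFbMc < 0)
    stop("invalid parameter: wFbMc must be > 0 when feedback is applied")
  fp0 <- solveFixedPoint(params)
  fp1 <- solveFixedPoint(networkParams(I = params@I, wMcGc = params@wMcGc,
                                       wSacGc = params@wSacGc, wFbMc = wFbMc,
                                       feedbackOn = TRUE))
  c(deltaMc = fp1@mc - fp0@mc, deltaGc = fp1@gc - fp0@gc)
}

#' Sweep feedback effects over a parameter grid
#'
#' Maps baseline fixed-point rates and feedback-induced rate changes over a
#' grid of MC/TC-GC coupling strengths by feedback strengths.
#'
#' @param I odor input.
#' @param wSacGc dSAC-to-GC strength.
#' @param wMcGcAxis strictly increasing grid of coupling strengths.
#' @param wFbAxis strictly increasing grid of feedback strengths.
#' @return A [SweepResult-class].
#' @export
sweepParameterGrid <- function(I = 10, wSacGc = 1,
                               wMcGcAxis = seq(0.1, 2, length.out = 20),
                               wFbAxis = seq(0, 2, length.out = 20)) {
  if (!length(wMcGcAxis) || !length(wFbAxis))
    stop("axes must be nonempty")
  if (is.unsorted(wMcGcAxis, strictly = TRUE) ||
      is.unsorted(wFbAxis, strictly = TRUE))
    stop("axes must be strictly increasing")
  nr <- length(wMcGcAxis); nc <- length(wFbAxis)
  bMc <- bGc <- dMc <- dGc <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    p0 <- networkParams(I = I, wMcGc = wMcGcAxis[i], wSacGc = wSacGc)
    fp0 <- tryCatch(solveFixedPoint(p0), error = function(e)
      stop(sprintf("solver failed at wMcGc = %g: %s", wMcGcAxis[i],
                   conditionMessage(e))))
    for (j in seq_len(nc)) {
      bMc[i, j] <- fp0@mc; bGc[i, j] <- fp0@gc
      d <- tryCatch(feedbackDelta(p0, wFbAxis[j]), error = function(e)
        stop(sprintf("solver failed at wMcGc = %g, wFb = %g: %s",
                     wMcGcAxis[i], wFbAxis[j], conditionMessage(e))))
      dMc[i, j] <- d[1]; dGc[i, j] <- d[2]
    }
  }
  new("SweepResult", wMcGcAxis = as.numeric(wMcGcAxis),
      wFbAxis = as.numeric(wFbAxis), baselineMc = bMc, baselineGc = bGc,
      deltaMc = dMc, deltaGc = dGc)
}

#' Jacobian eigenvalues of the linear branch
#'
#' Stability diagnostic: the unrectified system's Jacobian is
#' \code{[[-1, -w], [w, -1]]} with eigenvalues \code{-1 +/- i w}; the real
#' part is -1 for any coupling, so the fixed point is always a stable
#' focus/node.
#'
#' @param params a [NetworkParams-class].
#' @return complex vector of the two eigenvalues.
#' @export
jacobianEigenvalues <- function(params) {
  stopifnot(is(params, "NetworkParams"))
  w <- params@wMcGc
  eigen(matrix(c(-1, w, -w, -1), 2, 2), only.values = TRUE)$values
}
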