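# Rate model: integration, nullclines, fixed points, feedback sweeps.
# Expected values frozen from the hand-derived steady-state algebra:
#   GC* = (w*I - w*wfb*FB - wsac*SAC - 2*wfb*FB) / (1 + w^2)
#   MC* = I - w*GC* - wfb*FB     (rectified branch: GC* = 0, MC* = I - wfb*FB)
# e.g. I=10, w=0.3, wsac=1, no feedback: GC* = 2/1.09 = 1.834862,
# MC* = 10 - 0.3*GC* = 9.449541; with feedback wfb=1 (SAC = 0.1):
# GC* = 0.6/1.09 = 0.550459, MC* = 8.834862.

test_that("quiescent uncoupled circuit stays at rest", {
  p <- networkParams(I = 0, wMcGc = 0, wSacGc = 0)
  tr <- integrateDynamics(p, init = c(0, 0), dt = 0.01, tEnd = 5)
  expect_true(all(tr$mc == 0))
  expect_true(all(tr$gc == 0))
})

test_that("Euler integration converges to the closed-form steady state", {
  p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
  fin <- tail(integrateDynamics(p, dt = 0.01, tEnd = 100), 1)
  expect_equal(fin$mc, 9.4495, tolerance = 1e-4)
  expect_equal(fin$gc, 1.8349, tolerance = 1e-4)

  pf <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1, wFbMc = 1,
                      feedbackOn = TRUE)
  finf <- tail(integrateDynamics(pf, dt = 0.01, tEnd = 100), 1)
  expect_equal(finf$mc, 8.8349, tolerance = 1e-4)
  expect_equal(finf$gc, 0.5505, tolerance = 1e-4)
})

test_that("integration agrees with the analytic fixed point over random parameters", {
  set.seed(42)
  for (i in 1:30) {
    fb <- i %% 2 == 0
    p <- networkParams(I = runif(1, 0, 20), wMcGc = runif(1, 0, 3),
                       wSacGc = runif(1, 0, 2),
                       wFbMc = if (fb) runif(1, 0.1, 2) else 0,
                       feedbackOn = fb)
    fp <- solveFixedPoint(p)
    fin <- suppressWarnings(
      tail(integrateDynamics(p, dt = 0.005, tEnd = 60), 1))
    expect_lt(abs(fin$mc - mcRate(fp)), 1e-6 * max(1, abs(mcRate(fp))))
    expect_lt(abs(fin$gc - gcRate(fp)), 1e-6 * max(1, abs(gcRate(fp))))
  }
})

test_that("integration rejects bad inputs and flags divergence", {
  p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
  expect_error(integrateDynamics(p, dt = 0), "dt")
  expect_error(integrateDynamics(p, dt = 0.1, tEnd = 0.01), "tEnd")
  expect_error(networkParams(I = NaN), "finite|invalid")
  expect_error(networkParams(wMcGc = -1), ">= 0|invalid")
  # a state beyond the divergence bound trips the guard
  expect_error(suppressWarnings(
    integrateDynamics(p, init = c(1e7, 0), dt = 0.01, tEnd = 1)),
    "divergence")
})

test_that("nullclines evaluate to the algebraic curves", {
  # root of the MC/TC nullcline sits at MC = I
  expect_equal(mcNullcline(networkParams(I = 10, wMcGc = 1), 10), 0)
  # fixed point lies on the MC/TC nullcline
  expect_equal(mcNullcline(networkParams(I = 10, wMcGc = 0.3, wSacGc = 1),
                           9.449541), 1.834862, tolerance = 1e-5)
  # with feedback: (10 - 0 - 1) / 2
  pf <- networkParams(I = 10, wMcGc = 2, wSacGc = 1, wFbMc = 1,
                      feedbackOn = TRUE)
  expect_equal(mcNullcline(pf, 0), 4.5)
  # GC nullcline rectifies at low MC drive
  p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
  expect_equal(gcNullcline(p, 0), 0)
  expect_equal(gcNullcline(p, 9.449541), 0.3 * 9.449541 - 1,
               tolerance = 1e-9)
  expect_equal(gcNullcline(networkParams(I = 10, wMcGc = 1, wSacGc = 1), 3),
               2)
  # degenerate vertical nullcline
  expect_error(mcNullcline(networkParams(wMcGc = 0), 1), "degenerate")
})

test_that("solveFixedPoint matches the closed form on both branches", {
  fp0 <- solveFixedPoint(networkParams(I = 5, wMcGc = 0, wSacGc = 0))
  expect_equal(mcRate(fp0), 5)
  expect_equal(gcRate(fp0), 0)
  expect_true(isRectified(fp0))

  fp <- solveFixedPoint(networkParams(I = 10, wMcGc = 0.3, wSacGc = 1))
  expect_equal(mcRate(fp), 9.449541, tolerance = 1e-6)
  expect_equal(gcRate(fp), 1.834862, tolerance = 1e-6)
  expect_false(isRectified(fp))

  fpf <- solveFixedPoint(networkParams(I = 10, wMcGc = 0.3, wSacGc = 1,
                                       wFbMc = 1, feedbackOn = TRUE))
  expect_equal(mcRate(fpf), 8.834862, tolerance = 1e-6)
  expect_equal(gcRate(fpf), 0.550459, tolerance = 1e-6)
})

test_that("fixed points lie on both nullclines", {
  set.seed(7)
  for (i in 1:25) {
    fb <- i %% 2 == 0
    p <- networkParams(I = runif(1, 2, 20), wMcGc = runif(1, 0.1, 3),
                       wSacGc = runif(1, 0, 2),
                       wFbMc = if (fb) runif(1, 0.1, 2) else 0,
                       feedbackOn = fb)
    fp <- solveFixedPoint(p)
    expect_lt(abs(mcNullcline(p, mcRate(fp)) - gcRate(fp)), 1e-9)
    expect_lt(abs(gcNullcline(p, mcRate(fp)) - gcRate(fp)), 1e-9)
  }
})

test_that("feedback produces joint inhibition with the hand-derived magnitudes", {
  p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
  expect_equal(feedbackDelta(p, 0), c(deltaMc = 0, deltaGc = 0))
  d <- feedbackDelta(p, 1)
  expect_equal(unname(d["deltaMc"]), -0.6146789, tolerance = 1e-6)
  expect_equal(unname(d["deltaGc"]), -1.2844037, tolerance = 1e-6)
  expect_true(all(d < 0))
  expect_error(feedbackDelta(p, -1), "invalid")
  expect_error(
    feedbackDelta(networkParams(wFbMc = 1, feedbackOn = TRUE), 1),
    "feedbackOn")
})

test_that("stronger feedback inhibits more until the GC rate floors", {
  p <- networkParams(I = 10, wMcGc = 0.3, wSacGc = 1)
  base <- solveFixedPoint(p)
  ds <- sapply(c(0.5, 1, 1.5, 2), function(w) feedbackDelta(p, w))
  expect_true(all(diff(abs(ds["deltaMc", ])) > 0))
  rect <- sapply(c(0.5, 1, 1.5, 2), function(w)
    isRectified(solveFixedPoint(networkParams(I = 10, wMcGc = 0.3,
                                              wSacGc = 1, wFbMc = w,
                                              feedbackOn = TRUE))))
  # while the GC fixed point stays positive, GC inhibition deepens strictly;
  # once rectified, GC is fully silenced and the delta saturates at -baseline
  unrect <- which(!rect)
  expect_true(all(diff(abs(ds["deltaGc", unrect])) > 0))
  expect_equal(unname(ds["deltaGc", rect]),
               rep(-gcRate(base), sum(rect)), tolerance = 1e-12)
})

test_that("feedback deltas are continuous in the stimulation strength", {
  # halving the grid step roughly halves the largest jump (no jumps in w)
  p <- networkParams(I = 10, wMcGc = 0.8, wSacGc = 1)
  maxJump <- function(h) {
    ds <- sapply(seq(0.2, 2, by = h), function(w) feedbackDelta(p, w))
    max(abs(diff(ds["deltaMc", ])), abs(diff(ds["deltaGc", ])))
  }
  expect_lt(maxJump(0.025), 0.6 * maxJump(0.05) + 1e-9)
  expect_lt(maxJump(0.0125), 0.6 * maxJump(0.025) + 1e-9)
})

test_that("fixed points respond affinely to the odor drive when unrectified", {
  mk <- function(I) solveFixedPoint(networkParams(I = I, wMcGc = 0.5,
                                                  wSacGc = 1))
  f1 <- mk(10); f2 <- mk(20); f3 <- mk(30)
  expect_equal(mcRate(f3) - mcRate(f2), mcRate(f2) - mcRate(f1),
               tolerance = 1e-12)
  expect_equal(gcRate(f3) - gcRate(f2), gcRate(f2) - gcRate(f1),
               tolerance = 1e-12)
})

test_that("parameter sweeps are consistent with single-point solutions", {
  sw <- sweepParameterGrid(I = 10, wSacGc = 1, wMcGcAxis = 0.3,
                           wFbAxis = 1)
  d <- feedbackDelta(networkParams(I = 10, wMcGc = 0.3, wSacGc = 1), 1)
  expect_equal(sw@deltaMc[1, 1], unname(d["deltaMc"]))
  expect_equal(sw@deltaGc[1, 1], unname(d["deltaGc"]))

  sw2 <- sweepParameterGrid(I = 10, wSacGc = 1,
                            wMcGcAxis = seq(0.2, 1, by = 0.2),
                            wFbAxis = c(0, 0.5, 1))
  # no feedback, no change
  expect_true(all(sw2@deltaMc[, 1] == 0) && all(sw2@deltaGc[, 1] == 0))
  # baselines do not depend on the feedback axis
  expect_true(all(sw2@baselineMc == sw2@baselineMc[, 1]))
  # where the baseline GC already rectifies to 0, feedback cannot lower it
  sw3 <- sweepParameterGrid(I = 10, wSacGc = 12,
                            wMcGcAxis = c(0.05, 0.1), wFbAxis = c(0.5, 1))
  expect_true(all(sw3@baselineGc == 0))
  expect_true(all(sw3@deltaGc == 0))
  expect_error(sweepParameterGrid(wMcGcAxis = c(2, 1), wFbAxis = 1),
               "increasing")
})

test_that("the linear branch is always a stable focus", {
  for (w in c(0, 0.3, 1, 5)) {
    ev <- jacobianEigenvalues(networkParams(wMcGc = w))
    expect_equal(Re(ev), c(-1, -1))
  }
})
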