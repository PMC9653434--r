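# Trace extraction, smoothing, dF/F, z-scores and response classification.

test_that("trace extraction averages the mask pixels", {
  fr <- array(7, c(3, 8, 8))
  mask <- matrix(0L, 8, 8); mask[2:4, 2:4] <- 1L
  ts <- extractTraces(calciumMovie(fr, 15), roiSet(mask))
  expect_equal(unname(traceMatrix(ts)), matrix(7, 1, 3))

  set.seed(1)
  fr2 <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  m2 <- matrix(0L, 8, 8); m2[3, 4] <- 1L
  ts2 <- extractTraces(calciumMovie(fr2, 15), roiSet(m2))
  expect_equal(unname(traceMatrix(ts2)[1, ]), fr2[, 3, 4])
})

test_that("not-kept frames are filled by linear interpolation", {
  fr <- array(0, c(5, 4, 4))
  for (i in 1:5) fr[i, , ] <- i * 10
  mask <- matrix(1L, 4, 4)
  mv <- calciumMovie(fr, 15, keptFrames = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  fr[3, , ] <- 999   # corrupted frame value must not leak into the trace
  mv@frames <- fr
  expect_message(ts <- extractTraces(mv, roiSet(mask)), "interpolated")
  expect_equal(unname(traceMatrix(ts)[1, ]), c(10, 20, 30, 40, 50))
})

test_that("extracted traces follow the generated cells' fluorescence", {
  gm <- compactMovie(movieTruthParams(nCells = 20))
  ts <- extractTraces(gm$movie, gm$rois)
  cc <- sapply(seq_len(20), function(j)
    cor(traceMatrix(ts)[j, ], gm$truth$fluor[, j]))
  expect_true(all(cc >= 0.8))
})

test_that("moving-average smoothing behaves as a box filter", {
  x <- c(0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0)
  ts <- traceSet(rbind(x), 15)
  sm <- smoothTraces(ts, 5)
  expect_equal(unname(traceMatrix(sm)[1, 4:8]), rep(1, 5))
  expect_equal(traceMatrix(smoothTraces(ts, 1)), traceMatrix(ts))
  const <- traceSet(rbind(rep(3, 10)), 15)
  expect_equal(unname(traceMatrix(smoothTraces(const, 5))[1, ]), rep(3, 10))
  expect_error(smoothTraces(ts, 4), "odd")
  expect_error(smoothTraces(ts, 13), "window")
})

test_that("dF/F normalization is exact and scale-invariant", {
  expect_equal(computeDff(rep(4, 10), 1:5), rep(0, 10))
  expect_equal(computeDff(c(10, 10, 12), 1:2)[3], 0.2)
  tr <- c(8, 10, 12, 9, 11)
  expect_equal(computeDff(2 * tr, 1:2), computeDff(tr, 1:2))
  expect_error(computeDff(c(-1, -1, 5), 1:2), "baseline error")
  expect_error(computeDff(1:5, 4:7), "inside")
})

test_that("the z statistic reproduces the hand-worked example", {
  zs <- computeZScore(c(2, 3, 2, 3), c(1, 1, 1, 1))
  # mu_resp 2.5, sample var 1/3, radicand (1/3)/4 = 1/12, z = 1.5*sqrt(12)
  expect_equal(zs@z, 1.5 * sqrt(12), tolerance = 1e-12)
  expect_equal(zs@z, 5.196, tolerance = 1e-4)
  expect_equal(zs@muResp, 2.5)
  expect_equal(zs@sigmaResp, sqrt(1 / 3))
  expect_equal(zs@n, 4L)
})

test_that("the z statistic is affine-invariant and handles degeneracy", {
  set.seed(5)
  r <- rnorm(8, 2); b <- rnorm(8)
  z0 <- computeZScore(r, b)@z
  expect_equal(computeZScore(3 * r + 7, 3 * b + 7)@z, z0)
  # identical windows: zero by convention
  expect_equal(computeZScore(b, b)@z, 0)
  # baseline more variable than response: printed form undefined, fallback kept
  zs <- computeZScore(rep(2, 4) + 0.01 * rnorm(4), c(0, 4, 0, 4))
  expect_true(is.nan(zs@z))
  expect_true(is.finite(zs@zFallback))
  expect_error(computeZScore(1:3, 1:4), "pairing")
  expect_error(computeZScore(1, 1), "2 trials")
})

test_that("paired-test classification matches a direct t computation", {
  r <- c(1, 1, 1, 1, 1, 1); b <- r
  out <- classifyResponse(r, b, alpha = 0.01)
  expect_equal(out$label, "nonresponsive")
  expect_equal(out$pValue, 1)

  d <- c(-1.1, -0.9, -1.0, -1.0, -1.05, -0.95)
  out2 <- classifyResponse(d, rep(0, 6), alpha = 0.01)
  # independent oracle: p from the t statistic computed by hand
  tstat <- mean(d) / (sd(d) / sqrt(6))
  pOracle <- 2 * pt(-abs(tstat), df = 5)
  expect_equal(out2$pValue, pOracle, tolerance = 1e-12)
  expect_equal(out2$label, "inhibited")

  expect_message(out3 <- classifyResponse(c(2, 2, 2), c(1, 1, 1), 0.01),
                 "zero-variance")
  expect_equal(out3$pValue, 0)
  expect_equal(out3$label, "excited")
})

test_that("classification labels never contradict the mean-difference sign", {
  set.seed(6)
  for (i in 1:50) {
    r <- rnorm(10, sample(c(-1, 0, 1), 1)); b <- rnorm(10)
    out <- classifyResponse(r, b, alpha = 0.05)
    if (out$label == "excited") expect_gt(mean(r - b), 0)
    if (out$label == "inhibited") expect_lt(mean(r - b), 0)
  }
})

test_that("false-positive rate on null cells sits at the nominal level", {
  g <- generateTraceSet(1000, nTrials = 20, effects = 0, seed = 8)
  labs <- vapply(seq_len(1000), function(i)
    classifyResponse(g$resp[i, ], g$base[i, ], alpha = 0.01)$label,
    character(1))
  frac <- mean(labs != "nonresponsive")
  # exact binomial 99% band: robust against the Monte-Carlo wobble of a
  # fixed-seed draw while still pinning the calibration at the alpha level
  ci <- qbinom(c(0.005, 0.995), 1000, 0.01) / 1000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("trial window means pick the stated 1-s windows", {
  # 10 Hz, 30 s: trace value equals the frame index so window means are
  # predictable exactly
  n <- 300
  ts <- traceSet(rbind(seq_len(n)), 10)
  tt <- trialTable(data.frame(onset_s = 10, stimulus = "light", block = 1,
                              shutter_close_s = 9.95,
                              shutter_open_s = 12.05))
  wm <- trialWindowMeans(ts, tt)
  # baseline frames centered in [8.95, 9.95): indices 90..99
  expect_equal(wm$base[1, 1], mean(90:99))
  # response frames centered in [12.05, 13.05): indices 121..130
  expect_equal(wm$resp[1, 1], mean(121:130))
})

test_that("responseStats aggregates z, p and labels per cell", {
  gm <- compactMovie(movieTruthParams(nCells = 12, fracExcited = 0.5,
                                      fracInhibited = 0.5, stimRate = 3,
                                      tonicRate = 1))
  ts <- smoothTraces(extractTraces(gm$movie, gm$rois), 5)
  tt <- generateProtocol(compactTwophotonSpec(), 1, seed = 2)
  rs <- responseStats(ts, tt, stimulus = c("odor_a", "odor_b"),
                      alpha = 0.05)
  expect_equal(nrow(rs), 12)
  expect_true(all(rs$label %in% c("excited", "inhibited", "nonresponsive")))
  expect_error(responseStats(ts, tt, stimulus = "nope"), "no trials")
})
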