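# Frame QC, motion correction, PCA reconstruction and ROI refinement.

texturedFrames <- function(n, h = 16, w = 16, seed = 1) {
  set.seed(seed)
  base <- matrix(runif(h * w), h, w)
  frames <- array(0, c(n, h, w))
  for (i in seq_len(n)) frames[i, , ] <- base
  frames
}

test_that("identical textured frames are all kept; an unattainable threshold flags all", {
  mv <- calciumMovie(texturedFrames(6), frameRate = 15)
  expect_true(all(keptFrames(flagZFrames(mv))))
  set.seed(2)
  noisy <- calciumMovie(array(rnorm(6 * 16 * 16), c(6, 16, 16)), 15)
  expect_true(all(!keptFrames(flagZFrames(noisy, rThreshold = 1.0))))
})

test_that("injected out-of-plane frames are identified exactly", {
  gm <- compactMovie(movieTruthParams(nCells = 20, zFrames = 10:12))
  flagged <- suppressMessages(flagZFrames(gm$movie))
  expect_identical(which(!keptFrames(flagged)), 10:12)
  # brute-force oracle: direct correlation with the average projection
  avg <- apply(movieFrames(gm$movie), c(2, 3), mean)
  r <- sapply(seq_len(nFrames(gm$movie)), function(i)
    cor(as.vector(movieFrames(gm$movie)[i, , ]), as.vector(avg)))
  expect_identical(which(r <= 0.65), 10:12)
})

test_that("frame flagging is permutation-covariant", {
  gm <- compactMovie(movieTruthParams(nCells = 15, zFrames = c(5, 40)),
                     seed = 9)
  mv <- gm$movie
  set.seed(3)
  perm <- sample(nFrames(mv))
  mvp <- calciumMovie(movieFrames(mv)[perm, , ], 15)
  k1 <- keptFrames(suppressMessages(flagZFrames(mv)))
  k2 <- keptFrames(suppressMessages(flagZFrames(mvp)))
  expect_identical(k2, k1[perm])
})

test_that("zero-variance frames are flagged with a message", {
  fr <- texturedFrames(4)
  fr[2, , ] <- 7
  expect_message(out <- flagZFrames(calciumMovie(fr, 15)),
                 "zero variance")
  expect_false(keptFrames(out)[2])
})

test_that("an aligned movie registers with near-zero shifts", {
  gm <- compactMovie(movieTruthParams(nCells = 20))
  reg <- correctLateralMotion(gm$movie)
  expect_lt(max(abs(reg$shifts)), 0.5)
  expect_equal(movieFrames(reg$movie), movieFrames(gm$movie))
})

test_that("injected drift on half the frames is recovered within half a pixel", {
  set.seed(11)
  n <- 570
  half <- sample(n, n %/% 2)
  gm <- compactMovie(movieTruthParams(nCells = 20, driftFrames = half,
                                      driftShift = c(3, -2)), seed = 4)
  reg <- suppressMessages(correctLateralMotion(gm$movie))
  # recovery is defined up to the common reference offset
  ref <- colMeans(reg$shifts[-half, , drop = FALSE])
  rel <- sweep(reg$shifts[half, , drop = FALSE], 2, ref)
  expect_lt(max(abs(sweep(rel, 2, c(3, -2)))), 0.5)
  expect_lt(max(abs(sweep(reg$shifts[-half, , drop = FALSE], 2, ref))), 0.5)
})

test_that("single-frame movies register to themselves", {
  mv <- calciumMovie(texturedFrames(1), 15)
  reg <- correctLateralMotion(mv)
  expect_equal(unname(reg$shifts[1, ]), c(0, 0))
  expect_equal(movieFrames(reg$movie), movieFrames(mv))
})

test_that("excessive shifts flag the frame instead of shifting it", {
  gm <- compactMovie(movieTruthParams(nCells = 20,
                                      driftFrames = 50,
                                      driftShift = c(40, 0)), seed = 5)
  expect_message(reg <- correctLateralMotion(gm$movie), "exceeds guard")
  expect_false(keptFrames(reg$movie)[50])
})

test_that("PCA reconstruction recovers movies of rank at most the component count", {
  set.seed(4)
  h <- 12; w <- 12; n <- 40
  # rank-1: one spatial map times one time course plus a constant offset
  map <- matrix(runif(h * w), h, w)
  tc <- sin(seq_len(n) / 3) + 2
  fr <- array(outer(tc, as.vector(map)), c(n, h, w)) + 5
  rec1 <- pcaReconstruct(calciumMovie(fr, 15), nComponents = 1)
  expect_equal(movieFrames(rec1), fr, tolerance = 1e-8)
  # rank-5 with 10 components: exact
  fr5 <- array(0, c(n, h, w))
  flat <- matrix(0, n, h * w)
  for (k in 1:5)
    flat <- flat + outer(rnorm(n), as.vector(matrix(runif(h * w), h, w)))
  fr5 <- array(flat, c(n, h, w)) + 3
  rec5 <- pcaReconstruct(calciumMovie(fr5, 15), nComponents = 10)
  expect_equal(movieFrames(rec5), fr5, tolerance = 1e-8)
})

test_that("PCA reconstruction denoises a 10-cell movie and is idempotent", {
  params <- movieTruthParams(nCells = 10)
  gm <- compactMovie(params, seed = 6)
  clean <- compactMovie(modifyList(params, list(noiseSigma = 0)), seed = 6)
  rec <- pcaReconstruct(gm$movie, 10)
  errRaw <- mean((movieFrames(gm$movie) - movieFrames(clean$movie))^2)
  errRec <- mean((movieFrames(rec) - movieFrames(clean$movie))^2)
  expect_lt(errRec, errRaw)
  # the residual carries most of the noise energy, bounded by it
  expect_lt(mean((movieFrames(rec) - movieFrames(gm$movie))^2), errRaw)
  rec2 <- pcaReconstruct(rec, 10)
  expect_equal(movieFrames(rec2), movieFrames(rec), tolerance = 1e-8)
})

test_that("PCA reconstruction validates its component count", {
  mv <- calciumMovie(texturedFrames(5), 15)
  expect_error(pcaReconstruct(mv, 0), "invalid parameter")
  expect_error(pcaReconstruct(mv, 5), "invalid parameter")
})

test_that("ROI refinement trims rim pixels but keeps coherent cells intact", {
  # one strongly active cell; ROI drawn 2 px too wide around it
  params <- movieTruthParams(nCells = 1, fracExcited = 1, fracInhibited = 0,
                             stimRate = 3, spontRate = 0.2)
  gm <- compactMovie(params, seed = 12)
  truthMask <- roiMasks(gm$rois)
  cellPx <- which(truthMask == 1)
  # dilate by ~2 px around the cell center
  pos <- gm$truth$positions[1, ]; rad <- gm$truth$radii[1]
  h <- nrow(truthMask); w <- ncol(truthMask)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # widen past the cell's full footprint (3 sigma) so the rim is signal-free
  d2 <- (yy - pos[1])^2 + (xx - pos[2])^2
  wide <- matrix(0L, h, w); wide[d2 <= (3 * rad + 2)^2] <- 1L
  rimPx <- which(wide == 1 & d2 > (3 * rad)^2)
  refined <- refineRois(gm$movie, roiSet(wide))
  keptPx <- which(roiMasks(refined) == 1)
  expect_gte(mean(!(rimPx %in% keptPx)), 0.8)
  expect_identical(roiProvenance(refined), "refined")

  # tight ROI over the same coherent cell stays (nearly) unchanged
  tight <- refineRois(gm$movie, roiSet(truthMask))
  expect_gte(mean(cellPx %in% which(roiMasks(tight) == 1)), 0.9)
})

test_that("ROI refinement keeps the mask when there is no coherent signal", {
  set.seed(13)
  fr <- array(rnorm(200 * 20 * 20), c(200, 20, 20))
  mask <- matrix(0L, 20, 20); mask[5:10, 5:10] <- 1L
  expect_warning(out <- refineRois(calciumMovie(fr, 15), roiSet(mask)),
                 "mask kept")
  expect_identical(roiMasks(out), mask)
  expect_identical(roiProvenance(out), "manual")
})

test_that("ROI refinement requires more pixels than components", {
  fr <- texturedFrames(10)
  mask <- matrix(0L, 16, 16); mask[1, 1:3] <- 1L
  expect_error(refineRois(calciumMovie(fr, 15), roiSet(mask)),
               "need more than")
})
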