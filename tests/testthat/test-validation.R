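sceneTracks <- function(n = 6L, d = 2, nCells = 15L, walkSd = 0) {
  # straight-line ground truth matching constantFlowTset, plus an
  # optional random walk emulating uncoordinated cell motion
  set.seed(20)
  p0 <- cbind(runif(nCells, 10, 30), runif(nCells, 6, 18),
              runif(nCells, 6, 18))
  walk <- matrix(0, nCells, 3)
  out <- list()
  for (f in seq_len(n)) {
    if (f > 1L && walkSd > 0)
      walk <- walk + matrix(rnorm(nCells * 3, 0, walkSd), nCells)
    pos <- p0 + walk
    pos[, 1] <- pos[, 1] + d * (f - 1)
    out[[f]] <- data.frame(cell = seq_len(nCells), frame = f,
                           x = pos[, 1], y = pos[, 2], z = pos[, 3],
                           dividing = FALSE)
  }
  do.call(rbind, out)
}

test_that("stepwise error vanishes for a perfect transform set", {
  n <- 6L
  tracks <- sceneTracks(n, d = 2)
  tset <- constantFlowTset(n, d = 2)
  rep_ <- stepwiseError(tracks, tset)
  expect_lt(rep_$overall$mean, 1e-6)
  # identity transforms on moving cells: error equals the step size
  id <- identityTset(n, dim = c(48L, 24L, 24L))
  repId <- stepwiseError(tracks, id)
  expect_equal(repId$overall$mean, 2, tolerance = 1e-9)
})

test_that("dividing cells are excluded from the error sets", {
  tracks <- sceneTracks(4, d = 2)
  tracks$dividing[tracks$cell == 1] <- TRUE
  rep_ <- stepwiseError(tracks, constantFlowTset(4, d = 2))
  expect_false(1 %in% rep_$perPoint$cell)
})

test_that("accumulated error is zero at the anchor and grows with noise", {
  n <- 7L
  tracks <- sceneTracks(n, d = 2)
  tset <- constantFlowTset(n, d = 2)
  rep_ <- accumulatedError(tracks, tset, timeStep = 10)
  expect_lt(max(rep_$perFrame$mean), 1e-6)
  # noisy fields: error accumulates monotonically outward (trend check)
  set.seed(21)
  noisy <- tset
  for (i in seq_along(noisy@forward)) {
    f <- noisy@forward[[i]]
    noisy@forward[[i]] <- initialize(f, ctrl = f@ctrl +
      matrix(rnorm(length(f@ctrl), 0, 0.3), nrow(f@ctrl)))
  }
  for (i in seq_along(noisy@backward)) {
    f <- noisy@backward[[i]]
    noisy@backward[[i]] <- initialize(f, ctrl = f@ctrl +
      matrix(rnorm(length(f@ctrl), 0, 0.3), nrow(f@ctrl)))
  }
  repN <- accumulatedError(tracks, noisy, timeStep = 10)
  med <- repN$perFrame
  med$off <- abs(med$frame - repN$anchor)
  fit <- lm(median ~ off, data = med)
  expect_gt(coef(fit)[2], 0)
  expect_gt(repN$slope, 0)
})

test_that("bidirectional anchoring bounds the unidirectional error", {
  n <- 7L
  tracks <- sceneTracks(n, d = 2)
  mkNoisy <- function(tset) {
    set.seed(22)
    for (i in seq_along(tset@forward))
      tset@forward[[i]] <- initialize(tset@forward[[i]],
        ctrl = tset@forward[[i]]@ctrl +
          matrix(rnorm(length(tset@forward[[i]]@ctrl), 0, 0.3),
                 nrow(tset@forward[[i]]@ctrl)))
    for (i in seq_along(tset@backward))
      tset@backward[[i]] <- initialize(tset@backward[[i]],
        ctrl = tset@backward[[i]]@ctrl +
          matrix(rnorm(length(tset@backward[[i]]@ctrl), 0, 0.3),
                 nrow(tset@backward[[i]]@ctrl)))
    tset
  }
  bid <- mkNoisy(constantFlowTset(n, d = 2))
  uniFields <- constantFlowTset(n, d = 2)
  # unidirectional: anchor at frame 1, all forward
  spacing <- uniFields@forward[[1]]@spacing
  uni <- new("TransformSet",
             forward = c(lapply(1:(uniFields@anchor - 1), function(i)
               initialize(uniFields@backward[[uniFields@anchor - i]],
                          ctrl = -uniFields@backward[[uniFields@anchor - i]]@ctrl,
                          direction = c(i, i + 1L))),
               uniFields@forward),
             backward = list(), anchor = 1L, nFrames = uniFields@nFrames)
  uni <- mkNoisy(uni)
  repB <- accumulatedError(tracks, bid, 10)
  repU <- accumulatedError(tracks, uni, 10)
  expect_lte(max(repB$perFrame$mean), max(repU$perFrame$mean) + 1e-9)
})

test_that("misregistration rate counts threshold exceedances", {
  rep_ <- list(perPoint = data.frame(cell = 1:2, frame = 2,
                                     error = c(10, 30)))
  class(rep_) <- "errorReport"
  expect_equal(misregistrationRate(rep_, 20), 0.5)
  expect_equal(misregistrationRate(rep_, 5), 1)
  expect_equal(misregistrationRate(rep_, 50), 0)
  # monotone non-increasing in the threshold
  set.seed(23)
  rep2 <- list(perPoint = data.frame(cell = 1, frame = 1,
                                     error = runif(100, 0, 40)))
  class(rep2) <- "errorReport"
  rates <- vapply(c(5, 10, 20, 40), function(d)
    misregistrationRate(rep2, d), 1)
  expect_true(all(diff(rates) <= 0))
  empty <- list(perPoint = data.frame())
  class(empty) <- "errorReport"
  expect_error(misregistrationRate(empty), "empty")
})

test_that("mixing tissue accumulates error faster than coherent flow", {
  n <- 8L
  # coherent tissue: mild uncorrelated wander around the mean flow;
  # mixing tissue: strong random walks the field cannot follow
  coherent <- sceneTracks(n, d = 2, walkSd = 0.25)
  mixing <- sceneTracks(n, d = 2, walkSd = 2)
  tset <- constantFlowTset(n, d = 2)
  mc <- mixingControl(coherent, mixing, tset, tset, timeStep = 20,
                      binMinutes = 20)
  expect_gt(mc$ratio, 2)
  expect_gt(mc$normalizedMixing, mc$normalizedCoherent)
  # identical regimes give a ratio near 1
  mc0 <- mixingControl(mixing, mixing, tset, tset, timeStep = 20)
  expect_equal(mc0$ratio, 1, tolerance = 1e-9)
  short <- sceneTracks(2L, d = 2)
  expect_error(mixingControl(short, short, constantFlowTset(2),
                             constantFlowTset(2), 20), "span too short")
})

test_that("the resolution sweep reports one row per fraction", {
  p <- sceneParams(nFrames = 2L, volumeDim = c(48L, 48L, 48L),
                   radius0 = 10, radius1 = 10.5, length0 = 28,
                   length1 = 30, noiseSigma = 0.01)
  sc <- makeScene(p, seed = 8)
  r <- renderStack(sc)
  stk <- preprocessHyperstack(r$stack, 0.5)
  tab <- suppressWarnings(
    resolutionSweep(stk, r$tracks, fractions = c(0.25, 0.5),
                    params = regParams(levels = 2)))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("fraction", "gridVoxels", "meanStepwise",
                    "wallTime") %in% names(tab)))
  expect_true(all(tab$meanStepwise >= 0))
})
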