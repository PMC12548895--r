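# registration unit tests run on small volumes so the whole file stays
# within a couple of minutes; the full-scene checks live in the
# acceptance suite

test_that("zero-displacement fields are the exact identity map", {
  tset <- identityTset(5)
  set.seed(1)
  pts <- cbind(runif(20, 1, 22), runif(20, 1, 22), runif(20, 1, 22))
  for (b in c(1L, 5L)) {
    out <- propagatePoints(pts, tset, tset@anchor, b)
    expect_equal(out[, 1:3], pts, tolerance = 1e-14)
    expect_false(any(attr(out, "outOfDomain")))
  }
  expect_equal(propagatePoints(pts, tset, 3, 3)[, 1:3], pts)
})

test_that("registering a frame to itself yields a near-zero field", {
  v <- blobVolume(24, rbind(c(9, 12, 12), c(16, 10, 13)))
  fit <- registerPair(v, v, regParams(gridSpacing = 6), c(1, 1, 1))
  expect_lt(max(abs(fit$field@ctrl)), 0.1)
})

test_that("a constructed translation is recovered within half a voxel", {
  v <- blobVolume(32, rbind(c(12, 16, 16), c(20, 13, 18), c(16, 20, 12)))
  moved <- morphomap:::shiftArray3(v, c(3, 0, 0))
  fit <- registerPair(v, moved, regParams(gridSpacing = 6), c(1, 1, 1))
  fg <- which(v > 0.25)
  g <- arrayInd(fg, dim(v)) - 1L
  out <- transformPoints(fit$field, g, units = "voxel")
  disp <- colMeans(out[, 1:3] - g)
  expect_lt(max(abs(disp - c(3, 0, 0))), 0.5)
  # non-increasing target: final target below the identity-transform target
  d <- dim(v)
  ncd <- fit$field@lattice
  t0 <- morphomap:::cpp_ffd_cost_grad(as.numeric(v), as.numeric(moved),
                                      d, matrix(0, prod(ncd), 3), ncd,
                                      fit$field@spacing, 0.01, FALSE)$cost
  expect_lt(fit$target, t0)
})

test_that("a known smooth warp is recovered on the foreground", {
  # warp a blob volume by a smooth analytic displacement (max ~2.5 voxels)
  n <- 32L
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  ux <- 2.5 * sin(pi * g$y / n)
  centres <- rbind(c(12, 16, 16), c(20, 12, 18), c(14, 22, 14))
  mkvol <- function(xs) {
    v <- 0
    for (k in seq_len(nrow(centres)))
      v <- v + exp(-((xs - centres[k, 1])^2 + (g$y - centres[k, 2])^2 +
                       (g$z - centres[k, 3])^2) / 18)
    array(v, c(n, n, n))
  }
  ref <- mkvol(g$x)
  mov <- mkvol(g$x - ux)   # pattern displaced by +ux
  fit <- registerPair(ref, mov, regParams(gridSpacing = 5), c(1, 1, 1))
  fg <- which(ref > 0.25)
  pts <- as.matrix(g[fg, ])
  out <- transformPoints(fit$field, pts, units = "voxel")
  err <- sqrt(rowSums((out[, 1:3] - cbind(pts[, 1] + ux[fg], pts[, 2],
                                          pts[, 3]))^2))
  expect_lt(mean(err), 1)
})

test_that("register errors on mismatched or non-finite input", {
  v <- blobVolume(16, matrix(c(8, 8, 8), 1))
  expect_error(registerPair(v, v[1:8, , ], regParams()), "share shape")
  bad <- v; bad[1] <- NA
  expect_error(registerPair(v, bad, regParams()), "non-finite")
})

test_that("sequence registration anchors at the midpoint", {
  arr <- array(rep(blobVolume(16, matrix(c(8, 8, 8), 1)), 2),
               c(16, 16, 16, 1, 2))
  hs <- hyperstack(arr, c(1, 1, 1))
  ts <- registerSequence(hs, regParams(gridSpacing = 6, levels = 2))
  expect_equal(ts@anchor, 2L)         # floor(2/2) + 1
  expect_length(ts@backward, 1)
  expect_length(ts@forward, 0)
  arr6 <- array(rep(blobVolume(16, matrix(c(8, 8, 8), 1)), 6),
                c(16, 16, 16, 1, 6))
  ts6 <- registerSequence(hyperstack(arr6, c(1, 1, 1)),
                          regParams(gridSpacing = 6, levels = 2))
  expect_equal(ts6@anchor, 4L)
  expect_length(ts6@forward, 2)
  expect_length(ts6@backward, 3)
  # static stack: all fields near identity
  for (f in c(ts6@forward, ts6@backward))
    expect_lt(max(abs(f@ctrl)), 0.1)
  expect_error(registerSequence(hyperstack(arr6[, , , , 1, drop = FALSE],
                                           c(1, 1, 1))), "2 frames")
})

test_that("propagation chains use the anchor-outward fields only", {
  tset <- constantFlowTset(7, d = 2)
  a <- tset@anchor
  pts <- cbind(20, 12, 12)
  out <- propagatePoints(pts, tset, a, 7)
  expect_equal(out[1, 1], 20 + 2 * (7 - a), tolerance = 1e-9)
  out2 <- propagatePoints(pts, tset, a, 1)
  expect_equal(out2[1, 1], 20 - 2 * (a - 1), tolerance = 1e-9)
  expect_error(propagatePoints(pts, tset, 1, 7), "anchor")
  # out-of-domain points are clamped and flagged
  far <- cbind(470, 12, 12)
  outF <- propagatePoints(far, tset, a, a + 1L)
  expect_true(attr(outF, "outOfDomain"))
})

test_that("constant flow accumulates the analytic displacement", {
  tset <- constantFlowTset(6, d = 2)
  a <- tset@anchor
  set.seed(2)
  pts <- cbind(runif(10, 8, 24), runif(10, 6, 18), runif(10, 6, 18))
  out <- propagatePoints(pts, tset, a, 6)
  expect_equal(out[, 1], pts[, 1] + 2 * (6 - a), tolerance = 0.5)
  expect_equal(out[, 2:3], pts[, 2:3], tolerance = 0.5)
})

test_that("mask warping: identity, translation, dilation volumes", {
  m <- ballMask(30L, 8)
  d <- dim(m@voxels)
  spacing <- 6
  ncd <- as.integer(floor((d - 1) / spacing) + 4L)
  idf <- new("TransformField", ctrl = matrix(0, prod(ncd), 3),
             lattice = ncd, spacing = spacing, domain = d,
             direction = c(1L, 2L), voxelSize = c(1, 1, 1))
  expect_identical(applyTransformToMask(m, idf)@voxels, m@voxels)
  # pure translation: mask moves with the field, volume preserved
  trf <- initialize(idf, ctrl = cbind(rep(3, prod(ncd)), 0, 0))
  wt <- applyTransformToMask(m, trf)
  expect_lt(abs(sum(wt@voxels) / sum(m@voxels) - 1), 0.05)
  c0 <- colMeans(arrayInd(which(m@voxels), d))
  c1 <- colMeans(arrayInd(which(wt@voxels), d))
  expect_equal(c1 - c0, c(3, 0, 0), tolerance = 0.2)
  # uniform 10% dilation about the centre: volume ratio ~ 1.1^3
  g <- as.matrix(expand.grid(x = seq_len(ncd[1]) - 2L,
                             y = seq_len(ncd[2]) - 2L,
                             z = seq_len(ncd[3]) - 2L)) * spacing
  ctr <- (d - 1) / 2
  dil <- initialize(idf, ctrl = 0.1 * sweep(g, 2, ctr))
  wd <- applyTransformToMask(m, dil)
  # volume ratio ~ 1.1^3 within 10% (digitisation shifts the boundary)
  expect_lt(abs(sum(wd@voxels) / sum(m@voxels) / 1.1^3 - 1), 0.10)
  expect_error(applyTransformToMask(ballMask(20L, 5), idf), "domain")
})

test_that("downscaling keeps the physical grid spacing near 10 um", {
  arr <- array(runif(40 * 40 * 40 * 2), c(40, 40, 40, 1, 2))
  hs <- hyperstack(arr, c(0.593, 0.593, 0.593))
  for (spec in list(c(0.10, 2), c(0.15, 3), c(0.20, 3), c(0.25, 4))) {
    ds <- downscaleForRegistration(hs, spec[1])
    expect_equal(ds$gridVoxels, as.integer(spec[2]))
    expect_equal(dim(ds$stack@data)[1], max(4, round(40 * spec[1])))
  }
  ds25 <- downscaleForRegistration(hs, 0.25)
  expect_equal(mean(ds25$stack@voxelSize), 2.37, tolerance = 0.01)
  expect_warning(dsw <- downscaleForRegistration(hs, 1.0), "unsupported")
  expect_equal(dsw$gridVoxels, round(10 / 0.593 / 1))
})

test_that("transform-set archives round trip bit-exactly", {
  tset <- constantFlowTset(5, d = 1.5)
  path <- tempfile(fileext = ".mmr")
  writeTransformSet(tset, path)
  back <- readTransformSet(path)
  expect_equal(back@anchor, tset@anchor)
  expect_equal(back@nFrames, tset@nFrames)
  expect_identical(back@forward[[1]]@ctrl, tset@forward[[1]]@ctrl)
  expect_identical(back@backward[[2]]@domain, tset@backward[[2]]@domain)
  pts <- cbind(20, 10, 10)
  expect_identical(propagatePoints(pts, back, back@anchor, 5),
                   propagatePoints(pts, tset, tset@anchor, 5))
})

test_that("forward-backward propagation over a registered pair closes", {
  v <- blobVolume(28, rbind(c(10, 14, 14), c(18, 12, 16)))
  g <- expand.grid(x = 0:27, y = 0:27, z = 0:27)
  ux <- 1.5 * sin(pi * g$y / 28)
  centres <- rbind(c(10, 14, 14), c(18, 12, 16))
  mk <- function(xs) {
    s <- 0
    for (k in 1:2)
      s <- s + exp(-((xs - centres[k, 1])^2 + (g$y - centres[k, 2])^2 +
                       (g$z - centres[k, 3])^2) / 18)
    array(s, c(28, 28, 28))
  }
  A <- mk(g$x); B <- mk(g$x - ux)
  fAB <- registerPair(A, B, regParams(gridSpacing = 5), c(1, 1, 1))$field
  fBA <- registerPair(B, A, regParams(gridSpacing = 5), c(1, 1, 1))$field
  fg <- which(A > 0.3)
  pts <- as.matrix(g[fg, ])[seq(1, length(fg), by = 7), , drop = FALSE]
  there <- transformPoints(fAB, pts, units = "voxel")
  back <- transformPoints(fBA, there[, 1:3], units = "voxel")
  err <- sqrt(rowSums((back[, 1:3] - pts)^2))
  expect_lt(mean(err), 1)
})
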