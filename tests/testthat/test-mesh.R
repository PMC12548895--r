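test_that("mask-to-mesh on a digital ball matches sphere area and genus", {
  m <- ballMask(45L, 15)
  msh <- maskToMesh(m)
  expect_s4_class(msh, "SurfaceMesh")
  expect_equal(eulerCharacteristic(msh), 2L)
  expect_lt(abs(sum(faceAreas(msh)) / (4 * pi * 15^2) - 1), 0.05)
  expect_lt(abs(meshVolume(msh) / (4 / 3 * pi * 15^3) - 1), 0.05)
  expect_error(maskToMesh(binaryMask(array(FALSE, c(5, 5, 5)), 1)),
               "empty mask")
})

test_that("mask-to-mesh rejects multiple large components", {
  vox <- array(FALSE, c(20, 20, 10))
  vox[2:8, 2:8, 2:8] <- TRUE
  vox[12:18, 12:18, 2:8] <- TRUE
  expect_error(maskToMesh(binaryMask(vox, 1)), "multiple large components")
})

test_that("face areas: analytic triangle, degenerate warning", {
  tri <- surfaceMesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                     matrix(1:3, 1))
  expect_equal(faceAreas(tri), 6)
  degen <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       matrix(1:3, 1))
  expect_warning(a <- faceAreas(degen), "degenerate")
  expect_lt(a, 1e-9)
})

test_that("Laplacian smoothing reduces radial noise and fixes planes", {
  m <- ballMask(41L, 13)
  msh <- maskToMesh(m)
  ctr <- colMeans(vertices(msh))
  set.seed(7)
  rad <- sweep(vertices(msh), 2, ctr)
  rr <- sqrt(rowSums(rad^2))
  noisy <- initialize(msh, vertices = sweep(rad * (1 + rnorm(length(rr), 0, 0.5 / 13)),
                                            2, ctr, "+"))
  rmsDev <- function(mm) {
    r <- sqrt(rowSums(sweep(vertices(mm), 2, colMeans(vertices(mm)))^2))
    sd(r)
  }
  sm <- smoothMesh(noisy, alpha = 0.9, iterations = 5)
  expect_lt(rmsDev(sm), rmsDev(noisy))
  expect_identical(faces(sm), faces(noisy))
  # alpha 0 is a no-op
  expect_identical(vertices(smoothMesh(noisy, alpha = 0)), vertices(noisy))
  # a flat grid stays flat (harmonic fixed point)
  plane <- gridMesh(8)
  ps <- smoothMesh(plane, 0.9, 5)
  expect_lt(max(abs(vertices(ps)[, 3])), 1e-6)
})

test_that("mesh rasterisation: unit cube volume and ball round trip", {
  s <- 1
  cubeV <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
  cubeF <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                 c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                 c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- surfaceMesh(cubeV + 0.3, cubeF)   # keep inside the grid
  mk <- meshToMask(cube, 0.1)
  expect_lt(abs(sum(mk@voxels) * 0.1^3 - 1), 0.05)
  # open hemisphere errors with its boundary loops
  hemi <- ballMask(31L, 10)
  hm <- maskToMesh(hemi)
  keep <- vertices(hm)[, 3] <= 15
  fkeep <- apply(matrix(keep[faces(hm)], ncol = 3), 1, all)
  idx <- which(keep)
  remap <- match(seq_len(nrow(vertices(hm))), idx)
  open <- surfaceMesh(vertices(hm)[keep, ],
                      matrix(remap[faces(hm)[fkeep, ]], ncol = 3))
  expect_error(meshToMask(open, 1), "boundary loop")
  closed <- closeMeshHoles(open)
  expect_length(boundaryLoops(closed), 0)
  # ball round trip: mask -> mesh -> mask volume within 10%
  m <- ballMask(35L, 11)
  msh <- maskToMesh(m)
  back <- meshToMask(msh, 1, dims = dim(m@voxels))
  expect_gt(sum(back@voxels) / sum(m@voxels), 0.9)
  expect_lt(sum(back@voxels) / sum(m@voxels), 1.1)
})

test_that("mesh propagation preserves topology and follows the flow", {
  msh <- gridMesh(6)
  # keep the whole trajectory inside the field domain
  msh <- surfaceMesh(sweep(vertices(msh), 2, c(20, 6, 6), "+"), faces(msh))
  n <- 7L
  tset <- constantFlowTset(n, d = 2)
  lss <- propagateMesh(msh, tset)
  expect_equal(nFrames(lss), n)
  expect_identical(faces(lss), faces(msh))
  for (f in seq_len(n))
    expect_equal(nrow(positions(lss, f)), nrow(vertices(msh)))
  a <- anchorFrame(lss)
  # +2 voxels per forward step, -2 per backward step along x
  expect_equal(positions(lss, n)[, 1],
               vertices(msh)[, 1] + 2 * (n - a), tolerance = 1e-9)
  expect_equal(positions(lss, 1L)[, 1],
               vertices(msh)[, 1] - 2 * (a - 1), tolerance = 1e-9)
  # identity set keeps the mesh constant
  lss0 <- propagateMesh(msh, identityTset(5, dim = c(48L, 24L, 24L)))
  for (f in 1:5)
    expect_equal(positions(lss0, f), unname(vertices(msh)), tolerance = 1e-12)
})

test_that("geodesic neighbourhoods behave like discs on a flat grid", {
  msh <- gridMesh(10)
  g <- morphomap:::faceGraph(msh)
  cent <- morphomap:::faceCentroids(msh)
  seed <- which.min(rowSums(sweep(cent, 2, c(5, 5, 0))^2))
  expect_identical(geodesicNeighbourhood(msh, seed, 0, g), seed)
  nb <- geodesicNeighbourhood(msh, seed, 3, g)
  eu <- sqrt(rowSums(sweep(cent, 2, cent[seed, ])^2))
  # the centroid-hop path zigzags, so geodesic >= Euclidean with a
  # bounded distortion on a regular grid
  expect_true(all(eu[nb] <= 3 + 1e-9))
  expect_true(all(which(eu <= 3 * 0.5) %in% nb))
  expect_length(geodesicNeighbourhood(msh, seed, 1e6, g), nrow(faces(msh)))
  expect_error(geodesicNeighbourhood(msh, 0L, 1), "invalid face")
})

test_that("geodesic membership is symmetric in distance", {
  msh <- gridMesh(6)
  g <- morphomap:::faceGraph(msh)
  set.seed(8)
  for (k in 1:10) {
    a <- sample(nrow(faces(msh)), 1)
    b <- sample(nrow(faces(msh)), 1)
    r <- runif(1, 0.5, 4)
    expect_equal(b %in% geodesicNeighbourhood(msh, a, r, g),
                 a %in% geodesicNeighbourhood(msh, b, r, g))
  }
})

test_that("PLY and OFF round trips preserve geometry", {
  msh <- gridMesh(4)
  for (fmt in c("ascii", "binary_little_endian")) {
    path <- tempfile(fileext = ".ply")
    writePLY(msh, path, format = fmt)
    back <- readPLY(path)
    expect_equal(vertices(back), unname(vertices(msh)))
    expect_equal(faces(back), faces(msh))
  }
  off <- tempfile(fileext = ".off")
  writeLines(c("OFF", paste(nrow(vertices(msh)), nrow(faces(msh)), 0),
               apply(vertices(msh), 1, paste, collapse = " "),
               apply(cbind(3L, faces(msh) - 1L), 1, paste, collapse = " ")),
             off)
  back <- readOFF(off)
  expect_equal(back@vertices, unname(vertices(msh)))
  expect_equal(back@faces, faces(msh))
})

triAreaOf <- function(lss, f)
  faceAreas(surfaceMesh(positions(lss, f), faces(lss)))

test_that("area is stable along an area-preserving live-shape flow", {
  # rigid motion per frame preserves per-face area exactly
  msh <- gridMesh(6)
  R <- rotMat(c(0, 0, 1), 0.3)
  pos <- list(vertices(msh),
              vertices(msh) %*% t(R),
              sweep(vertices(msh) %*% t(R %*% R), 2, c(1, 2, 0), "+"))
  lss <- new("LiveShapeSequence", faces = faces(msh), positions = pos,
             anchorFrame = 1L, outOfDomain = rep(list(rep(FALSE, nrow(vertices(msh)))), 3))
  a0 <- sum(triAreaOf(lss, 1))
  for (f in 2:3)
    expect_lt(abs(sum(triAreaOf(lss, f)) / a0 - 1), 0.02)
})
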