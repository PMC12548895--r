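# lightweight SurfaceMap stand-ins for chain tests: meshes with known
# motion, no image registration involved
smapOf <- function(mesh, specimen = "e01", stage = "Gr2", frame = 1L) {
  corr <- data.frame(atlasFace = seq_len(nrow(mesh@faces)),
                     mapFace = seq_len(nrow(mesh@faces)),
                     distance = 0)
  new("SurfaceMap", mesh = mesh, correspondence = corr,
      specimen = specimen, frame = as.integer(frame), stage = stage,
      provenance = list())
}

flowMeshes <- function(p, stages, uRange = c(0, 1), nU = 16L, nV = 16L) {
  lapply(stages, function(t) sceneMesh(p, t, uRange = uRange,
                                       nU = nU, nV = nV))
}

test_that("identity hooks keep chain positions constant", {
  p <- sceneParams()
  msh <- sceneMesh(p, 0.5, nU = 10L, nV = 10L)
  hooks <- lapply(1:3, function(g)
    list(specimen = "e01", from = g, to = g + 1L,
         smapFrom = smapOf(msh), smapTo = smapOf(msh)))
  ch <- buildChain(vertices(msh), 1L, hooks, 4L)
  expect_true(all(ch$covered))
  for (s in 2:4)
    expect_equal(ch$positions[[s]], unname(vertices(msh)),
                 tolerance = 1e-12)
})

test_that("a cohort sharing one flow reproduces the analytic trajectory", {
  p <- sceneParams()
  times <- seq(0, 1, length.out = 5)
  meshes <- flowMeshes(p, times, nU = 20L, nV = 20L)
  hooks <- lapply(1:4, function(g)
    list(specimen = sprintf("e%02d", g), from = g, to = g + 1L,
         smapFrom = smapOf(meshes[[g]]), smapTo = smapOf(meshes[[g + 1]])))
  eye <- sceneMesh(p, times[2], nU = 13L, nV = 13L)   # different density
  ch <- buildChain(vertices(eye), 2L, hooks, 5L)
  expect_true(all(ch$covered))
  uv <- eye@provenance$uv
  for (s in c(1L, 4L, 5L)) {
    truth <- surfacePoint(p, uv[, 1], uv[, 2], times[s])
    err <- sqrt(rowSums((ch$positions[[s]] - truth)^2))
    expect_lt(mean(err), 2)
  }
})

test_that("uncovered transitions truncate the chain with a report", {
  p <- sceneParams()
  msh <- sceneMesh(p, 0.5, nU = 8L, nV = 8L)
  hooks <- list(list(specimen = "e01", from = 1L, to = 2L,
                     smapFrom = smapOf(msh), smapTo = smapOf(msh)))
  ch <- buildChain(vertices(msh), 1L, hooks, 4L)
  expect_true(ch$covered[2])
  expect_false(any(ch$covered[3:4]))
  expect_match(ch$truncated, "2->3")
})

test_that("step means average per-point across embryos", {
  p <- sceneParams()
  msh <- sceneMesh(p, 0.5, nU = 10L, nV = 10L)
  nf <- nrow(faces(msh))
  mkMap <- function(Jval) {
    new("DeformationMap", F = matrix(0, nf, 4), J = rep(Jval, nf),
        theta = rep(1.1, nf), direction = matrix(0, nf, 3),
        Jsmooth = rep(Jval, nf), thetaSmooth = rep(1.1, nf), mesh = msh,
        interval = c(1, 2), degenerate = rep(FALSE, nf))
  }
  hooks <- list(list(specimen = "e01", from = 1L, to = 2L,
                     smapFrom = smapOf(msh), smapTo = smapOf(msh)))
  ch <- buildChain(vertices(msh), 1L, hooks, 2L)
  em <- list(list(map = mkMap(1.1), smapTo = smapOf(msh)),
             list(map = mkMap(1.3), smapTo = smapOf(msh)))
  sm <- meanStepwiseDeformation(ch, 1L, em)
  expect_equal(unique(sm$Jbar), 1.2)
  expect_equal(unique(sm$n), 2L)
  # permutation invariance
  sm2 <- meanStepwiseDeformation(ch, 1L, rev(em))
  expect_equal(sm$Jbar, sm2$Jbar)
  # one embryo: the mean is its value
  expect_equal(unique(meanStepwiseDeformation(ch, 1L, em[1])$Jbar), 1.1)
})

test_that("cumulative products are associative over interval splits", {
  n <- 40L
  mkStep <- function(J) data.frame(point = 1:n, Jbar = J,
                                   thetaBar = sqrt(J), n = 2L)
  set.seed(30)
  steps <- lapply(1:5, function(i) mkStep(runif(n, 0.8, 1.3)))
  full <- cumulativeDeformation(steps)$table
  left <- cumulativeDeformation(steps[1:2])$table
  right <- cumulativeDeformation(steps[3:5])$table
  expect_equal(full$Jbar, left$Jbar * right$Jbar, tolerance = 1e-12)
  expect_equal(full$thetaBar, left$thetaBar * right$thetaBar,
               tolerance = 1e-12)
  # all-identity steps give exactly 1
  ones <- cumulativeDeformation(lapply(1:3, function(i) mkStep(1)))$table
  expect_true(all(ones$Jbar == 1))
  # explicit product example
  two <- cumulativeDeformation(list(mkStep(1.1), mkStep(1.2)))$table
  expect_equal(unique(two$Jbar), 1.32)
  # gaps exclude points
  gap <- mkStep(1.1); gap$n[5] <- 0L
  out <- cumulativeDeformation(list(gap, mkStep(1.2)))$table
  expect_false(out$covered[5])
  expect_true(is.na(out$Jbar[5]))
})

test_that("the fate map enforces continuity and single paths", {
  p <- sceneParams()
  times <- seq(0, 1, length.out = 4)
  meshes <- flowMeshes(p, times, nU = 14L, nV = 14L)
  hooks <- lapply(1:3, function(g)
    list(specimen = sprintf("e%02d", g), from = g, to = g + 1L,
         smapFrom = smapOf(meshes[[g]]), smapTo = smapOf(meshes[[g + 1]])))
  fm <- buildFateMap(vertices(meshes[[1]]), 1L, hooks, 4L)
  expect_s3_class(fm, "dynamicAtlas")
  expect_length(fm$positions, 4)
  expect_equal(fm$path, c("e01", "e02", "e03"))
  # a corrupted hook (part of the mesh displaced far away) breaks the
  # pointwise continuity guard
  badHooks <- hooks
  vbad <- vertices(meshes[[3]])
  vbad[1:30, ] <- vbad[1:30, ] + 500
  badHooks[[2]]$smapTo <- smapOf(surfaceMesh(vbad, faces(meshes[[3]])))
  expect_error(buildFateMap(vertices(meshes[[1]]), 1L, badHooks, 4L),
               "continuity failure")
  # missing transition fails the build naming the stages
  expect_error(buildFateMap(vertices(meshes[[1]]), 1L, hooks[-2], 4L),
               "does not cover")
})

test_that("pseudo-cell tracking snaps, tracks, and rejects far seeds", {
  p <- sceneParams()
  times <- seq(0, 1, length.out = 4)
  meshes <- flowMeshes(p, times, nU = 14L, nV = 14L)
  hooks <- lapply(1:3, function(g)
    list(specimen = "e01", from = g, to = g + 1L,
         smapFrom = smapOf(meshes[[g]]), smapTo = smapOf(meshes[[g + 1]])))
  fm <- buildFateMap(vertices(meshes[[1]]), 1L, hooks, 4L)
  seeds <- fm$positions[[1]][c(5, 50, 100), , drop = FALSE]
  tr <- trackPseudoCells(fm, seeds, 1L, 4L)
  expect_true(all(tr$accepted))
  expect_equal(tr$endpoints,
               fm$positions[[4]][tr$pointIds, , drop = FALSE],
               tolerance = 1e-12)
  # b = a returns the snapped positions
  tr0 <- trackPseudoCells(fm, seeds, 1L, 1L)
  expect_equal(tr0$endpoints,
               fm$positions[[1]][tr0$pointIds, , drop = FALSE])
  # far seeds are rejected with their distance
  far <- trackPseudoCells(fm, matrix(c(1e4, 1e4, 1e4), 1), 1L, 4L)
  expect_false(any(far$accepted))
  expect_gt(far$snapDistance[1], far$snapRadius)
  # a stationary atlas keeps trajectories constant
  hooks0 <- lapply(1:3, function(g)
    list(specimen = "e01", from = g, to = g + 1L,
         smapFrom = smapOf(meshes[[1]]), smapTo = smapOf(meshes[[1]])))
  fm0 <- buildFateMap(vertices(meshes[[1]]), 1L, hooks0, 4L)
  tr1 <- trackPseudoCells(fm0, fm0$positions[[1]][c(5, 50), ], 1L, 4L)
  for (traj in tr1$trajectories)
    expect_lt(max(abs(sweep(traj, 2, traj[1, ]))), 1e-9)
})

test_that("zone growth profiles track analytic uniform growth", {
  p <- sceneParams()
  msh <- sceneMesh(p, 0, nU = 12L, nV = 12L)
  zones <- partitionZones(msh, 5L)
  expect_length(zones, nrow(faces(msh)))
  expect_equal(sort(unique(zones)), 1:5)
  # uniform x1.1 area growth per stage: every zone grows geometrically
  shapes <- lapply(0:4, function(k)
    surfaceMesh(vertices(msh) * sqrt(1.1)^k, faces(msh)))
  gp <- zoneGrowthProfiles(shapes, zones)
  for (z in 1:5) {
    ratio <- gp$raw[-1, z] / gp$raw[-5, z]
    expect_equal(ratio, rep(1.1, 4), tolerance = 1e-9)
  }
  # static shapes give flat profiles
  gp0 <- zoneGrowthProfiles(rep(list(msh), 4), zones)
  expect_true(all(abs(gp0$raw - gp0$raw[1, ][col(gp0$raw)]) < 1e-9))
  # single zone equals the total area
  gp1 <- zoneGrowthProfiles(shapes, rep(1L, nrow(faces(msh))))
  expect_equal(gp1$raw[, 1],
               vapply(shapes, function(s) sum(faceAreas(s)), 1))
  expect_error(zoneGrowthProfiles(shapes, zones[-1]), "every face")
})

test_that("profile comparison scores identity, reversal, and exclusion", {
  set.seed(31)
  raw <- matrix(runif(40, 1, 10), 4, 10)
  gp <- structure(list(raw = raw, smooth = raw, zones = 1:10,
                       stages = 1:4), class = "growthProfile")
  same <- compareGrowthProfiles(gp, gp, toleranceRank = 0)
  expect_equal(same$overall, 100)
  rev_ <- structure(list(raw = -raw, smooth = -raw, zones = 1:10,
                         stages = 1:4), class = "growthProfile")
  flipped <- compareGrowthProfiles(gp, rev_, toleranceRank = 0)
  expect_lt(flipped$overall, 25)
  # making one zone noisy hurts; excluding it recovers the match
  noisy <- raw
  noisy[, 5] <- rev(raw[, 5]) * 10
  gpN <- structure(list(raw = noisy, smooth = noisy, zones = 1:10,
                        stages = 1:4), class = "growthProfile")
  withZone <- compareGrowthProfiles(gp, gpN, toleranceRank = 0)
  without <- compareGrowthProfiles(gp, gpN, excludeZones = 5,
                                   toleranceRank = 0)
  expect_gte(without$overall, withZone$overall)
  expect_equal(without$excluded, 5)
  expect_error(compareGrowthProfiles(gp, structure(
    list(raw = raw[, 1:5], smooth = raw[, 1:5], zones = 1:5, stages = 1:4),
    class = "growthProfile")), "share zones")
})
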