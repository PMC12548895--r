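#' @include mesh.R staging.R
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene parameters
#'
#' A parametric thin epithelial sheet: a tapered half-cylinder crescent
#' `S(u, v, t)` that closes circumferentially and elongates axially into
#' a (nearly closed) tube as `t` runs 0 to 1, emulating heart-tube
#' morphogenesis. The closed-form metric gives exact per-face area and
#' stretch ratios between any two times, which is what makes the scene a
#' ground-truth oracle. The taper breaks the crescent's two-fold symmetry
#' so that pose recovery is unambiguous.
#'
#' @param radius0,radius1 tube radius (um) at t = 0 and 1.
#' @param arc0,arc1 circumferential arc (radians) at t = 0 and 1.
#' @param length0,length1 axial length (um) at t = 0 and 1.
#' @param midStretch amplitude of the u-dependent axial stretch ramp.
#' @param taper relative radius gradient along u (symmetry breaking).
#' @param nU,nV mesh grid resolution (cells along u and v).
#' @param volumeDim rendering volume in voxels.
#' @param voxelSize rendering voxel size (um).
#' @param nFrames frames per acquisition.
#' @param timeStep minutes per frame.
#' @param shellSigma membrane shell Gaussian sigma (um).
#' @param cellSigma labelled-cell blob sigma (um).
#' @param cellRadius nominal cell radius (um) used by error criteria.
#' @param nCells number of labelled cells.
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param bleachRate exponential intensity decay per frame.
#' @param mixing if TRUE cells take random tangential walks (gastrulation
#'   control) instead of following the tissue flow.
#' @param mixingStep sd of the per-frame (u, v) walk when `mixing`.
#' @return list of class `"sceneParams"`.
#' @export
sceneParams <- function(radius0 = 12, radius1 = 14, arc0 = pi,
                        arc1 = 1.85 * pi, length0 = 36, length1 = 50,
                        midStretch = 0.25, taper = 0.25,
                        nU = 24L, nV = 24L,
                        volumeDim = c(64L, 64L, 64L), voxelSize = 1,
                        nFrames = 8L, timeStep = 10,
                        shellSigma = 1.2, cellSigma = 1.5, cellRadius = 3,
                        nCells = 80L, noiseSigma = 0.02, bleachRate = 0.02,
                        mixing = FALSE, mixingStep = 0.05) {
  p <- list(radius0 = radius0, radius1 = radius1, arc0 = arc0, arc1 = arc1,
            length0 = length0, length1 = length1, midStretch = midStretch,
            taper = taper, nU = as.integer(nU), nV = as.integer(nV),
            volumeDim = as.integer(volumeDim), voxelSize = voxelSize,
            nFrames = as.integer(nFrames), timeStep = timeStep,
            shellSigma = shellSigma, cellSigma = cellSigma,
            cellRadius = cellRadius, nCells = as.integer(nCells),
            noiseSigma = noiseSigma, bleachRate = bleachRate,
            mixing = mixing, mixingStep = mixingStep)
  p$centre <- p$volumeDim * p$voxelSize / 2
  if (p$arc1 >= 2 * pi) stop("arc1 must stay below 2*pi (self-contact)")
  if (p$radius1 * 2 + 4 > min(p$volumeDim * p$voxelSize) ||
      p$length1 + 4 > max(p$volumeDim * p$voxelSize))
    stop("volume too small to contain the surface")
  class(p) <- "sceneParams"
  p
}

# time courses of the family parameters
sceneAt <- function(p, t) {
  list(r = p$radius0 + (p$radius1 - p$radius0) * t,
       psi = p$arc0 + (p$arc1 - p$arc0) * t,
       L = p$length0 + (p$length1 - p$length0) * t,
       a = p$midStretch * t)
}

#' Evaluate the synthetic surface
#'
#' @param p [sceneParams].
#' @param u,v surface coordinates in \[0, 1\] (vectors of equal length).
#' @param t pseudo-time in \[0, 1\].
#' @return n x 3 matrix of world positions (um).
#' @export
surfacePoint <- function(p, u, v, t) {
  s <- sceneAt(p, t)
  z <- s$L * ((u - 0.5) + s$a * sin(2 * pi * u) / (2 * pi))
  ru <- s$r * (1 + p$taper * (u - 0.5))
  alpha <- s$psi * (v - 0.5)
  cbind(p$centre[1] + ru * cos(alpha),
        p$centre[2] + ru * sin(alpha),
        p$centre[3] + z)
}

#' Analytic stretch ratios of the synthetic flow
#'
#' Closed-form axial and circumferential stretch ratios between times
#' `t0` and `t1` at coordinate `u` (the metric is independent of `v`),
#' with the derived area ratio `J` and anisotropy ratio.
#'
#' @param p [sceneParams].
#' @param u axial coordinate(s).
#' @param t0,t1 pseudo-times.
#' @return data.frame with `lambdaU`, `lambdaV`, `J`, `theta`.
#' @export
analyticDeformation <- function(p, u, t0, t1) {
  su <- function(t) {
    s <- sceneAt(p, t)
    zu <- s$L * (1 + s$a * cos(2 * pi * u))
    rpu <- s$r * p$taper              # d r_u / du, constant in u
    sqrt(zu^2 + rpu^2)
  }
  sv <- function(t) {
    s <- sceneAt(p, t)
    s$r * s$psi                        # taper factor cancels in the ratio
  }
  lambdaU <- su(t1) / su(t0)
  lambdaV <- sv(t1) / sv(t0) + 0 * u
  data.frame(u = u, lambdaU = lambdaU, lambdaV = lambdaV,
             J = lambdaU * lambdaV,
             theta = pmax(lambdaU, lambdaV) / pmin(lambdaU, lambdaV))
}

#' Sample the synthetic surface as a triangle mesh
#'
#' Regular (u, v) grid triangulated into a [SurfaceMesh-class]; node and
#' face (u, v) coordinates are kept in the provenance so analytic ground
#' truth can be evaluated per node/face.
#'
#' @param p [sceneParams].
#' @param t pseudo-time.
#' @param uRange covered axial window (caps outside are missing).
#' @param nU,nV grid resolution (defaults from `p`).
#' @return A [SurfaceMesh-class] with `provenance$uv` and
#'   `provenance$faceUV`.
#' @export
sceneMesh <- function(p, t, uRange = c(0, 1), nU = p$nU, nV = p$nV) {
  us <- seq(uRange[1], uRange[2], length.out = nU + 1L)
  vs <- seq(0, 1, length.out = nV + 1L)
  g <- expand.grid(u = us, v = vs)       # u varies fastest
  V <- surfacePoint(p, g$u, g$v, t)
  id <- function(i, j) i + (j - 1L) * (nU + 1L)
  F <- matrix(0L, 2L * nU * nV, 3)
  k <- 1L
  for (j in seq_len(nV))
    for (i in seq_len(nU)) {
      F[k, ] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
      F[k + 1L, ] <- c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
      k <- k + 2L
    }
  fuv <- cbind((g$u[F[, 1]] + g$u[F[, 2]] + g$u[F[, 3]]) / 3,
               (g$v[F[, 1]] + g$v[F[, 2]] + g$v[F[, 3]]) / 3)
  surfaceMesh(V, F, provenance = list(source = "sceneMesh", t = t,
                                      uv = cbind(g$u, g$v), faceUV = fuv))
}

#' Generate a ground-truth synthetic scene
#'
#' Builds the mesh trajectory of the deforming sheet, labelled-cell
#' tracks advected by the analytic flow (or random tangential walks in
#' mixing mode), and the per-face analytic deformation between
#' consecutive frames. Everything is deterministic under the seed.
#'
#' @param params [sceneParams].
#' @param seed integer seed.
#' @return list of class `"syntheticScene"` with `params`, `times`,
#'   `shapes` (a [LiveShapeSequence-class]), `cells` (anchors),
#'   `tracks` (data.frame: cell, frame, x, y, z, layer, dividing),
#'   `analytic` (function(u, t0, t1)), and `seed`.
#' @export
makeScene <- function(params = sceneParams(), seed = 1L) {
  withSeed(seed, {
    p <- params
    times <- seq(0, 1, length.out = p$nFrames)
    ref <- sceneMesh(p, times[1])
    uv <- ref@provenance$uv
    positions <- lapply(times, function(t)
      surfacePoint(p, uv[, 1], uv[, 2], t))
    anchor <- as.integer(floor(p$nFrames / 2) + 1L)
    shapes <- new("LiveShapeSequence", faces = ref@faces,
                  positions = positions, anchorFrame = anchor,
                  outOfDomain = rep(list(rep(FALSE, nrow(uv))), p$nFrames))
    cu <- runif(p$nCells, 0.06, 0.94)
    cv <- runif(p$nCells, 0.06, 0.94)
    layer <- sample(c("Myo", "Spl", "Endo"), p$nCells, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
    tracks <- vector("list", p$nFrames)
    uc <- cu; vc <- cv
    for (f in seq_len(p$nFrames)) {
      if (p$mixing && f > 1L) {
        uc <- pmin(0.98, pmax(0.02, uc + rnorm(p$nCells, 0, p$mixingStep)))
        vc <- pmin(0.98, pmax(0.02, vc + rnorm(p$nCells, 0, p$mixingStep)))
      }
      pos <- surfacePoint(p, uc, vc, times[f])
      tracks[[f]] <- data.frame(cell = seq_len(p$nCells), frame = f,
                                x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                layer = layer, dividing = FALSE)
    }
    structure(list(params = p, times = times, shapes = shapes,
                   cells = data.frame(cell = seq_len(p$nCells), u = cu,
                                      v = cv, layer = layer),
                   tracks = do.call(rbind, tracks),
                   analytic = function(u, t0, t1)
                     analyticDeformation(p, u, t0, t1),
                   seed = seed),
              class = "syntheticScene")
  })
}

#' Render a synthetic scene into a Hyperstack
#'
#' Membrane-shell intensity (Gaussian profile across the surface) plus
#' brighter Gaussian blobs at the labelled cells, additive Gaussian
#' noise, and exponential photobleaching. The exact cell positions are
#' returned as the ground-truth track set.
#'
#' @param scene a `"syntheticScene"`.
#' @return list with `stack` (a [Hyperstack-class]) and `tracks`.
#' @export
renderStack <- function(scene) {
  p <- scene$params
  withSeed(scene$seed + 101L, {
    dims <- p$volumeDim
    vs <- p$voxelSize
    nf <- p$nFrames
    arr <- array(0, c(dims, 1L, nf))
    # quasi-uniform surface sampling: spacing ~ half a voxel
    sMax <- sceneAt(p, 1)
    nu <- ceiling(sMax$L / (0.5 * vs))
    nv <- ceiling(sMax$r * sMax$psi / (0.5 * vs))
    g <- expand.grid(u = seq(0, 1, length.out = nu),
                     v = seq(0, 1, length.out = nv))
    for (f in seq_len(nf)) {
      t <- scene$times[f]
      surf <- worldToVoxel(surfacePoint(p, g$u, g$v, t), vs)
      # weight by the local area element to even out the splat density
      an <- analyticDeformation(p, g$u, 0, max(t, 1e-9))
      w <- an$lambdaU * an$lambdaV
      shell <- cpp_splat_gauss(dims, surf, w / mean(w), p$shellSigma / vs)
      tr <- scene$tracks[scene$tracks$frame == f, ]
      blobs <- cpp_splat_gauss(dims,
                               worldToVoxel(as.matrix(tr[, c("x", "y", "z")]),
                                            vs),
                               rep(2.5, nrow(tr)), p$cellSigma / vs)
      vol <- array(shell, dims) / max(shell) * 0.6 +
        array(blobs, dims) / max(blobs) * 0.6
      vol <- vol * exp(-p$bleachRate * (f - 1))
      if (p$noiseSigma > 0)
        vol <- vol + array(rnorm(prod(dims), 0, p$noiseSigma), dims)
      arr[, , , 1L, f] <- vol
    }
    list(stack = hyperstack(arr, rep(vs, 3), p$timeStep,
                            meta = list(synthetic = TRUE,
                                        seed = scene$seed)),
         tracks = scene$tracks)
  })
}

#' Analytic landmarks of the synthetic shape
#'
#' pt1/pt2 span the crescent opening (width), pt3/pt4 the axial extent
#' (height), pt5/pt6 a parallel chord, pt7 the axial exit point.
#'
#' @param p [sceneParams].
#' @param t pseudo-time.
#' @return a [landmarkSet].
#' @export
sceneLandmarks <- function(p, t) {
  landmarkSet(rbind(surfacePoint(p, 0.5, 0, t),
                    surfacePoint(p, 0.5, 1, t),
                    surfacePoint(p, 0, 0.5, t),
                    surfacePoint(p, 1, 0.5, t),
                    surfacePoint(p, 0.25, 0, t),
                    surfacePoint(p, 0.25, 1, t),
                    surfacePoint(p, 1, 0.5, t) + c(0, 0, 1e-6)))
}

#' Build a synthetic staged atlas
#'
#' Canonical shapes of the family at `nStages` pseudo-times, with
#' analytic landmarks, a monotone reference staging parameter, and
#' per-group calibration samples of the h/w feature. The calibration
#' noise defaults to a quarter of the smallest adjacent-group mean gap,
#' i.e. groups separated by about four standard deviations, mirroring a
#' well-resolved staging system.
#'
#' @param nStages number of atlas groups (default 8, labelled Gr2..Gr9).
#' @param params [sceneParams].
#' @param seed integer seed.
#' @param nPerGroup calibration specimens per group.
#' @param sigma calibration noise sd; `NULL` for the default above.
#' @param labels group labels.
#' @return list of class `"syntheticAtlas"`: `shapes` (per stage: `mesh`,
#'   `stage`, `landmarks`, `referenceParameter`, `time`), `calibration`
#'   (named list of h/w samples), `sigma`, `times`, `params`.
#' @export
makeSyntheticAtlas <- function(nStages = 8L, params = sceneParams(),
                               seed = 1L, nPerGroup = 6L, sigma = NULL,
                               labels = paste0("Gr", seq_len(nStages) + 1L)) {
  if (nStages < 2L) stop("need at least 2 stages")
  withSeed(seed + 500L, {
    times <- seq(0, 1, length.out = nStages)
    shapes <- vector("list", nStages)
    hw <- numeric(nStages)
    for (s in seq_len(nStages)) {
      lm <- sceneLandmarks(params, times[s])
      hw[s] <- computeFeatures(lm)$hOverW
      shapes[[s]] <- list(mesh = sceneMesh(params, times[s]),
                          stage = labels[s], landmarks = lm,
                          referenceParameter = 0.2 + 0.8 * times[s],
                          time = times[s])
    }
    if (is.null(sigma)) sigma <- min(abs(diff(hw))) / 4
    calibration <- setNames(lapply(seq_len(nStages), function(s)
      rnorm(nPerGroup, hw[s], sigma)), labels)
    structure(list(shapes = shapes, calibration = calibration,
                   sigma = sigma, times = times, hw = hw, labels = labels,
                   params = params),
              class = "syntheticAtlas")
  })
}

#' Generate a fragmented multi-specimen cohort
#'
#' Each specimen observes a contiguous window of atlas stages, carries a
#' random rigid pose and a global size factor, a specimen-specific mesh
#' density, and tube-end caps removed per `capCutFraction` (the missing
#' inflow/outflow tracts). Size, pose, density and coverage are the
#' modelled sources of inter-specimen variability; the underlying shape
#' family is shared, so analytic ground truth remains exact.
#'
#' @param nSpecimens cohort size.
#' @param params [sceneParams].
#' @param nStages atlas stages on the timeline.
#' @param windowStages stages covered per specimen.
#' @param capCutFraction fraction of the axial range removed at each end.
#' @param seed integer seed.
#' @return list of class `"syntheticCohort"`: per specimen `id`,
#'   `stages` (covered stage indices), `times`, `shapes` (posed
#'   [LiveShapeSequence-class], one frame per covered stage),
#'   `landmarks` (per frame), `pose` (similarityTransform), `sizeFactor`,
#'   `uRange`, plus the shared `params` and stage `times`.
#' @export
makeCohort <- function(nSpecimens = 6L, params = sceneParams(),
                       nStages = 8L, windowStages = 4L,
                       capCutFraction = 0.1, seed = 1L) {
  withSeed(seed + 900L, {
    times <- seq(0, 1, length.out = nStages)
    starts <- round(seq(1, nStages - windowStages + 1,
                        length.out = nSpecimens))
    covered <- sort(unique(unlist(lapply(starts, function(s)
      s:(s + windowStages - 2L)))))
    if (!identical(covered, seq_len(nStages - 1L)))
      stop("sampled windows leave a stage transition uncovered")
    specimens <- vector("list", nSpecimens)
    for (i in seq_len(nSpecimens)) {
      stages <- starts[i]:(starts[i] + windowStages - 1L)
      cut <- capCutFraction * runif(1, 0.8, 1.2)
      uR <- c(cut, 1 - cut)
      nUi <- sample(18:26, 1)
      nVi <- sample(18:26, 1)
      size <- runif(1, 0.93, 1.07)
      ax <- rnorm(3); ax <- ax / vnorm(ax)
      ang <- runif(1, 0.2, 1.2)
      R <- rotationMatrix(ax, ang)
      tr <- runif(3, -15, 15)
      pose <- similarityTransform(R, tr, size)
      ref <- sceneMesh(params, times[stages[1]], uRange = uR,
                       nU = nUi, nV = nVi)
      uv <- ref@provenance$uv
      positions <- lapply(times[stages], function(t)
        applySimilarity(pose, surfacePoint(params, uv[, 1], uv[, 2], t)))
      lss <- new("LiveShapeSequence", faces = ref@faces,
                 positions = positions, anchorFrame = 1L,
                 outOfDomain = rep(list(rep(FALSE, nrow(uv))),
                                   length(stages)))
      lms <- lapply(times[stages], function(t)
        landmarkSet(applySimilarity(pose,
                                    sceneLandmarks(params, t))))
      specimens[[i]] <- list(id = sprintf("e%02d", i), stages = stages,
                             times = times[stages], shapes = lss,
                             landmarks = lms, pose = pose,
                             sizeFactor = size, uRange = uR,
                             uv = uv, faceUV = ref@provenance$faceUV)
    }
    structure(list(specimens = specimens, params = params, times = times,
                   nStages = nStages, seed = seed),
              class = "syntheticCohort")
  })
}
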