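#' @include mapping.R
NULL

#' Build a cross-stage correspondence chain
#'
#' Carries a reference point cloud (the eye points, typically one
#' SurfaceMap's nodes) across atlas stages using the motion of hook
#' specimens: at each transition the eye points are snapped to the
#' nearest nodes of a hook's SurfaceMap at the earlier stage, and the
#' hook's own morphed positions at the later stage give the carried
#' positions. `mode = "average"` averages the predictions of all hooks
#' covering a transition (cumulative-deformation mode);
#' `mode = "single_path"` uses exactly one hook per transition (fate-map
#' mode, prioritising anatomical coherence over averaging).
#'
#' @param eyePoints n x 3 matrix in atlas coordinates.
#' @param eyeStage stage index (1-based) where the eye points live.
#' @param hooks list of hook entries, each a list with `specimen`,
#'   `from`, `to` (consecutive stage indices) and `smapFrom`, `smapTo`
#'   ([SurfaceMap-class] of the same specimen at the two stages).
#' @param nStages total stages on the atlas timeline.
#' @param mode `"average"` or `"single_path"`.
#' @return list of class `"correspondenceChain"`: `positions` (per-stage
#'   matrices, NULL where uncovered), `eyeStage`, `covered`,
#'   `contributors` (per transition), `truncated`.
#' @export
buildChain <- function(eyePoints, eyeStage, hooks, nStages,
                       mode = c("average", "single_path")) {
  mode <- match.arg(mode)
  eyePoints <- rbindMatrix(eyePoints)
  positions <- vector("list", nStages)
  positions[[eyeStage]] <- eyePoints
  contributors <- vector("list", nStages)
  truncated <- character()
  hookFor <- function(g, gn) {
    Filter(function(h) h$from == min(g, gn) && h$to == max(g, gn), hooks)
  }
  carry <- function(P, g, gn) {
    hs <- hookFor(g, gn)
    if (!length(hs)) return(NULL)
    if (mode == "single_path") hs <- hs[1]
    preds <- lapply(hs, function(h) {
      if (gn > g) {
        idx <- cpp_nn(P, h$smapFrom@mesh@vertices)$index
        h$smapTo@mesh@vertices[idx, , drop = FALSE]
      } else {
        idx <- cpp_nn(P, h$smapTo@mesh@vertices)$index
        h$smapFrom@mesh@vertices[idx, , drop = FALSE]
      }
    })
    list(pos = Reduce(`+`, preds) / length(preds),
         who = vapply(hs, function(h) h$specimen, ""))
  }
  if (eyeStage < nStages)
    for (g in eyeStage:(nStages - 1L)) {
      step <- carry(positions[[g]], g, g + 1L)
      if (is.null(step)) {
        truncated <- c(truncated, sprintf("%d->%d", g, g + 1L))
        break
      }
      positions[[g + 1L]] <- step$pos
      contributors[[g]] <- step$who
    }
  if (eyeStage > 1L)
    for (g in eyeStage:2L) {
      step <- carry(positions[[g]], g, g - 1L)
      if (is.null(step)) {
        truncated <- c(truncated, sprintf("%d->%d", g, g - 1L))
        break
      }
      positions[[g - 1L]] <- step$pos
      contributors[[g - 1L]] <- step$who
    }
  structure(list(positions = positions, eyeStage = eyeStage,
                 covered = !vapply(positions, is.null, TRUE),
                 contributors = contributors, truncated = truncated),
            class = "correspondenceChain")
}

#' Mean stepwise deformation at the chain's reference points
#'
#' For one stage transition, gathers per-face growth and anisotropy from
#' every contributing embryo's deformation map (computed on its native
#' Live-Shape, end frame) through that embryo's SurfaceMap
#' correspondence, and averages them per reference point. The mean is
#' arithmetic over embryos; a geometric mean is available since the
#' quantities are multiplicative, and a message reports when the two
#' differ by more than 1 percent.
#'
#' @param chain a `"correspondenceChain"`.
#' @param transition earlier stage index `g` of the transition
#'   `g -> g+1`.
#' @param embryoMaps list, one per contributing embryo, each with `map`
#'   (a [DeformationMap-class] on the specimen's end-frame Live-Shape)
#'   and `smapTo` (the specimen's [SurfaceMap-class] at stage `g+1`).
#' @param smoothed use geodesically smoothed values (default TRUE).
#' @param meanType `"arithmetic"` (default) or `"geometric"`.
#' @return data.frame with `point`, `Jbar`, `thetaBar`, `n`.
#' @export
meanStepwiseDeformation <- function(chain, transition, embryoMaps,
                                    smoothed = TRUE,
                                    meanType = c("arithmetic", "geometric")) {
  meanType <- match.arg(meanType)
  P <- chain$positions[[transition + 1L]]
  if (is.null(P)) stop("chain does not cover stage ", transition + 1L)
  n <- nrow(P)
  Jm <- matrix(NA_real_, n, length(embryoMaps))
  Tm <- matrix(NA_real_, n, length(embryoMaps))
  for (e in seq_along(embryoMaps)) {
    em <- embryoMaps[[e]]
    cent <- faceCentroids(em$smapTo@mesh)
    idx <- cpp_nn(P, cent)$index
    Jm[, e] <- if (smoothed) em$map@Jsmooth[idx] else em$map@J[idx]
    Tm[, e] <- if (smoothed) em$map@thetaSmooth[idx] else em$map@theta[idx]
  }
  cnt <- rowSums(!is.na(Jm))
  if (any(cnt == 0L))
    warning(sum(cnt == 0L), " reference point(s) with zero contributors")
  am <- rowMeans(Jm, na.rm = TRUE)
  if (meanType == "geometric") {
    gm <- exp(rowMeans(log(Jm), na.rm = TRUE))
    if (max(abs(gm / am - 1), na.rm = TRUE) > 0.01)
      message("geometric and arithmetic step means differ by > 1%")
    Jbar <- gm
    thetaBar <- exp(rowMeans(log(Tm), na.rm = TRUE))
  } else {
    Jbar <- am
    thetaBar <- rowMeans(Tm, na.rm = TRUE)
  }
  data.frame(point = seq_len(n), Jbar = Jbar, thetaBar = thetaBar, n = cnt)
}

#' Cumulative deformation as a product of step means
#'
#' Per reference point, the cumulative growth and anisotropy over a
#' contiguous stage interval are the products of the mean stepwise
#' values. Points lacking coverage at any step are excluded rather than
#' imputed.
#'
#' @param stepMeans ordered list of data.frames from
#'   [meanStepwiseDeformation], one per transition.
#' @param interval the (first stage, last stage) the steps span.
#' @return list of class `"cumulativeDeformation"` with `table`
#'   (data.frame: point, Jbar, thetaBar, covered) and `interval`.
#' @export
cumulativeDeformation <- function(stepMeans,
                                  interval = c(1L, length(stepMeans) + 1L)) {
  if (!length(stepMeans)) stop("no step means supplied")
  n <- nrow(stepMeans[[1]])
  J <- rep(1, n)
  th <- rep(1, n)
  covered <- rep(TRUE, n)
  for (sm in stepMeans) {
    if (nrow(sm) != n) stop("step means disagree on reference points")
    ok <- sm$n > 0L & is.finite(sm$Jbar)
    covered <- covered & ok
    J[ok] <- J[ok] * sm$Jbar[ok]
    th[ok] <- th[ok] * sm$thetaBar[ok]
  }
  J[!covered] <- NA_real_
  th[!covered] <- NA_real_
  structure(list(table = data.frame(point = seq_len(n), Jbar = J,
                                    thetaBar = th, covered = covered),
                 interval = interval, nSteps = length(stepMeans)),
            class = "cumulativeDeformation")
}

#' Build the in-silico fate map (Dynamic Atlas)
#'
#' Carries a single reference point cloud through all stage transitions
#' with one specimen (the most complete motion profile) per transition —
#' a single-path chain that keeps trajectories anatomically coherent. A
#' stage-to-stage jump exceeding `continuityFactor` times the median
#' jump of that transition fails the build, naming the transition.
#'
#' @param eyePoints reference point cloud (atlas coordinates).
#' @param eyeStage its stage index.
#' @param pathHooks list of hook entries (see [buildChain]), exactly one
#'   per transition.
#' @param nStages stages on the timeline.
#' @param continuityFactor continuity multiple (default 10).
#' @return list of class `"dynamicAtlas"`: `positions` per stage,
#'   `stages`, `path` (specimen per transition), `eyeStage`.
#' @export
buildFateMap <- function(eyePoints, eyeStage, pathHooks, nStages,
                         continuityFactor = 10) {
  chain <- buildChain(eyePoints, eyeStage, pathHooks, nStages,
                      mode = "single_path")
  if (!all(chain$covered))
    stop("fate-map path does not cover stages: ",
         paste(which(!chain$covered), collapse = ", "),
         if (length(chain$truncated))
           paste0(" (truncated at ",
                  paste(chain$truncated, collapse = ", "), ")"))
  for (g in seq_len(nStages - 1L)) {
    jump <- rowNorms(chain$positions[[g + 1L]] - chain$positions[[g]])
    med <- median(jump)
    if (med > 0 && max(jump) > continuityFactor * med)
      stop(sprintf(
        "continuity failure at transition %d -> %d (max jump %.2f, median %.2f)",
        g, g + 1L, max(jump), med))
  }
  path <- vapply(seq_len(nStages - 1L), function(g) {
    i <- which(vapply(pathHooks, function(h) h$from == g, TRUE))[1]
    if (is.na(i)) NA_character_ else pathHooks[[i]]$specimen
  }, "")
  structure(list(positions = chain$positions, stages = seq_len(nStages),
                 path = path, eyeStage = eyeStage),
            class = "dynamicAtlas")   # plain list; S3 tag for printing
}

#' @export
print.dynamicAtlas <- function(x, ...) {
  cat(sprintf(
    "Dynamic Atlas: %d reference points over stages %d..%d (path: %s)\n",
    nrow(x$positions[[x$eyeStage]]), min(x$stages), max(x$stages),
    paste(x$path, collapse = " -> ")))
  invisible(x)
}

#' Track pseudo-cells on the Dynamic Atlas
#'
#' Snaps each seed to its nearest reference point at the start stage and
#' follows that point's stage positions to the target stage (forward or
#' backward). Seeds farther than the snap radius are rejected with their
#' distance.
#'
#' @param atlas a `"dynamicAtlas"`.
#' @param seeds n x 3 matrix at stage `from`.
#' @param from,to stage indices.
#' @param snapRadius rejection radius (um); default the median
#'   inter-node spacing of the stage-`from` cloud.
#' @return list with `pointIds`, `accepted`, `snapDistance`,
#'   `trajectories` (list per accepted seed: stages x 3 matrix), and
#'   `endpoints` (matrix at stage `to`).
#' @export
trackPseudoCells <- function(atlas, seeds, from, to, snapRadius = NULL) {
  seeds <- rbindMatrix(seeds)
  P <- atlas$positions[[from]]
  if (is.null(P)) stop("stage ", from, " not covered by the atlas")
  if (is.null(snapRadius)) {
    d2 <- cpp_pdist2(P, P)
    diag(d2) <- Inf
    snapRadius <- median(sqrt(apply(d2, 1, min)))
  }
  nn <- cpp_nn(seeds, P)
  accepted <- nn$distance <= snapRadius
  stages <- if (to >= from) from:to else from:to
  traj <- lapply(which(accepted), function(i) {
    id <- nn$index[i]
    do.call(rbind, lapply(stages, function(s) atlas$positions[[s]][id, ]))
  })
  endpoints <- if (length(traj))
    do.call(rbind, lapply(traj, function(m) m[nrow(m), ]))
  else matrix(numeric(), 0, 3)
  list(pointIds = nn$index, accepted = accepted,
       snapDistance = nn$distance, trajectories = traj,
       endpoints = endpoints, stages = stages, snapRadius = snapRadius)
}

#' Write a Dynamic Atlas archive
#'
#' Per-stage point clouds as PLY, trajectories as CSV
#' (pointId, stage, x, y, z) and the concatenation path as JSON.
#'
#' @param atlas a `"dynamicAtlas"`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
writeDynamicAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in atlas$stages) {
    P <- atlas$positions[[s]]
    if (is.null(P)) next
    writePLY(surfaceMesh(P, matrix(integer(), 0, 3)),
             file.path(dir, sprintf("stage_%02d.ply", s)),
             format = "ascii")
    rows[[length(rows) + 1L]] <-
      data.frame(pointId = seq_len(nrow(P)), stage = s,
                 x = P[, 1], y = P[, 2], z = P[, 3])
  }
  write.csv(do.call(rbind, rows), file.path(dir, "trajectories.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(path = atlas$path, eyeStage = atlas$eyeStage),
                       file.path(dir, "path.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Partition mesh faces into zones
#'
#' Deterministic equal-count slabs along the first principal axis of the
#' face centroids; a simple stand-in for hand-drawn anatomical zones.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param nZones number of zones (default 10).
#' @return integer vector, zone label per face.
#' @export
partitionZones <- function(mesh, nZones = 10L) {
  cent <- faceCentroids(mesh)
  ax <- svd(sweep(cent, 2, colMeans(cent)))$v[, 1]
  proj <- as.vector(sweep(cent, 2, colMeans(cent)) %*% ax)
  as.integer(cut(rank(proj, ties.method = "first"), nZones, labels = FALSE))
}

#' Zone growth profiles across stages
#'
#' Sums per-face areas within each zone at every stage and smooths each
#' zone's profile across stages with a degree-3 B-spline fit.
#'
#' @param shapes list of per-stage [SurfaceMesh-class] sharing one
#'   topology.
#' @param zones integer vector, zone per face.
#' @return list of class `"growthProfile"`: `raw` and `smooth`
#'   (stages x zones matrices), `zones`, `stages`.
#' @export
zoneGrowthProfiles <- function(shapes, zones) {
  nf <- nrow(shapes[[1]]@faces)
  if (length(zones) != nf)
    stop("zones must label every face (", nf, " faces, ",
         length(zones), " labels)")
  zl <- sort(unique(zones))
  K <- length(shapes)
  raw <- matrix(0, K, length(zl), dimnames = list(NULL, zl))
  for (s in seq_len(K)) {
    a <- triArea(shapes[[s]]@vertices, shapes[[s]]@faces)
    raw[s, ] <- rowsum(a, zones)[, 1]
  }
  smooth <- raw
  if (K >= 4L) {
    x <- seq_len(K)
    B <- splines::bs(x, degree = 3)
    for (z in seq_along(zl))
      smooth[, z] <- stats::fitted(lm(raw[, z] ~ B))
  }
  structure(list(raw = raw, smooth = smooth, zones = zl,
                 stages = seq_len(K)),
            class = "growthProfile")
}

#' Compare two zone growth profiles by rank agreement
#'
#' At each stage, zones are ranked by their (smoothed) growth value in
#' each profile; the per-stage agreement is the fraction of zones whose
#' ranks match within the tolerance window, and the overall match is the
#' mean across stages (percent). Noisy zones (for example cut tube ends)
#' can be excluded.
#'
#' @param a,b `"growthProfile"` objects over the same zones and stages.
#' @param excludeZones zone labels to drop.
#' @param toleranceRank rank window (default 1).
#' @return list with `perStage` (percent per stage), `overall` (percent),
#'   `toleranceRank`, `excluded`.
#' @export
compareGrowthProfiles <- function(a, b, excludeZones = NULL,
                                  toleranceRank = 1L) {
  if (!identical(a$zones, b$zones) || nrow(a$smooth) != nrow(b$smooth))
    stop("profiles must share zones and stages")
  keep <- !(a$zones %in% excludeZones)
  A <- a$smooth[, keep, drop = FALSE]
  B <- b$smooth[, keep, drop = FALSE]
  perStage <- vapply(seq_len(nrow(A)), function(s) {
    ra <- rank(A[s, ], ties.method = "first")
    rb <- rank(B[s, ], ties.method = "first")
    100 * mean(abs(ra - rb) <= toleranceRank)
  }, 1)
  list(perStage = perStage, overall = mean(perStage),
       toleranceRank = toleranceRank,
       excluded = a$zones[!keep])
}
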