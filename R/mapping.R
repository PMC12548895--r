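#' @include pointset.R registration.R mesh.R
NULL

invertSimilarity <- function(tr) {
  Rinv <- t(tr$rotation)
  similarityTransform(Rinv, -as.vector(Rinv %*% tr$translation) / tr$scale,
                      1 / tr$scale)
}

#' Project a staged Live-Shape frame into atlas space
#'
#' The three-step projection pipeline: (1) the atlas shape is rigidly
#' aligned to the live mesh by robust Student's-t mixture registration;
#' (2) atlas regions without live correspondence (typically the missing
#' tube ends) are removed, giving the cut atlas; (3) both shapes are
#' rasterised as thin membrane masks on a common grid and the live mask
#' is non-rigidly registered onto the cut-atlas mask; the recovered
#' B-spline field moves the live nodes onto the atlas geometry. The
#' morphed nodes are finally carried into canonical atlas coordinates by
#' the inverse rigid transform, and every atlas face is matched to its
#' nearest morphed face. The result keeps the live topology (the
#' specimen's own dynamics) on the atlas geometry.
#'
#' @param live a [SurfaceMesh-class], the staged Live-Shape frame.
#' @param atlasShape list with at least `mesh` ([SurfaceMesh-class]) and
#'   `stage` (label), as produced by [makeSyntheticAtlas].
#' @param regPar [regParams] for the mask registration.
#' @param tmmPar [tmmParams] for the rigid stage.
#' @param cutThreshold distance (um) for [cutUnmatched]; `NULL` for the
#'   adaptive default.
#' @param gridVoxel rasterisation voxel (um); `NULL` picks a size that
#'   keeps the grid near 56 voxels across.
#' @param shellThickness mask shell thickness (um).
#' @param specimen,frame annotations stored in the result.
#' @return A [SurfaceMap-class].
#' @export
projectToAtlas <- function(live, atlasShape, regPar = regParams(),
                           tmmPar = tmmParams(), cutThreshold = NULL,
                           gridVoxel = NULL, shellThickness = 4,
                           specimen = "specimen", frame = 1L) {
  atlasMesh <- atlasShape$mesh
  ## 1. rigid: atlas -> live
  rig <- tmmRegister(atlasMesh@vertices, live@vertices, tmmPar)
  atlasAligned <- surfaceMesh(rig$aligned, atlasMesh@faces)
  ## 2. AtlasCut in the live frame
  cut <- cutUnmatched(atlasAligned, live, cutThreshold)
  atlasCut <- cut$mesh
  ## 3. mask-based non-rigid morphing, live -> AtlasCut
  allV <- rbind(live@vertices, atlasCut@vertices)
  lo <- apply(allV, 2, min)
  hi <- apply(allV, 2, max)
  if (is.null(gridVoxel))
    gridVoxel <- max(max(hi - lo) / 56, 0.5)
  margin <- 4 * gridVoxel
  off <- lo - margin
  dims <- as.integer(ceiling((hi - lo + 2 * margin) / gridVoxel)) + 1L
  shift <- function(mesh) initialize(mesh,
                                     vertices = sweep(mesh@vertices, 2, off))
  liveMask <- meshToShellMask(shift(live), gridVoxel, shellThickness, dims)
  atlasMask <- meshToShellMask(shift(atlasCut), gridVoxel, shellThickness,
                               dims)
  soft <- function(m)
    rescale01(array(cpp_gauss3(as.numeric(m@voxels), dims, 1.5), dims))
  reg <- registerPair(soft(liveMask), soft(atlasMask), regPar,
                      voxelSize = rep(gridVoxel, 3))
  morphed <- transformPoints(reg$field, sweep(live@vertices, 2, off))
  morphed <- sweep(morphed[, 1:3, drop = FALSE], 2, off, "+")
  ## back to canonical atlas coordinates
  inv <- invertSimilarity(rig$transform)
  mapMesh <- surfaceMesh(applySimilarity(inv, morphed), live@faces,
                         provenance = list(source = "projectToAtlas",
                                           stage = atlasShape$stage))
  corr <- faceToFaceMatch(atlasMesh, mapMesh)
  names(corr) <- c("atlasFace", "mapFace", "distance")
  new("SurfaceMap", mesh = mapMesh, correspondence = corr,
      specimen = specimen, frame = as.integer(frame),
      stage = as.character(atlasShape$stage),
      provenance = list(rigid = rig$transform, rigidRMSE = rig$rmse,
                        cutThreshold = cut$threshold,
                        removedNodes = length(cut$removedNodes),
                        registrationTarget = reg$target,
                        gridVoxel = gridVoxel, gridDims = dims,
                        shellThickness = shellThickness))
}

#' Validate a projection by its transferred area pattern
#'
#' Transfers the per-face areas of the original live mesh onto the atlas
#' through the face correspondence, and rank-correlates that pattern
#' against an independent geometric route (nearest rigidly-aligned live
#' face per atlas face). A projection that lands the pattern on the
#' right anatomical regions scores near 1; a shuffled correspondence
#' scores near 0.
#'
#' @param live the original [SurfaceMesh-class].
#' @param surfaceMap the [SurfaceMap-class] from [projectToAtlas].
#' @param atlasShape the atlas entry used for the projection.
#' @return list with `transferred` (per atlas face, NA where unmatched)
#'   and `rankCorrelation` (Spearman).
#' @export
validateMappingByArea <- function(live, surfaceMap, atlasShape) {
  corr <- surfaceMap@correspondence
  if (!nrow(corr)) stop("empty correspondence")
  liveAreas <- suppressWarnings(faceAreas(live))
  nAtlas <- nrow(atlasShape$mesh@faces)
  transferred <- rep(NA_real_, nAtlas)
  transferred[corr$atlasFace] <- liveAreas[corr$mapFace]
  ## independent route: rigid alignment only
  rig <- surfaceMap@provenance$rigid
  if (is.null(rig)) stop("surfaceMap lacks rigid provenance")
  liveRigid <- surfaceMesh(applySimilarity(invertSimilarity(rig),
                                           live@vertices), live@faces)
  ref <- faceToFaceMatch(atlasShape$mesh, liveRigid)
  reference <- liveAreas[ref$targetFace]
  okf <- which(!is.na(transferred))
  rc <- cor(transferred[okf], reference[okf], method = "spearman")
  list(transferred = transferred, rankCorrelation = rc)
}
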