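#' @include morphomap-package.R
NULL

#' Hyperstack: a 3D+t intensity volume
#'
#' Canonical in-memory form of a live-imaging acquisition. Voxel data are
#' stored as a 5D array indexed (x, y, z, channel, t); most of the pipeline
#' requires a single channel (see [mergeChannels]). Spatial units are
#' micrometres via `voxelSize`, frame spacing in minutes via `timeStep`.
#' Axis order is fixed: all voxel indices in the package are 0-based in
#' world-coordinate helpers and 1-based in R array indexing.
#'
#' @slot data 5D numeric array (x, y, z, channel, t).
#' @slot voxelSize numeric(3), micrometres per voxel along x, y, z.
#' @slot timeStep numeric(1), minutes between frames.
#' @slot isotropic logical, TRUE when all three voxel sizes are equal.
#' @slot meta list of free-form provenance (rotations applied, crops, ...).
#' @exportClass Hyperstack
setClass("Hyperstack",
  representation(data = "array", voxelSize = "numeric", timeStep = "numeric",
                 isotropic = "logical", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 5L)
      msg <- c(msg, "data must be a 5D (x, y, z, channel, t) array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values")
    if (length(object@timeStep) != 1L || object@timeStep <= 0)
      msg <- c(msg, "timeStep must be a single positive value")
    if (isTRUE(object@isotropic) &&
        diff(range(object@voxelSize)) > 1e-9)
      msg <- c(msg, "isotropic = TRUE but voxel sizes differ")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a 3D segmentation mask
#'
#' @slot voxels logical 3D array (x, y, z).
#' @slot voxelSize numeric(3), micrometres per voxel.
#' @slot frameIndex integer(1), the Hyperstack frame this mask segments.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(voxels = "array", voxelSize = "numeric",
                 frameIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (!is.logical(object@voxels))
      msg <- c(msg, "voxels must be logical")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values")
    if (length(msg)) msg else TRUE
  })

#' TransformField: one pairwise B-spline displacement field
#'
#' Displacements live on a regular control lattice with `spacing` voxels
#' between knots; the dense transform is the cubic B-spline tensor-product
#' interpolation of the control displacements. Zero control displacements
#' give the identity map. Evaluation outside the voxel domain clamps to the
#' boundary (see [transformPoints]).
#'
#' @slot ctrl numeric matrix (nControl x 3) of control displacements, voxels.
#' @slot lattice integer(3), control lattice dimensions.
#' @slot spacing numeric(1), knot spacing in voxels.
#' @slot domain integer(3), voxel dimensions of the registered frames.
#' @slot direction integer(2), (reference frame, moving frame), 1-based.
#' @slot voxelSize numeric(3), micrometres per voxel of the domain.
#' @exportClass TransformField
setClass("TransformField",
  representation(ctrl = "matrix", lattice = "integer", spacing = "numeric",
                 domain = "integer", direction = "integer",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@ctrl) != 3L) msg <- c(msg, "ctrl must have 3 columns")
    if (nrow(object@ctrl) != prod(object@lattice))
      msg <- c(msg, "ctrl rows must equal prod(lattice)")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
    if (length(object@direction) != 2L)
      msg <- c(msg, "direction must be (from, to)")
    if (length(msg)) msg else TRUE
  })

#' TransformSet: bidirectional pairwise fields anchored at the midpoint
#'
#' Holds the fields of a registered sequence. `forward` maps the anchor
#' frame outward towards the last frame (anchor -> anchor+1 -> ...), and
#' `backward` towards the first. With N frames there are exactly N - 1
#' fields in total.
#'
#' @slot forward list of [TransformField] (anchor -> N).
#' @slot backward list of [TransformField] (anchor -> 1).
#' @slot anchor integer(1), anchor frame (1-based).
#' @slot nFrames integer(1).
#' @exportClass TransformSet
setClass("TransformSet",
  representation(forward = "list", backward = "list", anchor = "integer",
                 nFrames = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@forward) + length(object@backward) !=
        object@nFrames - 1L)
      msg <- c(msg, "need exactly nFrames - 1 fields")
    if (object@anchor < 1L || object@anchor > object@nFrames)
      msg <- c(msg, "anchor out of range")
    ok <- TRUE
    fw <- object@forward
    for (i in seq_along(fw))
      if (!all(fw[[i]]@direction ==
               c(object@anchor + i - 1L, object@anchor + i))) ok <- FALSE
    bw <- object@backward
    for (i in seq_along(bw))
      if (!all(bw[[i]]@direction ==
               c(object@anchor - i + 1L, object@anchor - i))) ok <- FALSE
    if (!ok) msg <- c(msg, "field directions inconsistent with position")
    if (length(msg)) msg else TRUE
  })

#' SurfaceMesh: a triangular surface in world (micrometre) coordinates
#'
#' @slot vertices numeric matrix (nVertices x 3), micrometres.
#' @slot faces integer matrix (nFaces x 3) of 1-based vertex indices.
#' @slot provenance list describing how the mesh was produced.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L)
      msg <- c(msg, "vertices must have 3 columns")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must have 3 columns")
    if (nrow(object@faces) &&
        (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
      msg <- c(msg, "face indices out of range")
    if (length(msg)) msg else TRUE
  })

#' LiveShapeSequence: one mesh topology with per-frame node positions
#'
#' The continuous description of tissue motion: the anchor-frame mesh is
#' propagated node-wise through a [TransformSet], so the triangulation is
#' identical at every frame and only node positions change (nodes are never
#' exchanged).
#'
#' @slot faces integer matrix (nFaces x 3), shared across frames.
#' @slot positions list of numeric matrices (nVertices x 3), one per frame.
#' @slot anchorFrame integer(1), frame whose segmentation seeded the mesh.
#' @slot outOfDomain list of logical vectors flagging clamped nodes.
#' @exportClass LiveShapeSequence
setClass("LiveShapeSequence",
  representation(faces = "matrix", positions = "list",
                 anchorFrame = "integer", outOfDomain = "list"),
  validity = function(object) {
    msg <- character()
    nv <- vapply(object@positions, nrow, 1L)
    if (length(unique(nv)) > 1L)
      msg <- c(msg, "node count must be constant across frames")
    if (length(object@positions) &&
        (object@anchorFrame < 1L ||
         object@anchorFrame > length(object@positions)))
      msg <- c(msg, "anchorFrame out of range")
    if (length(msg)) msg else TRUE
  })

#' StagingModel: per-group Gaussian mixture over a morphometric feature
#'
#' Each reference atlas group contributes one normal component over the
#' staging feature (the height/width landmark ratio); equal priors by
#' default. Frames in the uncertain leading/trailing runs must exceed
#' `boundaryThreshold` posterior probability to be assigned.
#'
#' @slot groups character vector of group labels, ordered by mean.
#' @slot mu numeric means per group.
#' @slot sigma numeric standard deviations per group (floored > 0).
#' @slot priors numeric mixing weights, sum to 1.
#' @slot boundaryThreshold numeric(1), posterior cutoff for boundary frames.
#' @exportClass StagingModel
setClass("StagingModel",
  representation(groups = "character", mu = "numeric", sigma = "numeric",
                 priors = "numeric", boundaryThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- length(object@groups)
    if (length(object@mu) != k || length(object@sigma) != k ||
        length(object@priors) != k)
      msg <- c(msg, "groups, mu, sigma, priors must have equal length")
    if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
    if (abs(sum(object@priors) - 1) > 1e-8)
      msg <- c(msg, "priors must sum to 1")
    if (is.unsorted(object@mu)) msg <- c(msg, "groups must be ordered by mean")
    if (length(msg)) msg else TRUE
  })

#' DeformationMap: per-face finite-deformation quantities
#'
#' Stores, for every triangle shared by a rest and a deformed mesh, the 2x2
#' deformation gradient, the growth rate J = det(F) (local area ratio), the
#' anisotropy ratio of principal stretches, the world-frame principal
#' stretch direction, and geodesically smoothed J and anisotropy. Values
#' are attached to the deformed-state mesh.
#'
#' @slot F numeric matrix (nFaces x 4), columns F11, F21, F12, F22.
#' @slot J numeric per-face growth rate.
#' @slot theta numeric per-face anisotropy ratio (>= 1).
#' @slot direction numeric matrix (nFaces x 3), principal stretch direction.
#' @slot Jsmooth,thetaSmooth numeric, geodesically smoothed fields.
#' @slot mesh [SurfaceMesh], the deformed-state mesh the map is plotted on.
#' @slot interval character(2) or numeric(2), (rest, deformed) identifiers.
#' @slot degenerate logical per-face flag for excluded faces.
#' @exportClass DeformationMap
setClass("DeformationMap",
  representation(F = "matrix", J = "numeric", theta = "numeric",
                 direction = "matrix", Jsmooth = "numeric",
                 thetaSmooth = "numeric", mesh = "SurfaceMesh",
                 interval = "ANY", degenerate = "logical"),
  validity = function(object) {
    nf <- nrow(object@mesh@faces)
    if (length(object@J) != nf || length(object@theta) != nf)
      return("per-face fields must match face count")
    bad <- !object@degenerate & (object@theta < 1 - 1e-9)
    if (any(bad, na.rm = TRUE)) return("theta must be >= 1")
    TRUE
  })

#' SurfaceMap: a Live-Shape frame morphed into atlas space
#'
#' @slot mesh [SurfaceMesh] with the Live-Shape topology, atlas geometry.
#' @slot correspondence data.frame (atlasFace, mapFace, distance) matching
#'   each atlas face to its nearest morphed-live face.
#' @slot specimen character(1) specimen identifier.
#' @slot frame integer(1) source frame.
#' @slot stage character(1) atlas group label.
#' @slot provenance list with per-stage parameters of the projection.
#' @exportClass SurfaceMap
setClass("SurfaceMap",
  representation(mesh = "SurfaceMesh", correspondence = "data.frame",
                 specimen = "character", frame = "integer",
                 stage = "character", provenance = "list"),
  validity = function(object) {
    cn <- c("atlasFace", "mapFace", "distance")
    if (!all(cn %in% names(object@correspondence)))
      return("correspondence needs atlasFace, mapFace, distance")
    nf <- nrow(object@mesh@faces)
    if (nrow(object@correspondence) &&
        max(object@correspondence$mapFace) > nf)
      return("correspondence references missing SurfaceMap face")
    TRUE
  })
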