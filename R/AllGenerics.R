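#' @include AllClasses.R
NULL

#' Accessors for morphomap classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a morphomap object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x, ...) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x, ...) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(x, frame, channel = 1L, ...)
  standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x, ...) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("anchorFrame", function(x, ...) standardGeneric("anchorFrame"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x, frame, ...) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("growthRates", function(x, smoothed = FALSE, ...)
  standardGeneric("growthRates"))
#' @rdname accessors
#' @export
setGeneric("anisotropyRatios", function(x, smoothed = FALSE, ...)
  standardGeneric("anisotropyRatios"))
#' @rdname accessors
#' @export
setGeneric("correspondence", function(x, ...) standardGeneric("correspondence"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "Hyperstack", function(x, ...) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "BinaryMask", function(x, ...) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("nFrames", "Hyperstack", function(x, ...) dim(x@data)[5L])
#' @rdname accessors
#' @export
setMethod("nFrames", "TransformSet", function(x, ...) x@nFrames)
#' @rdname accessors
#' @export
setMethod("nFrames", "LiveShapeSequence", function(x, ...)
  length(x@positions))
#' @rdname accessors
#' @export
setMethod("nChannels", "Hyperstack", function(x, ...) dim(x@data)[4L])

#' @rdname accessors
#' @export
setMethod("intensity", "Hyperstack", function(x, frame, channel = 1L, ...) {
  if (missing(frame)) return(x@data[, , , channel, , drop = FALSE])
  x@data[, , , channel, frame]
})

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(x, ...) x@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(x, ...) x@faces)
#' @rdname accessors
#' @export
setMethod("faces", "LiveShapeSequence", function(x, ...) x@faces)
#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMap", function(x, ...) x@mesh@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMap", function(x, ...) x@mesh@faces)
#' @rdname accessors
#' @export
setMethod("anchorFrame", "LiveShapeSequence", function(x, ...) x@anchorFrame)
#' @rdname accessors
#' @export
setMethod("anchorFrame", "TransformSet", function(x, ...) x@anchor)
#' @rdname accessors
#' @export
setMethod("positions", "LiveShapeSequence", function(x, frame, ...) {
  if (missing(frame)) return(x@positions)
  x@positions[[frame]]
})
#' @rdname accessors
#' @export
setMethod("growthRates", "DeformationMap", function(x, smoothed = FALSE, ...)
  if (smoothed) x@Jsmooth else x@J)
#' @rdname accessors
#' @export
setMethod("anisotropyRatios", "DeformationMap",
  function(x, smoothed = FALSE, ...)
    if (smoothed) x@thetaSmooth else x@theta)
#' @rdname accessors
#' @export
setMethod("correspondence", "SurfaceMap", function(x, ...) x@correspondence)

setMethod("show", "Hyperstack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "Hyperstack: %d x %d x %d voxels, %d channel(s), %d frame(s)\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  voxel size (um): %s%s | time step: %g min\n",
              paste(signif(object@voxelSize, 4), collapse = " x "),
              if (object@isotropic) " (isotropic)" else "",
              object@timeStep))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask: %d x %d x %d, %d foreground voxels (frame %d)\n",
              d[1], d[2], d[3], sum(object@voxels), object@frameIndex))
})

setMethod("show", "TransformField", function(object) {
  cat(sprintf(
    "TransformField %d -> %d: lattice %s, spacing %g vox, max |u| = %.3g vox\n",
    object@direction[1], object@direction[2],
    paste(object@lattice, collapse = "x"), object@spacing,
    max(abs(object@ctrl))))
})

setMethod("show", "TransformSet", function(object) {
  cat(sprintf(
    "TransformSet: %d frames, anchor %d, %d forward + %d backward fields\n",
    object@nFrames, object@anchor, length(object@forward),
    length(object@backward)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "LiveShapeSequence", function(object) {
  cat(sprintf(
    "LiveShapeSequence: %d frames (anchor %d), %d nodes, %d faces\n",
    length(object@positions), object@anchorFrame,
    if (length(object@positions)) nrow(object@positions[[1]]) else 0L,
    nrow(object@faces)))
})

setMethod("show", "StagingModel", function(object) {
  cat(sprintf("StagingModel: %d groups (%s), boundary threshold %.2f\n",
              length(object@groups),
              paste(object@groups, collapse = ", "),
              object@boundaryThreshold))
})

setMethod("show", "DeformationMap", function(object) {
  ok <- !object@degenerate
  cat(sprintf(
    "DeformationMap on %d faces (%d degenerate): median J = %.3f, median theta = %.3f\n",
    length(object@J), sum(object@degenerate),
    median(object@J[ok]), median(object@theta[ok])))
})

setMethod("show", "SurfaceMap", function(object) {
  cat(sprintf(
    "SurfaceMap: specimen %s frame %d -> stage %s (%d matched atlas faces)\n",
    object@specimen, object@frame, object@stage,
    nrow(object@correspondence)))
})
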