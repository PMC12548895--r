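#' @include imaging_io.R
NULL

#' Registration parameters
#'
#' Settings of the pairwise free-form-deformation registration. The control
#' grid spacing defaults to 10 micrometres — half the average cardiomyocyte
#' diameter — so the transform can resolve deformation at cell scale without
#' chasing noise. The target function is the mean per-voxel sum of squared
#' differences plus `lambda` times the mean squared lattice Laplacian of
#' the control displacements (a bending-energy surrogate that keeps the
#' deformation smooth).
#'
#' @param gridSpacing control-point spacing in micrometres (default 10).
#' @param lambda regularisation weight (default 0.01).
#' @param tol relative target-function change for convergence (default 1e-8).
#' @param maxIter maximum iterations per resolution level (default 100).
#' @param levels multiresolution hierarchy depth (default 4).
#' @param similarity similarity measure; only `"SSD"` is implemented.
#' @return list of class `"regParams"`.
#' @export
regParams <- function(gridSpacing = 10, lambda = 0.01, tol = 1e-8,
                      maxIter = 100L, levels = 4L, similarity = "SSD") {
  stopifnot(gridSpacing > 0, lambda >= 0, levels >= 1L)
  if (similarity != "SSD")
    stop("only SSD similarity is implemented")
  structure(list(gridSpacing = gridSpacing, lambda = lambda, tol = tol,
                 maxIter = as.integer(maxIter), levels = as.integer(levels),
                 similarity = similarity), class = "regParams")
}

latticeDims <- function(dims, spacing) {
  as.integer(floor((dims - 1) / spacing) + 4L)
}

# one level of limited-memory quasi-Newton descent on the FFD target
# function; fn and gr share evaluations at identical iterates
optimizeLevel <- function(ref, mov, ctrl, ncd, spacing, params) {
  d <- dim(ref)
  refv <- as.numeric(ref)
  movv <- as.numeric(mov)
  nc <- prod(ncd)
  cache <- new.env(parent = emptyenv())
  cache$x <- NULL
  evalAt <- function(x) {
    if (!is.null(cache$x) && identical(x, cache$x)) return(invisible(NULL))
    r <- cpp_ffd_cost_grad(refv, movv, d, matrix(x, nc, 3), ncd, spacing,
                           params$lambda, TRUE)
    cache$x <- x
    cache$cost <- r$cost
    cache$grad <- as.numeric(r$grad)
    invisible(NULL)
  }
  fn <- function(x) { evalAt(x); cache$cost }
  gr <- function(x) { evalAt(x); cache$grad }
  o <- stats::optim(as.numeric(ctrl), fn, gr, method = "L-BFGS-B",
                    control = list(
                      maxit = params$maxIter,
                      factr = max(10, params$tol / .Machine$double.eps)))
  list(ctrl = matrix(o$par, nc, 3), cost = o$value)
}

#' Register a pair of frames with a B-spline free-form deformation
#'
#' Minimises the SSD-plus-regularisation target function over a cubic
#' B-spline displacement lattice, coarse to fine over `params$levels`
#' resolution levels (each level halves the image resolution of the next;
#' the physical control spacing is held at `gridSpacing`). The returned
#' field maps reference-frame coordinates to the corresponding
#' moving-frame coordinates, which is the direction point propagation
#' needs.
#'
#' @param reference,moving 3D numeric arrays with intensities in \[0, 1\],
#'   or single-frame [Hyperstack-class] objects.
#' @param params a [regParams] list.
#' @param voxelSize micrometres per voxel (taken from the Hyperstack when
#'   one is supplied).
#' @param direction integer(2) frame annotation stored in the field.
#' @return list with `field` (a [TransformField-class]) and `target`
#'   (final target-function value).
#' @export
registerPair <- function(reference, moving, params = regParams(),
                         voxelSize = c(1, 1, 1),
                         direction = c(1L, 2L)) {
  if (is(reference, "Hyperstack")) {
    voxelSize <- reference@voxelSize
    reference <- intensity(reference, 1L)
  }
  if (is(moving, "Hyperstack")) moving <- intensity(moving, 1L)
  if (!all(dim(reference) == dim(moving)))
    stop("reference and moving frames must share shape")
  if (!all(is.finite(reference)) || !all(is.finite(moving)))
    stop("non-finite intensities")
  d <- dim(reference)
  L <- params$levels
  ctrl <- NULL
  prev <- NULL
  for (lev in seq_len(L)) {
    f <- 2^(L - lev)
    dl <- pmax(4L, as.integer(round(d / f)))
    if (lev == L) dl <- d
    refL <- array(cpp_resize3(as.numeric(reference), d, dl, 1L), dl)
    movL <- array(cpp_resize3(as.numeric(moving), d, dl, 1L), dl)
    voxL <- mean(voxelSize * d / dl)
    spacing <- max(2, round(params$gridSpacing / voxL))
    ncd <- latticeDims(dl, spacing)
    ctrl <- matrix(0, prod(ncd), 3)
    if (!is.null(prev)) {
      # warm start: sample the coarser displacement field at the new
      # control positions (coefficient ~ value approximation; the level's
      # own optimisation corrects the residual)
      grid <- as.matrix(expand.grid(x = seq_len(ncd[1]) - 2L,
                                    y = seq_len(ncd[2]) - 2L,
                                    z = seq_len(ncd[3]) - 2L)) * spacing
      scale <- prev$dl / dl              # per-axis cur -> prev coords
      gridPrev <- sweep(grid, 2, scale, "*")
      disp <- cpp_ffd_disp_points(gridPrev, prev$ctrl, prev$ncd,
                                  prev$spacing, as.numeric(prev$dl))
      ctrl <- sweep(disp, 2, scale, "/")
    }
    res <- optimizeLevel(refL, movL, ctrl, ncd, spacing, params)
    prev <- list(ctrl = res$ctrl, ncd = ncd, spacing = spacing, dl = dl)
  }
  field <- new("TransformField", ctrl = prev$ctrl, lattice = prev$ncd,
               spacing = prev$spacing, domain = as.integer(d),
               direction = as.integer(direction),
               voxelSize = rep_len(as.numeric(voxelSize), 3L))
  list(field = field, target = res$cost)
}

#' Evaluate a transform field at points
#'
#' Maps positions from the field's reference frame to the moving frame by
#' cubic B-spline interpolation of the control displacements. Positions
#' outside the voxel domain are clamped to the boundary and flagged.
#'
#' @param field a [TransformField-class].
#' @param points numeric matrix (n x 3), micrometres (or voxels with
#'   `units = "voxel"`, 0-based).
#' @param units `"um"` or `"voxel"`.
#' @return matrix of mapped positions with attribute `"outOfDomain"`
#'   (logical vector).
#' @export
transformPoints <- function(field, points, units = c("um", "voxel")) {
  units <- match.arg(units)
  points <- rbindMatrix(points)
  v <- if (units == "um") worldToVoxel(points, field@voxelSize) else points
  dom <- field@domain
  oob <- v[, 1] < -0.5 | v[, 2] < -0.5 | v[, 3] < -0.5 |
    v[, 1] > dom[1] - 0.5 | v[, 2] > dom[2] - 0.5 | v[, 3] > dom[3] - 0.5
  vc <- pmin(pmax(v, -0.5), matrix(dom - 0.5, nrow(v), 3, byrow = TRUE))
  disp <- cpp_ffd_disp_points(vc, field@ctrl, field@lattice, field@spacing,
                              as.numeric(dom))
  out <- vc + disp
  if (units == "um") out <- voxelToWorld(out, field@voxelSize)
  attr(out, "outOfDomain") <- oob
  out
}

rbindMatrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  storage.mode(points) <- "double"
  points
}

#' Register a whole sequence into a TransformSet
#'
#' With `bidirectional = TRUE` (the default) registration starts at the
#' midpoint anchor `floor(N/2)` (0-based; frame `floor(N/2) + 1` in R
#' indexing) and proceeds outward in both directions, which roughly halves
#' the worst-case accumulated propagation error relative to anchoring at
#' the first frame. With `bidirectional = FALSE` the anchor is frame 1 and
#' all fields run forward.
#'
#' @param stack a single-channel [Hyperstack-class] with `t >= 2`.
#' @param params a [regParams] list.
#' @param bidirectional logical.
#' @param verbose print per-pair progress.
#' @return A [TransformSet-class].
#' @export
registerSequence <- function(stack, params = regParams(),
                             bidirectional = TRUE, verbose = FALSE) {
  n <- nFrames(stack)
  if (n < 2L) stop("registerSequence needs at least 2 frames")
  anchor <- if (bidirectional) as.integer(floor(n / 2) + 1L) else 1L
  forward <- list()
  backward <- list()
  if (anchor < n)
    for (i in anchor:(n - 1L)) {
      if (verbose) message(sprintf("registering %d -> %d", i, i + 1L))
      forward[[i - anchor + 1L]] <-
        registerPair(intensity(stack, i), intensity(stack, i + 1L), params,
                     stack@voxelSize, direction = c(i, i + 1L))$field
    }
  if (anchor > 1L)
    for (i in anchor:2L) {
      if (verbose) message(sprintf("registering %d -> %d", i, i - 1L))
      backward[[anchor - i + 1L]] <-
        registerPair(intensity(stack, i), intensity(stack, i - 1L), params,
                     stack@voxelSize, direction = c(i, i - 1L))$field
    }
  new("TransformSet", forward = forward, backward = backward,
      anchor = anchor, nFrames = as.integer(n))
}

#' Propagate points through a TransformSet
#'
#' Applies the chain of pairwise fields to carry positions from frame
#' `from` to frame `to`. The chain must run away from the anchor (the set
#' stores anchor-outward fields only); propagating from the anchor reaches
#' every frame.
#'
#' @param points n x 3 matrix of positions (micrometres by default).
#' @param tset a [TransformSet-class].
#' @param from,to frame indices (1-based).
#' @param units `"um"` or `"voxel"`.
#' @return matrix of positions at frame `to`, with attribute
#'   `"outOfDomain"` flagging points clamped anywhere along the chain.
#' @export
propagatePoints <- function(points, tset, from, to,
                            units = c("um", "voxel")) {
  units <- match.arg(units)
  points <- rbindMatrix(points)
  oob <- rep(FALSE, nrow(points))
  if (from == to) {
    attr(points, "outOfDomain") <- oob
    return(points)
  }
  a <- tset@anchor
  if (to > from) {
    if (from < a)
      stop("no forward fields below the anchor; propagate from the anchor")
    idx <- (from:(to - 1L)) - a + 1L
    chain <- tset@forward[idx]
  } else {
    if (from > a)
      stop("no backward fields above the anchor; propagate from the anchor")
    idx <- a - (from:(to + 1L)) + 1L
    chain <- tset@backward[idx]
  }
  for (f in chain) {
    points <- transformPoints(f, points, units)
    oob <- oob | attr(points, "outOfDomain")
  }
  attr(points, "outOfDomain") <- oob
  points
}

#' Warp a binary mask through a transform field
#'
#' Pushes the mask forward through the field: the output voxel at `x` is
#' foreground when the field's inverse image of `x` lies inside the input
#' mask (linear interpolation of the 0/1 field, threshold 0.5). The
#' inverse is found by fixed-point iteration, which converges for the
#' smooth moderate fields the registration produces.
#'
#' @param mask a [BinaryMask-class] on the field's reference frame.
#' @param field a [TransformField-class].
#' @return Warped [BinaryMask-class].
#' @export
applyTransformToMask <- function(mask, field) {
  d <- dim(mask@voxels)
  if (!all(d == field@domain)) stop("mask and field domain mismatch")
  grid <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                                y = seq_len(d[2]) - 1,
                                z = seq_len(d[3]) - 1))
  y <- grid
  for (i in 1:10) {
    disp <- cpp_ffd_disp_points(y, field@ctrl, field@lattice, field@spacing,
                                as.numeric(d))
    yNew <- grid - disp
    if (max(abs(yNew - y)) < 1e-3) { y <- yNew; break }
    y <- yNew
  }
  vals <- cpp_sample_trilinear(as.numeric(mask@voxels), d, y)
  initialize(mask, voxels = array(vals >= 0.5, d))
}

#' TransformSet archive I/O
#'
#' Serialises a TransformSet as a single binary archive: a JSON header
#' (anchor, frame count, per-field lattice dimensions, spacings, domains
#' and directions) followed by the raw little-endian control lattices.
#'
#' @param tset a [TransformSet-class].
#' @param path archive path (conventionally `.mmr`).
#' @return `path` invisibly (write); a [TransformSet-class] (read).
#' @export
writeTransformSet <- function(tset, path) {
  fields <- c(tset@forward, tset@backward)
  header <- list(
    anchor = tset@anchor, nFrames = tset@nFrames,
    nForward = length(tset@forward), nBackward = length(tset@backward),
    fields = lapply(fields, function(f)
      list(lattice = f@lattice, spacing = f@spacing, domain = f@domain,
           direction = f@direction, voxelSize = f@voxelSize)))
  hdr <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(hdr))
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  for (f in fields)
    writeBin(as.numeric(f@ctrl), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeTransformSet
#' @export
readTransformSet <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)),
                            simplifyVector = FALSE)
  fields <- lapply(hdr$fields, function(h) {
    lattice <- as.integer(unlist(h$lattice))
    ctrl <- matrix(readBin(con, "numeric", prod(lattice) * 3, size = 8,
                           endian = "little"), ncol = 3)
    new("TransformField", ctrl = ctrl, lattice = lattice,
        spacing = as.numeric(h$spacing),
        domain = as.integer(unlist(h$domain)),
        direction = as.integer(unlist(h$direction)),
        voxelSize = as.numeric(unlist(h$voxelSize)))
  })
  nf <- hdr$nForward
  new("TransformSet",
      forward = if (nf > 0) fields[seq_len(nf)] else list(),
      backward = if (hdr$nBackward > 0) fields[nf + seq_len(hdr$nBackward)]
                 else list(),
      anchor = as.integer(hdr$anchor), nFrames = as.integer(hdr$nFrames))
}

#' Downscale a stack for registration at a fixed physical grid spacing
#'
#' Cubic-interpolation downscale to a fraction of the original resolution;
#' the matching control-grid spacing in voxels keeps the physical spacing
#' at about 10 micrometres: fractions 0.10, 0.15, 0.20, 0.25 map to 2, 3,
#' 3 and 4 voxels. Other fractions are accepted with a warning and a
#' spacing computed from the physical 10 micrometres.
#'
#' @param stack a [Hyperstack-class].
#' @param fraction resolution fraction.
#' @return list with `stack` (downscaled) and `gridVoxels`.
#' @export
downscaleForRegistration <- function(stack, fraction) {
  table <- c(`0.1` = 2L, `0.15` = 3L, `0.2` = 3L, `0.25` = 4L)
  key <- as.character(fraction)
  d <- dim(stack@data)
  newDims <- pmax(4L, as.integer(round(d[1:3] * fraction)))
  newVox <- stack@voxelSize * d[1:3] / newDims
  if (key %in% names(table)) {
    grid <- table[[key]]
  } else {
    warning("unsupported fraction; grid spacing computed from 10 um")
    grid <- max(2L, as.integer(round(10 / mean(newVox))))
  }
  out <- array(0, c(newDims, d[4], d[5]))
  for (t in seq_len(d[5]))
    for (ch in seq_len(d[4]))
      out[, , , ch, t] <- array(
        cpp_resize3(as.numeric(stack@data[, , , ch, t]), d[1:3], newDims, 2L),
        newDims)
  list(stack = initialize(stack, data = out, voxelSize = newVox,
                          isotropic = diff(range(newVox)) <= 1e-9,
                          meta = c(stack@meta, list(downscale = fraction))),
       gridVoxels = as.integer(grid))
}
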