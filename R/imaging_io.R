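#' @include AllGenerics.R
NULL

#' Construct a Hyperstack from an array
#'
#' Accepts a 3D (x, y, z), 4D (x, y, z, t) or 5D (x, y, z, channel, t)
#' array. A 4D array is interpreted as single-channel.
#'
#' @param data numeric array.
#' @param voxelSize micrometres per voxel along x, y, z.
#' @param timeStep minutes between frames.
#' @param meta optional provenance list.
#' @return A [Hyperstack-class].
#' @export
hyperstack <- function(data, voxelSize, timeStep = 1, meta = list()) {
  nd <- length(dim(data))
  if (nd == 3L) dim(data) <- c(dim(data), 1L, 1L)
  else if (nd == 4L) {
    d <- dim(data)
    dim(data) <- c(d[1:3], 1L, d[4])
  } else if (nd != 5L)
    stop("data must be a 3D, 4D or 5D array")
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  new("Hyperstack", data = data, voxelSize = voxelSize,
      timeStep = as.numeric(timeStep),
      isotropic = diff(range(voxelSize)) <= 1e-9, meta = meta)
}

#' Construct a BinaryMask
#'
#' @param voxels logical (or coercible) 3D array.
#' @param voxelSize micrometres per voxel.
#' @param frameIndex frame the mask segments (1-based).
#' @return A [BinaryMask-class].
#' @export
binaryMask <- function(voxels, voxelSize, frameIndex = 1L) {
  storage.mode(voxels) <- "logical"
  new("BinaryMask", voxels = voxels,
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      frameIndex = as.integer(frameIndex))
}

#' Read a multi-page TIFF time-lapse into a Hyperstack
#'
#' Pages are expected in ImageJ hyperstack order with channel fastest, then
#' z, then time (`axisOrder = "xyczt"`), or plain z-then-time for
#' single-channel stacks (`axisOrder = "xyzt"`). The time axis must be
#' declared: a 3D-only stack is rejected.
#'
#' @param path TIFF file.
#' @param nFrames number of time points (required, >= 2 for registration).
#' @param nChannels number of channels per page group.
#' @param axisOrder `"xyzt"` or `"xyczt"`.
#' @param voxelSize micrometres per voxel (x, y, z).
#' @param timeStep minutes between frames.
#' @return A [Hyperstack-class].
#' @export
loadHyperstack <- function(path, nFrames, nChannels = 1L,
                           axisOrder = c("xyzt", "xyczt"),
                           voxelSize = c(1, 1, 1), timeStep = 1) {
  axisOrder <- match.arg(axisOrder)
  if (missing(nFrames) || is.null(nFrames) || nFrames < 1L)
    stop("time axis required: declare nFrames")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (axisOrder == "xyzt") nChannels <- 1L
  npage <- length(pages)
  if (npage %% (nFrames * nChannels) != 0L)
    stop(sprintf("page count %d incompatible with %d frames x %d channels",
                 npage, nFrames, nChannels))
  nz <- npage %/% (nFrames * nChannels)
  if (nFrames < 2L && nz > 1L && npage == nz)
    stop("time axis required")
  p1 <- pages[[1]]
  if (length(dim(p1)) == 3L) p1 <- p1[, , 1]
  ny <- nrow(p1); nx <- ncol(p1)
  arr <- array(0, c(nx, ny, nz, nChannels, nFrames))
  k <- 1L
  for (t in seq_len(nFrames))
    for (z in seq_len(nz))
      for (ch in seq_len(nChannels)) {
        pg <- pages[[k]]
        if (length(dim(pg)) == 3L) pg <- pg[, , 1]
        arr[, , z, ch, t] <- t(pg)   # rows are y, columns are x
        k <- k + 1L
      }
  hyperstack(arr, voxelSize, timeStep, meta = list(source = path))
}

#' Write a Hyperstack to a multi-page float TIFF
#'
#' Pages are written channel-fastest, then z, then time, matching
#' [loadHyperstack]'s `"xyczt"` convention. 32-bit float pages preserve
#' values exactly for intensities in \[0, 1\].
#'
#' @param stack a [Hyperstack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHyperstack <- function(stack, path) {
  d <- dim(stack@data)
  pages <- vector("list", d[3] * d[4] * d[5])
  k <- 1L
  for (t in seq_len(d[5]))
    for (z in seq_len(d[3]))
      for (ch in seq_len(d[4])) {
        pages[[k]] <- t(stack@data[, , z, ch, t])
        k <- k + 1L
      }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Merge two channels into one
#'
#' Combines a two-channel acquisition into the single-channel intensity
#' volume the registration stages consume. `"sum"` adds the channels,
#' clips at 1 and rescales each frame to \[0, 1\]; `"max"` takes the
#' voxelwise maximum and rescales likewise.
#'
#' @param stack two-channel [Hyperstack-class].
#' @param mode `"sum"` or `"max"`.
#' @return Single-channel [Hyperstack-class].
#' @export
mergeChannels <- function(stack, mode = c("sum", "max")) {
  if (!is.character(mode) || !all(mode %in% c("sum", "max")))
    stop("unknown merge mode; supported modes: sum, max")
  mode <- match.arg(mode)
  if (nChannels(stack) != 2L)
    stop("mergeChannels needs a 2-channel stack")
  d <- dim(stack@data)
  out <- array(0, c(d[1:3], 1L, d[5]))
  for (t in seq_len(d[5])) {
    a <- stack@data[, , , 1L, t]
    b <- stack@data[, , , 2L, t]
    m <- if (mode == "sum") pmin(a + b, 1) else pmax(a, b)
    out[, , , 1L, t] <- rescale01(m)
  }
  initialize(stack, data = out,
             meta = c(stack@meta, list(channelMerge = mode)))
}

# per-frame [0,1] rescale; a constant frame maps to all zeros by convention
rescale01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(array(0, dim(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Resample an anisotropic stack to isotropic voxels
#'
#' Live acquisitions have fine in-plane resolution `a` and a coarser axial
#' step `b >= a`; new z slices are added by nearest-neighbour interpolation
#' so no new intensity values are invented. In-plane anisotropy is not
#' supported.
#'
#' @param stack a [Hyperstack-class].
#' @return Isotropic [Hyperstack-class] with voxel `a` on all axes.
#' @export
resampleIsotropic <- function(stack) {
  vs <- stack@voxelSize
  if (abs(vs[1] - vs[2]) > 1e-9)
    stop("in-plane anisotropy (x != y) unsupported")
  if (vs[3] < vs[1] - 1e-9)
    stop("axial voxel must not be finer than in-plane voxel")
  if (stack@isotropic) return(stack)
  d <- dim(stack@data)
  nzNew <- max(1L, as.integer(round(d[3] * vs[3] / vs[1])))
  out <- array(0, c(d[1], d[2], nzNew, d[4], d[5]))
  for (t in seq_len(d[5]))
    for (ch in seq_len(d[4])) {
      v <- cpp_resize3(as.numeric(stack@data[, , , ch, t]), d[1:3],
                       c(d[1], d[2], nzNew), 0L)
      out[, , , ch, t] <- array(v, c(d[1], d[2], nzNew))
    }
  initialize(stack, data = out, voxelSize = rep(vs[1], 3),
             isotropic = TRUE,
             meta = c(stack@meta, list(resampled = TRUE)))
}

#' Preprocess an isotropic Hyperstack
#'
#' Optional crop, 3D Gaussian smoothing (default sigma 0.5 voxels), and a
#' per-frame intensity rescale to \[0, 1\] that also mitigates
#' photobleaching. An optional 90-degree rotation about the y axis
#' (x -> z, z -> -x) is applied and recorded in the metadata.
#'
#' @param stack isotropic [Hyperstack-class].
#' @param sigma Gaussian sigma in voxels; 0 skips smoothing.
#' @param crop `NULL` or list with 1-based inclusive index ranges
#'   `x`, `y`, `z` (each `c(lo, hi)`).
#' @param rotateY90 logical; rotate the volume 90 degrees about y.
#' @return Preprocessed [Hyperstack-class].
#' @export
preprocessHyperstack <- function(stack, sigma = 0.5, crop = NULL,
                                 rotateY90 = FALSE) {
  if (!stack@isotropic)
    stop("preprocessHyperstack expects an isotropic stack")
  dat <- stack@data
  d <- dim(dat)
  if (!is.null(crop)) {
    for (ax in c("x", "y", "z")) {
      rng <- crop[[ax]]
      i <- match(ax, c("x", "y", "z"))
      if (is.null(rng)) next
      if (rng[1] < 1L || rng[2] > d[i] || rng[1] > rng[2])
        stop("crop box outside volume")
    }
    gx <- if (is.null(crop$x)) seq_len(d[1]) else crop$x[1]:crop$x[2]
    gy <- if (is.null(crop$y)) seq_len(d[2]) else crop$y[1]:crop$y[2]
    gz <- if (is.null(crop$z)) seq_len(d[3]) else crop$z[1]:crop$z[2]
    dat <- dat[gx, gy, gz, , , drop = FALSE]
    d <- dim(dat)
  }
  out <- array(0, d)
  for (t in seq_len(d[5]))
    for (ch in seq_len(d[4])) {
      v <- dat[, , , ch, t]
      if (sigma > 0)
        v <- array(cpp_gauss3(as.numeric(v), d[1:3], sigma), d[1:3])
      out[, , , ch, t] <- rescale01(v)
    }
  meta <- c(stack@meta, list(sigma = sigma))
  if (rotateY90) {
    out <- aperm(out, c(3, 2, 1, 4, 5))
    out <- out[dim(out)[1]:1, , , , , drop = FALSE]
    meta$rotatedY90 <- TRUE
  }
  initialize(stack, data = out, meta = meta)
}

#' Correct stage drift by translational cross-correlation
#'
#' Each frame is rigidly translated (integer voxels) to maximise its
#' cross-correlation with the previously corrected frame, a translational
#' stand-in for block-matching stage-drift correction. Rotation correction
#' is intentionally not performed: translation dominates stage drift and
#' keeps this stage deterministic.
#'
#' @param stack a [Hyperstack-class] with at least 2 frames.
#' @param channel channel used to estimate shifts (applied to all).
#' @return list with `stack` (corrected) and `shifts`, a data.frame of the
#'   applied per-frame corrections in voxels.
#' @export
correctDrift <- function(stack, channel = 1L) {
  d <- dim(stack@data)
  if (d[5] < 2L) stop("correctDrift needs at least 2 frames")
  out <- stack@data
  shifts <- matrix(0L, d[5], 3)
  for (t in 2:d[5]) {
    ref <- out[, , , channel, t - 1L]
    mov <- out[, , , channel, t]
    sh <- ccShift3(ref, mov)
    shifts[t, ] <- sh
    if (any(sh != 0L))
      for (ch in seq_len(d[4]))
        out[, , , ch, t] <- shiftArray3(out[, , , ch, t], sh)
  }
  list(stack = initialize(stack, data = out,
                          meta = c(stack@meta, list(driftCorrected = TRUE))),
       shifts = data.frame(frame = seq_len(d[5]), dx = shifts[, 1],
                           dy = shifts[, 2], dz = shifts[, 3]))
}

# integer shift maximising circular cross-correlation of mov against ref;
# returns the translation to APPLY to mov
ccShift3 <- function(ref, mov) {
  fa <- fft(ref)
  fb <- fft(mov)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  pk <- which.max(cc)
  d <- dim(ref)
  idx <- arrayInd(pk, d) - 1L
  # unwrap to signed shifts
  sh <- ifelse(idx > d / 2, idx - d, idx)
  as.integer(sh)
}

# shift a 3D array by integer voxels with zero fill
shiftArray3 <- function(a, sh) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    s <- sh[i]
    if (s >= 0) {
      if (s >= d[i]) return(out)
      src[[i]] <- 1:(d[i] - s); dst[[i]] <- (1 + s):d[i]
    } else {
      if (-s >= d[i]) return(out)
      src[[i]] <- (1 - s):d[i]; dst[[i]] <- 1:(d[i] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Fill enclosed cavities in a binary mask
#'
#' Closes gaps up to `maxGap` voxels (morphological closing with a
#' 6-connected structuring element) and fills background cavities not
#' connected to the volume border. Foreground never shrinks.
#'
#' @param mask a [BinaryMask-class].
#' @param maxGap maximum gap, in voxels, to close (default 1).
#' @return A filled [BinaryMask-class].
#' @export
fillHoles <- function(mask, maxGap = 1L) {
  m <- mask@voxels
  d <- dim(m)
  grown <- m
  for (i in seq_len(maxGap)) grown <- dilate6(grown)
  bg <- array(cpp_flood_background(as.logical(grown), d), d)
  filled <- grown | (!grown & !bg)
  for (i in seq_len(maxGap)) filled <- erode6(filled)
  initialize(mask, voxels = filled | m)
}

dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

erode6 <- function(m) !dilate6(!m)

#' Read / write binary masks as NIfTI-1
#'
#' The affine encodes the voxel size; world coordinates follow the same
#' micrometre frame as the meshes.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param mask a [BinaryMask-class] (for writing).
#' @param frameIndex frame annotation for the loaded mask.
#' @return [BinaryMask-class] (read) or `path` invisibly (write).
#' @export
readMask <- function(path, frameIndex = 1L) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  binaryMask(array(as.array(img) != 0, dim(img)[1:3]), vs, frameIndex)
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask@voxels), dim(mask@voxels)),
                         pixdim = mask@voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}
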