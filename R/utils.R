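#' @include AllClasses.R
NULL

#' World / voxel coordinate conversion
#'
#' The single authority for coordinate conversion in the package: voxel
#' index `i` (0-based) is centred at world position `(i + 0.5) * voxelSize`
#' micrometres. All meshes, landmarks and tracks live in world
#' (micrometre) coordinates; all image operations work in voxel indices.
#'
#' @param x n x 3 matrix (world micrometres or voxel indices).
#' @param voxelSize micrometres per voxel (length 1 or 3).
#' @return n x 3 matrix in the other frame.
#' @export
worldToVoxel <- function(x, voxelSize) {
  x <- rbindMatrix(x)
  sweep(x, 2, rep_len(voxelSize, 3L), "/") - 0.5
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(x, voxelSize) {
  x <- rbindMatrix(x)
  sweep(x + 0.5, 2, rep_len(voxelSize, 3L), "*")
}

vnorm <- function(v) sqrt(sum(v * v))

rowNorms <- function(m) sqrt(rowSums(m * m))

# rotation matrix about a unit axis by angle (radians)
rotationMatrix <- function(axis, angle) {
  a <- axis / vnorm(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * (a %*% t(a))
}
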