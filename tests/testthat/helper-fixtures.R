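# shared fixtures, all generated in code

# digital ball mask of radius r voxels in a cube of side n
ballMask <- function(n = 45L, r = 15, voxel = 1) {
  ctr <- (n - 1) / 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  vox <- array(sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) <= r,
               c(n, n, n))
  binaryMask(vox, voxel)
}

# flat regular grid mesh in the xy plane (n x n cells, unit spacing)
gridMesh <- function(n = 10L, spacing = 1) {
  g <- expand.grid(x = 0:n, y = 0:n)
  V <- cbind(g$x, g$y, 0) * spacing
  id <- function(i, j) i + 1L + (n + 1L) * j
  F <- NULL
  for (j in 0:(n - 1L))
    for (i in 0:(n - 1L)) {
      F <- rbind(F, c(id(i, j), id(i + 1L, j), id(i, j + 1L)),
                 c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L)))
    }
  surfaceMesh(V, F)
}

# small blob test volume for registration tests
blobVolume <- function(n = 32L, centres, sigma = 4) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  v <- 0
  for (k in seq_len(nrow(centres)))
    v <- v + exp(-((g$x - centres[k, 1])^2 + (g$y - centres[k, 2])^2 +
                     (g$z - centres[k, 3])^2) / (2 * sigma^2))
  array(v / max(v), c(n, n, n))
}

# an identity TransformSet with n frames (zero fields, unit voxel)
identityTset <- function(n, dim = c(24L, 24L, 24L), anchor = NULL) {
  if (is.null(anchor)) anchor <- as.integer(floor(n / 2) + 1L)
  spacing <- 6
  ncd <- as.integer(floor((dim - 1) / spacing) + 4L)
  mk <- function(from, to)
    new("TransformField", ctrl = matrix(0, prod(ncd), 3), lattice = ncd,
        spacing = spacing, domain = as.integer(dim),
        direction = as.integer(c(from, to)), voxelSize = c(1, 1, 1))
  fw <- list(); bw <- list()
  if (anchor < n) for (i in anchor:(n - 1L)) fw[[i - anchor + 1L]] <- mk(i, i + 1L)
  if (anchor > 1L) for (i in anchor:2L) bw[[anchor - i + 1L]] <- mk(i, i - 1L)
  new("TransformSet", forward = fw, backward = bw, anchor = anchor,
      nFrames = as.integer(n))
}

# a TransformSet implementing a constant +d voxel flow along x per forward
# step (and -d along the backward chain), on a unit-voxel domain
constantFlowTset <- function(n, d = 2, dim = c(48L, 24L, 24L)) {
  anchor <- as.integer(floor(n / 2) + 1L)
  spacing <- 6
  ncd <- as.integer(floor((dim - 1) / spacing) + 4L)
  mk <- function(from, to, dx)
    new("TransformField", ctrl = cbind(rep(dx, prod(ncd)), 0, 0),
        lattice = ncd, spacing = spacing, domain = as.integer(dim),
        direction = as.integer(c(from, to)), voxelSize = c(1, 1, 1))
  fw <- list(); bw <- list()
  if (anchor < n) for (i in anchor:(n - 1L)) fw[[i - anchor + 1L]] <- mk(i, i + 1L, d)
  if (anchor > 1L) for (i in anchor:2L) bw[[anchor - i + 1L]] <- mk(i, i - 1L, -d)
  new("TransformSet", forward = fw, backward = bw, anchor = anchor,
      nFrames = as.integer(n))
}

rotMat <- function(axis, angle) morphomap:::rotationMatrix(axis, angle)

vnorm3 <- function(v) sqrt(sum(v^2))

# a generic non-degenerate landmark configuration
exampleLandmarks <- function() {
  rbind(c(0, 0, 0), c(4, 0, 0), c(1, 1, 0), c(1, 7, 0),
        c(0, 2, 1), c(4, 2, 1), c(2, 5, 3))
}

angleBetweenRotations <- function(A, B) {
  acos(min(1, max(-1, (sum(diag(A %*% t(B))) - 1) / 2))) * 180 / pi
}
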