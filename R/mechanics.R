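#' @include mesh.R
NULL

#' Local 2D frame of a triangle
#'
#' Builds the 2x2 edge matrix of a triangle in an orthonormal in-plane
#' basis obtained by Gram-Schmidt on the edge vectors `e1 = r2 - r1`,
#' `e2 = r3 - r1`. The basis columns reproduce the 3D edges exactly:
#' `basis %*% edgeMatrix` equals `cbind(e1, e2)`.
#'
#' @param vertices 3 x 3 matrix, one vertex per row.
#' @return list with `edgeMatrix` (2x2), `basis` (3x2), `origin`, and
#'   `degenerate` flag.
#' @export
triangleFrame <- function(vertices) {
  vertices <- rbindMatrix(vertices)
  e1 <- vertices[2, ] - vertices[1, ]
  e2 <- vertices[3, ] - vertices[1, ]
  n1 <- vnorm(e1)
  tol <- 1e-12
  if (n1 < tol)
    return(list(edgeMatrix = matrix(0, 2, 2), basis = matrix(0, 3, 2),
                origin = vertices[1, ], degenerate = TRUE))
  b1 <- e1 / n1
  p <- e2 - sum(e2 * b1) * b1
  n2 <- vnorm(p)
  if (n2 < tol || triArea(vertices, matrix(1:3, 1)) < 1e-9)
    return(list(edgeMatrix = matrix(0, 2, 2), basis = matrix(0, 3, 2),
                origin = vertices[1, ], degenerate = TRUE))
  b2 <- p / n2
  em <- matrix(c(sum(e1 * b1), 0, sum(e2 * b1), sum(e2 * b2)), 2, 2)
  list(edgeMatrix = em, basis = cbind(b1, b2), origin = vertices[1, ],
       degenerate = FALSE)
}

#' Deformation gradient between two triangle frames
#'
#' `F = T R^-1` maps rest edge coordinates to deformed edge coordinates,
#' with `R` and `T` the rest and deformed 2x2 edge matrices.
#'
#' @param rest,deformed outputs of [triangleFrame].
#' @return 2x2 matrix.
#' @export
deformationGradient <- function(rest, deformed) {
  if (rest$degenerate) stop("singular rest frame")
  deformed$edgeMatrix %*% solve(rest$edgeMatrix)
}

#' Growth rate of a deformation gradient
#'
#' `J = det(F)`, the local area ratio deformed/rest: 1 for isochoric
#' (area-preserving) deformation, above 1 for expansion, below 1 for
#' compression.
#'
#' @param F 2x2 deformation gradient.
#' @return numeric.
#' @export
growthRate <- function(F) det(F)

#' Green-Lagrange strain tensor
#'
#' `eps = (F^T F - I) / 2`, symmetric by construction.
#'
#' @param F 2x2 deformation gradient.
#' @return symmetric 2x2 matrix.
#' @export
strainTensor <- function(F) 0.5 * (t(F) %*% F - diag(2))

#' Anisotropy ratio and principal stretch direction
#'
#' The principal stretches are the singular values of `F`; the anisotropy
#' ratio is `sigma_max / sigma_min >= 1` (1 for isotropic deformation and
#' for any pure rotation). The stretch ratio of singular values is used
#' rather than eigenvalues of the strain tensor, whose ratio is ill-posed
#' when eigenvalues cross zero; both readings agree that uniform scaling
#' gives 1. The principal direction is the right-singular vector of the
#' largest stretch lifted to 3D through the rest-frame basis,
#' sign-normalised.
#'
#' @param F 2x2 deformation gradient.
#' @param frame the rest [triangleFrame] (for the 3D lift); optional.
#' @return list with `theta` (>= 1, `Inf` flagged for singular F) and
#'   `direction` (3D unit vector, or `NULL` without a frame).
#' @export
anisotropy <- function(F, frame = NULL) {
  sv <- svd(F)
  if (sv$d[2] < 1e-12)
    return(list(theta = Inf, direction = NULL, singular = TRUE))
  theta <- sv$d[1] / sv$d[2]
  dir <- NULL
  if (!is.null(frame)) {
    v <- sv$v[, 1]
    dir <- as.vector(frame$basis %*% v)
    # sign convention: largest-magnitude component positive
    i <- which.max(abs(dir))
    if (dir[i] < 0) dir <- -dir
    dir <- dir / vnorm(dir)
  }
  list(theta = theta, direction = dir, singular = FALSE)
}

#' Per-face deformation map between two frames of a Live-Shape
#'
#' Computes the deformation gradient, growth rate J, anisotropy ratio and
#' principal direction for every triangle shared by a rest and a deformed
#' mesh (same topology), then smooths J and the anisotropy by an
#' unweighted mean over the geodesic neighbourhood of each face on the
#' deformed mesh. The map is attached to the deformed-state mesh.
#'
#' @param restMesh,deformedMesh [SurfaceMesh-class] with identical faces.
#' @param smoothingRadius geodesic radius in micrometres (default 20;
#'   0 skips smoothing).
#' @param interval annotation of the (rest, deformed) pair.
#' @return A [DeformationMap-class].
#' @export
deformationMap <- function(restMesh, deformedMesh, smoothingRadius = 20,
                           interval = c(1, 2)) {
  if (!all(restMesh@faces == deformedMesh@faces))
    stop("rest and deformed meshes must share topology")
  Fc <- restMesh@faces
  nf <- nrow(Fc)
  Fm <- matrix(NA_real_, nf, 4)
  J <- theta <- rep(NA_real_, nf)
  dirs <- matrix(NA_real_, nf, 3)
  degen <- rep(FALSE, nf)
  for (f in seq_len(nf)) {
    rf <- triangleFrame(restMesh@vertices[Fc[f, ], ])
    df <- triangleFrame(deformedMesh@vertices[Fc[f, ], ])
    if (rf$degenerate || df$degenerate) {
      degen[f] <- TRUE
      next
    }
    Ff <- deformationGradient(rf, df)
    Fm[f, ] <- as.vector(Ff)
    J[f] <- growthRate(Ff)
    an <- anisotropy(Ff, rf)
    theta[f] <- an$theta
    if (!is.null(an$direction)) dirs[f, ] <- an$direction
  }
  if (any(degen))
    warning(sum(degen), " degenerate face(s) excluded from the map")
  Js <- J
  ths <- theta
  if (smoothingRadius > 0 && nf > 1L) {
    g <- faceGraph(deformedMesh)
    block <- 512L
    for (s in seq(1L, nf, by = block)) {
      rows <- s:min(nf, s + block - 1L)
      D <- igraph::distances(g, v = rows)
      for (k in seq_along(rows)) {
        nb <- which(D[k, ] <= smoothingRadius & !degen)
        if (length(nb)) {
          Js[rows[k]] <- mean(J[nb])
          ths[rows[k]] <- mean(theta[nb])
        }
      }
    }
  }
  new("DeformationMap", F = Fm, J = J, theta = theta, direction = dirs,
      Jsmooth = Js, thetaSmooth = ths, mesh = deformedMesh,
      interval = interval, degenerate = degen)
}

#' Export a deformation map as a data frame
#'
#' @param map a [DeformationMap-class].
#' @return data.frame with one row per face.
#' @export
deformationTable <- function(map) {
  data.frame(face = seq_along(map@J), J = map@J, theta = map@theta,
             dirX = map@direction[, 1], dirY = map@direction[, 2],
             dirZ = map@direction[, 3], Jsmooth = map@Jsmooth,
             thetaSmooth = map@thetaSmooth, degenerate = map@degenerate)
}

#' Export a deformation map as PLY with per-face scalars
#'
#' ASCII PLY carrying `J`, `theta` and their smoothed versions as float
#' face properties, for external mesh viewers.
#'
#' @param map a [DeformationMap-class].
#' @param path output file.
#' @return `path` invisibly.
#' @export
writeDeformationPLY <- function(map, path) {
  V <- map@mesh@vertices
  F <- map@mesh@faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property double x", "property double y",
               "property double z",
               paste("element face", nrow(F)),
               "property list uchar int vertex_indices",
               "property float J", "property float theta",
               "property float J_smooth", "property float theta_smooth",
               "end_header"), con)
  writeLines(paste(V[, 1], V[, 2], V[, 3]), con)
  writeLines(paste(3L, F[, 1], F[, 2], F[, 3],
                   map@J, map@theta, map@Jsmooth, map@thetaSmooth), con)
  invisible(path)
}

#' Cosine similarity of two undirected axes
#'
#' Absolute value of the dot product of the unit vectors, so antiparallel
#' axes score 1 and orthogonal axes 0.
#'
#' @param a,b 3D vectors.
#' @return numeric in \[0, 1\].
#' @export
cosineSimilarity <- function(a, b) {
  abs(sum(a * b)) / (vnorm(a) * vnorm(b))
}

#' Principal deformation axis of a propagated point set
#'
#' Propagates a point set across a frame span and fits a principal line
#' to the displaced points; used to compare tissue elongation axes with,
#' for example, cell-division axes via [cosineSimilarity].
#'
#' @param points n x 3 matrix (n >= 3) at frame `span[1]`.
#' @param tset a [TransformSet-class].
#' @param span integer(2), (from, to).
#' @return list with `axis` (unit 3-vector, undirected), `displaced`
#'   points, and `centre`.
#' @export
fitDeformationAxis <- function(points, tset, span) {
  points <- rbindMatrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  moved <- propagatePoints(points, tset, span[1], span[2])
  cen <- colMeans(moved)
  X <- sweep(moved[, 1:3, drop = FALSE], 2, cen)
  if (max(abs(X)) < 1e-12) stop("degenerate point set")
  sv <- svd(X)
  axis <- sv$v[, 1]
  i <- which.max(abs(axis))
  if (axis[i] < 0) axis <- -axis
  list(axis = axis, displaced = moved, centre = cen)
}
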