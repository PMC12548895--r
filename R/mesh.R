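#' @include utils.R registration.R
NULL

#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 numeric matrix, micrometres.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param provenance free-form list.
#' @return A [SurfaceMesh-class].
#' @export
surfaceMesh <- function(vertices, faces, provenance = list()) {
  vertices <- rbindMatrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  new("SurfaceMesh", vertices = vertices, faces = faces,
      provenance = provenance)
}

#' Extract a smoothed triangular surface from a binary mask
#'
#' The binary field is lightly Gaussian-smoothed (sub-voxel accuracy) and
#' the 0.5 level set extracted by marching tetrahedra, yielding a closed
#' genus-0 surface at the mask boundary. Small stray components (below 5
#' percent of the foreground) are dropped; several large components are an
#' error. An optional target face density re-extracts from a coarsened
#' field.
#'
#' @param mask a [BinaryMask-class], single large connected component.
#' @param targetDensity approximate faces per square micrometre, or `NULL`
#'   to keep the native resolution.
#' @param fieldSigma Gaussian sigma (voxels) applied to the binary field
#'   before extraction.
#' @return A [SurfaceMesh-class] in world micrometres.
#' @export
maskToMesh <- function(mask, targetDensity = NULL, fieldSigma = 1) {
  vox <- mask@voxels
  if (!any(vox)) stop("empty mask")
  d <- dim(vox)
  lab <- cpp_label6(as.logical(vox), d)
  nlab <- attr(lab, "n")
  if (nlab > 1L) {
    sizes <- tabulate(lab, nlab)
    big <- which(sizes >= 0.05 * sum(sizes))
    if (length(big) > 1L)
      stop("multiple large components (sizes: ",
           paste(sort(sizes[big], decreasing = TRUE), collapse = ", "), ")")
    vox <- array(lab == big, d)
  }
  pad <- 2L
  dp <- d + 2L * pad
  field <- array(0, dp)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(vox)
  field <- array(cpp_gauss3(as.numeric(field), dp, fieldSigma), dp)
  scale <- 1
  if (!is.null(targetDensity)) {
    # face density scales with the square of grid resolution; coarsen to
    # approach the requested density from above
    probe <- cpp_march_tets(as.numeric(field), dp, 0.5)
    area0 <- sum(triArea(voxelToWorld(probe$vertices - pad, mask@voxelSize),
                         probe$faces))
    dens0 <- nrow(probe$faces) / area0
    if (dens0 > targetDensity) {
      scale <- sqrt(targetDensity / dens0)
      dn <- pmax(6L, as.integer(round(dp * scale)))
      field <- array(cpp_resize3(as.numeric(field), dp, dn, 1L), dn)
      scale <- mean(dn / dp)
      dp <- dn
    }
  }
  mt <- cpp_march_tets(as.numeric(field), dp, 0.5)
  if (nrow(mt$vertices) == 0L) stop("empty mask")
  vworld <- voxelToWorld(mt$vertices / scale - pad, mask@voxelSize)
  surfaceMesh(vworld, mt$faces,
              provenance = list(source = "maskToMesh",
                                frame = mask@frameIndex,
                                fieldSigma = fieldSigma,
                                targetDensity = targetDensity))
}

triArea <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-face areas of a mesh
#'
#' Half cross-product magnitude per triangle; the sum is the surface area.
#' Degenerate faces (area below 1e-9 square micrometres) yield 0 with a
#' warning.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return numeric vector of areas in square micrometres.
#' @export
faceAreas <- function(mesh) {
  a <- triArea(mesh@vertices, mesh@faces)
  if (any(a < 1e-9))
    warning(sum(a < 1e-9), " degenerate face(s) with zero area")
  a
}

#' Laplacian mesh smoothing
#'
#' Each iteration moves every interior node towards the mean of its
#' one-ring neighbours by weight `alpha`; boundary nodes of open meshes
#' are kept fixed. Defaults follow the usual surface-cleanup setting of
#' 0.9 over 5 iterations.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param alpha smoothing weight in \[0, 1\].
#' @param iterations number of passes.
#' @return Smoothed [SurfaceMesh-class] (topology unchanged).
#' @export
smoothMesh <- function(mesh, alpha = 0.9, iterations = 5L) {
  if (alpha == 0 || iterations == 0L) return(mesh)
  V <- mesh@vertices
  F <- mesh@faces
  n <- nrow(V)
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  und <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  key <- paste(und[, 1], und[, 2])
  boundary <- unique(as.vector(und[key %in% names(which(table(key) == 1)), ]))
  adjI <- c(und[, 1], und[, 2])
  adjJ <- c(und[, 2], und[, 1])
  dup <- duplicated(paste(adjI, adjJ))
  adjI <- adjI[!dup]; adjJ <- adjJ[!dup]
  deg <- tabulate(adjI, n)
  free <- setdiff(seq_len(n), boundary)
  for (it in seq_len(iterations)) {
    nb <- rowsum(V[adjJ, , drop = FALSE], adjI)
    mean_nb <- nb / deg
    V[free, ] <- (1 - alpha) * V[free, , drop = FALSE] +
      alpha * mean_nb[free, , drop = FALSE]
  }
  initialize(mesh, vertices = V,
             provenance = c(mesh@provenance,
                            list(smoothed = c(alpha = alpha,
                                              iterations = iterations))))
}

meshEdges <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Euler characteristic of a mesh
#'
#' `V - E + F`; 2 for a closed genus-0 surface.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return integer.
#' @export
eulerCharacteristic <- function(mesh) {
  und <- meshEdges(mesh@faces)
  ne <- nrow(unique(und))
  nrow(mesh@vertices) - ne + nrow(mesh@faces)
}

#' Boundary edges of a mesh
#'
#' Edges with exactly one incident face, grouped into closed loops.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return list of integer vectors (vertex loops); empty for closed meshes.
#' @export
boundaryLoops <- function(mesh) {
  und <- meshEdges(mesh@faces)
  key <- paste(und[, 1], und[, 2])
  bnd <- und[key %in% names(which(table(key) == 1)), , drop = FALSE]
  bnd <- unique(bnd)
  if (nrow(bnd) == 0L) return(list())
  nxt <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  loops <- list()
  remaining <- unique(as.vector(bnd))
  used <- character()
  while (length(remaining)) {
    start <- remaining[1]
    loop <- start
    cur <- start
    prev <- -1L
    repeat {
      cands <- setdiff(nxt[[as.character(cur)]], prev)
      if (!length(cands)) break
      prev <- cur
      cur <- cands[1]
      if (cur == start) break
      loop <- c(loop, cur)
    }
    loops[[length(loops) + 1L]] <- loop
    remaining <- setdiff(remaining, loop)
  }
  loops
}

#' Close holes in a mesh by fan triangulation
#'
#' Each boundary loop is capped with a fan around its centroid. Used
#' before rasterisation of cut meshes.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return Closed [SurfaceMesh-class].
#' @export
closeMeshHoles <- function(mesh) {
  loops <- boundaryLoops(mesh)
  if (!length(loops)) return(mesh)
  V <- mesh@vertices
  F <- mesh@faces
  for (loop in loops) {
    cen <- colMeans(V[loop, , drop = FALSE])
    V <- rbind(V, cen)
    ci <- nrow(V)
    k <- length(loop)
    newF <- cbind(loop, loop[c(2:k, 1)], rep(ci, k))
    F <- rbind(F, newF)
  }
  initialize(mesh, vertices = V, faces = matrix(as.integer(F), ncol = 3),
             provenance = c(mesh@provenance,
                            list(closedHoles = length(loops))))
}

#' Enclosed volume of a closed mesh
#'
#' Magnitude of the summed signed tetrahedron volumes (divergence
#' theorem); requires consistent orientation, which [maskToMesh] output
#' provides.
#'
#' @param mesh closed [SurfaceMesh-class].
#' @return volume in cubic micrometres.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(rowSums(a * cr)) / 6)
}

#' Rasterise a closed mesh into a filled binary mask
#'
#' The surface is voxelised by parity counting along z columns and the
#' interior filled. An open mesh is an error reporting its boundary
#' loops; run [closeMeshHoles] first.
#'
#' @param mesh closed [SurfaceMesh-class].
#' @param voxelSize micrometres per voxel of the output grid.
#' @param dims optional grid dimensions (voxels); computed from the mesh
#'   extent (plus padding) when `NULL`, assuming non-negative mesh
#'   coordinates.
#' @return A [BinaryMask-class].
#' @export
meshToMask <- function(mesh, voxelSize, dims = NULL) {
  loops <- boundaryLoops(mesh)
  if (length(loops))
    stop("open mesh: ", length(loops), " boundary loop(s) of sizes ",
         paste(lengths(loops), collapse = ", "))
  v <- worldToVoxel(mesh@vertices, voxelSize)
  if (is.null(dims)) dims <- as.integer(ceiling(apply(v, 2, max)) + 2L)
  if (min(v) < -0.51)
    stop("mesh extends below the voxel grid origin; translate it first")
  out <- array(cpp_voxelize(v, mesh@faces, as.integer(dims)), dims)
  binaryMask(out, voxelSize)
}

#' Rasterise a surface into a membrane shell mask
#'
#' Marks voxels within `thickness/2` of the surface (sampled densely on
#' every face). This is the natural mask for thin-sheet tissues and for
#' the mask-based non-rigid morphing step, where open (cut) meshes must
#' still produce a registrable image.
#'
#' @param mesh a [SurfaceMesh-class] (open or closed).
#' @param voxelSize micrometres per voxel.
#' @param thickness shell thickness in micrometres.
#' @param dims optional grid dimensions.
#' @return A [BinaryMask-class].
#' @export
meshToShellMask <- function(mesh, voxelSize, thickness = 3, dims = NULL) {
  pts <- sampleMeshPoints(mesh, spacing = min(rep_len(voxelSize, 3)) * 0.7)
  v <- worldToVoxel(pts, voxelSize)
  if (is.null(dims)) dims <- as.integer(ceiling(apply(v, 2, max)) + 3L)
  r <- thickness / (2 * mean(rep_len(voxelSize, 3)))
  out <- array(cpp_shell_mask(as.integer(dims), v, r), dims)
  binaryMask(out, voxelSize)
}

# quasi-uniform point samples on the mesh surface (deterministic
# barycentric refinement per face, resolution set by `spacing`)
sampleMeshPoints <- function(mesh, spacing) {
  V <- mesh@vertices
  F <- mesh@faces
  areas <- triArea(V, F)
  out <- vector("list", nrow(F))
  for (f in seq_len(nrow(F))) {
    p <- V[F[f, ], , drop = FALSE]
    edge <- max(vnorm(p[2, ] - p[1, ]), vnorm(p[3, ] - p[1, ]),
                vnorm(p[3, ] - p[2, ]))
    k <- max(1L, ceiling(edge / spacing))
    # barycentric lattice with k subdivisions
    ij <- expand.grid(i = 0:k, j = 0:k)
    ij <- ij[ij$i + ij$j <= k, ]
    l1 <- ij$i / k; l2 <- ij$j / k; l3 <- 1 - l1 - l2
    out[[f]] <- cbind(l1 * p[1, 1] + l2 * p[2, 1] + l3 * p[3, 1],
                      l1 * p[1, 2] + l2 * p[2, 2] + l3 * p[3, 2],
                      l1 * p[1, 3] + l2 * p[2, 3] + l3 * p[3, 3])
  }
  do.call(rbind, out)
}

#' Propagate a mesh through a TransformSet into a Live-Shape sequence
#'
#' Applies [propagatePoints] node-wise from the anchor outward; the
#' triangulation never changes, only node positions.
#'
#' @param mesh [SurfaceMesh-class] at the anchor frame.
#' @param tset a [TransformSet-class].
#' @return A [LiveShapeSequence-class] covering every frame.
#' @export
propagateMesh <- function(mesh, tset) {
  n <- tset@nFrames
  a <- tset@anchor
  positions <- vector("list", n)
  flags <- vector("list", n)
  positions[[a]] <- mesh@vertices
  flags[[a]] <- rep(FALSE, nrow(mesh@vertices))
  cur <- mesh@vertices
  oob <- flags[[a]]
  if (a < n)
    for (f in a:(n - 1L)) {
      cur <- propagatePoints(cur, tset, f, f + 1L)
      oob <- oob | attr(cur, "outOfDomain")
      positions[[f + 1L]] <- unname(cur[, 1:3, drop = FALSE])
      flags[[f + 1L]] <- oob
    }
  cur <- mesh@vertices
  oob <- flags[[a]]
  if (a > 1L)
    for (f in a:2L) {
      cur <- propagatePoints(cur, tset, f, f - 1L)
      oob <- oob | attr(cur, "outOfDomain")
      positions[[f - 1L]] <- unname(cur[, 1:3, drop = FALSE])
      flags[[f - 1L]] <- oob
    }
  new("LiveShapeSequence", faces = mesh@faces, positions = positions,
      anchorFrame = a, outOfDomain = flags)
}

#' Extract one frame of a Live-Shape sequence as a mesh
#'
#' @param lss a [LiveShapeSequence-class].
#' @param frame frame index.
#' @return A [SurfaceMesh-class].
#' @export
liveShapeFrame <- function(lss, frame) {
  surfaceMesh(lss@positions[[frame]], lss@faces,
              provenance = list(source = "liveShapeFrame", frame = frame))
}

# face adjacency graph with centroid-distance weights
faceGraph <- function(mesh) {
  F <- mesh@faces
  nf <- nrow(F)
  cent <- faceCentroids(mesh)
  und <- meshEdges(F)
  key <- paste(und[, 1], und[, 2])
  faceOfEdge <- rep(seq_len(nf), 3)
  sp <- split(faceOfEdge, key)
  pairs <- do.call(rbind, lapply(sp[lengths(sp) == 2], function(x) x))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(igraph::make_empty_graph(nf, directed = FALSE))
  pairs <- unique(pairs)
  w <- rowNorms(cent[pairs[, 1], , drop = FALSE] -
                cent[pairs[, 2], , drop = FALSE])
  g <- igraph::make_empty_graph(nf, directed = FALSE)
  igraph::add_edges(g, as.vector(t(pairs)), weight = w)
}

faceCentroids <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' Geodesic face neighbourhood
#'
#' Faces whose centroid-to-centroid shortest-path distance on the
#' face-adjacency graph (edges weighted by Euclidean centroid distance)
#' is at most `radius`. The seed face is always included.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param face seed face index.
#' @param radius geodesic radius in micrometres.
#' @param graph optional precomputed face graph (for repeated queries).
#' @return integer vector of face indices.
#' @export
geodesicNeighbourhood <- function(mesh, face, radius, graph = NULL) {
  nf <- nrow(mesh@faces)
  if (face < 1L || face > nf) stop("invalid face index")
  if (is.null(graph)) graph <- faceGraph(mesh)
  d <- igraph::distances(graph, v = face)[1, ]
  which(d <= radius + 1e-12)
}

# ---- PLY / OFF I/O -------------------------------------------------------

#' Read and write PLY meshes
#'
#' Supports ASCII and binary little-endian PLY with float/double vertex
#' coordinates and triangular faces; [readOFF] reads ASCII OFF.
#'
#' @param path file path.
#' @param mesh a [SurfaceMesh-class] (writing).
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return [SurfaceMesh-class] (read) or `path` invisibly (write).
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!identical(magic, "ply")) stop("not a PLY file")
  fmt <- NULL
  nv <- nf <- 0L
  vprops <- character()
  inVertex <- FALSE
  vtype <- character()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("truncated PLY header")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      inVertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && inVertex && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
      vtype <- c(vtype, tok[2])
    } else if (tok[1] == "end_header") break
  }
  xyz <- match(c("x", "y", "z"), vprops)
  if (any(is.na(xyz))) stop("PLY lacks x/y/z vertex properties")
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int = 4L, int32 = 4L,
             uint = 4L, uint32 = 4L)
  if (fmt == "ascii") {
    vl <- readLines(con, nv)
    vm <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), as.numeric))
    V <- vm[, xyz, drop = FALSE]
    fl <- readLines(con, nf)
    fm <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), as.integer))
    if (any(fm[, 1] != 3L)) stop("only triangular faces supported")
    F <- fm[, 2:4, drop = FALSE] + 1L
  } else if (fmt == "binary_little_endian") {
    V <- matrix(0, nv, 3)
    propSize <- sizes[vtype]
    for (i in seq_len(nv)) {
      row <- numeric(length(vprops))
      for (p in seq_along(vprops)) {
        sz <- propSize[p]
        isFloat <- vtype[p] %in% c("float", "float32", "double", "float64")
        row[p] <- readBin(con, if (isFloat) "numeric" else "integer",
                          1, size = sz, endian = "little")
      }
      V[i, ] <- row[xyz]
    }
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE,
                     endian = "little")
      idx <- readBin(con, "integer", cnt, size = 4, endian = "little")
      if (cnt != 3L) stop("only triangular faces supported")
      F[i, ] <- idx + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  surfaceMesh(V, F, provenance = list(source = path))
}

#' @rdname readPLY
#' @export
writePLY <- function(mesh, path,
                     format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  V <- mesh@vertices
  F <- mesh@faces - 1L
  header <- c("ply", paste("format", format, "1.0"),
              paste("element vertex", nrow(V)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(F)),
              "property list uchar int vertex_indices", "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(V[, 1], V[, 2], V[, 3]), con)
    writeLines(paste(3L, F[, 1], F[, 2], F[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(V)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F[i, ]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname readPLY
#' @export
readOFF <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (trimws(ln[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vm <- do.call(rbind, lapply(strsplit(trimws(ln[3:(2 + nv)]), "\\s+"),
                              as.numeric))
  fm <- do.call(rbind,
                lapply(strsplit(trimws(ln[(3 + nv):(2 + nv + nf)]), "\\s+"),
                       as.integer))
  if (any(fm[, 1] != 3L)) stop("only triangular faces supported")
  surfaceMesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L,
              provenance = list(source = path))
}
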