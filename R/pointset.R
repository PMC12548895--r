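#' @include mesh.R
NULL

#' Similarity transform
#'
#' Rotation (proper orthonormal), translation and positive isotropic
#' scale; maps `x` to `scale * R x + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector (micrometres).
#' @param scale positive scalar.
#' @return list of class `"similarityTransform"`.
#' @export
similarityTransform <- function(rotation = diag(3),
                                translation = c(0, 0, 0), scale = 1) {
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("rotation must be proper orthonormal")
  if (scale <= 0) stop("scale must be positive")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale), class = "similarityTransform")
}

#' @rdname similarityTransform
#' @param transform a `"similarityTransform"`.
#' @param points n x 3 matrix.
#' @export
applySimilarity <- function(transform, points) {
  points <- rbindMatrix(points)
  sweep(points %*% t(transform$rotation) * transform$scale, 2,
        transform$translation, "+")
}

#' @rdname similarityTransform
#' @param a,b two similarity transforms.
#' @export
composeSimilarity <- function(a, b) {
  # (a o b)(x) = a(b(x))
  similarityTransform(a$rotation %*% b$rotation,
                      a$scale * as.vector(a$rotation %*% b$translation) +
                        a$translation,
                      a$scale * b$scale)
}

# weighted similarity Procrustes (Umeyama); P is an M x N weight matrix
# between component points Y (M x 3) and data points X (N x 3)
weightedSimilarity <- function(X, Y, P) {
  Np <- sum(P)
  pm <- rowSums(P)
  pn <- colSums(P)
  muX <- colSums(X * pn) / Np
  muY <- colSums(Y * pm) / Np
  Xh <- sweep(X, 2, muX)
  Yh <- sweep(Y, 2, muY)
  A <- t(Xh) %*% t(P) %*% Yh
  sv <- svd(A)
  C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% C %*% t(sv$v)
  denom <- sum(pm * rowSums(Yh^2))
  s <- sum(diag(C %*% diag(sv$d))) / denom
  if (!is.finite(s) || s <= 0) s <- 1e-8   # degenerate match set
  t_ <- muX - s * as.vector(R %*% muY)
  similarityTransform(R, t_, s)
}

# candidate initial rotations: identity plus every proper rotation that
# maps the source principal frame onto the target principal frame (all
# axis permutations and sign flips, 24 in total) — missing regions can
# reorder principal axes, so pairing by eigenvalue rank is not reliable
initRotations <- function(source, target, mode) {
  if (mode == "identity") return(list(diag(3)))
  es <- eigen(stats::cov(source), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(target), symmetric = TRUE)$vectors
  cands <- list(diag(3))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  for (pm in perms) {
    Ep <- es[, pm]
    for (k in seq_len(nrow(signs))) {
      R0 <- et %*% diag(signs[k, ]) %*% t(Ep)
      if (det(R0) > 0) cands[[length(cands) + 1L]] <- R0
    }
  }
  cands
}

# EM point-set registration over a mixture anchored at transformed source
# points; kernel "student" (heavy-tailed, robust) or "gaussian" (CPD)
emRegister <- function(source, target, nComponents, maxIter, tol, dof,
                       kernel, outlierWeight = 0.1, init = "pca") {
  Ns <- nrow(source)
  Nt <- nrow(target)
  if (Ns < 4L || Nt < 4L) stop("need at least 4 points per cloud")
  cs <- colMeans(source)
  ct <- colMeans(target)
  S <- sweep(source, 2, cs)
  X <- sweep(target, 2, ct)
  for (nm in c("S", "X")) {
    sv <- svd(get(nm))$d
    if (sv[3] < 1e-9 * sv[1])
      warning("degenerate (coplanar/collinear) point cloud: ", nm)
  }
  M <- max(4L, min(Ns, nComponents))
  Y <- S[unique(round(seq(1, Ns, length.out = M))), , drop = FALSE]
  M <- nrow(Y)
  V <- prod(apply(X, 2, function(v) diff(range(v)) + 1e-9))
  s0 <- sqrt(mean(rowSums(X^2)) / mean(rowSums(S^2)))
  emSteps <- function(state, nIter) {
    R <- state$R; s <- state$s; t_ <- state$t; sigma2 <- state$sigma2
    llPrev <- state$ll
    it <- 0L
    for (it in seq_len(nIter)) {
      Yt <- sweep(Y %*% t(R) * s, 2, t_, "+")
      D2 <- cpp_pdist2(Yt, X)
      if (kernel == "student") {
        lognorm <- lgamma((dof + 3) / 2) - lgamma(dof / 2) -
          1.5 * log(dof * pi) - 1.5 * log(sigma2)
        K <- exp(lognorm - (dof + 3) / 2 * log1p(D2 / (dof * sigma2)))
        U <- (dof + 3) / (dof + D2 / sigma2)
      } else {
        K <- exp(-D2 / (2 * sigma2)) / (2 * pi * sigma2)^1.5
        U <- matrix(1, M, Nt)
      }
      denom <- colSums(K) / M + outlierWeight / ((1 - outlierWeight) * V)
      P <- sweep(K / M, 2, denom, "/")
      ll <- sum(log(denom * (1 - outlierWeight))) # up to constants
      W <- P * U
      tr <- weightedSimilarity(X, Y, W)
      R <- tr$rotation
      s <- min(max(tr$scale, s0 / 4), s0 * 4)  # guard scale collapse
      t_ <- tr$translation
      Yt <- sweep(Y %*% t(R) * s, 2, t_, "+")
      D2 <- cpp_pdist2(Yt, X)
      sigma2 <- max(sum(W * D2) / (3 * sum(P)), 1e-8)
      if (is.finite(llPrev) && abs(ll - llPrev) < tol * abs(llPrev)) break
      llPrev <- ll
    }
    list(R = R, s = s, t = t_, sigma2 = sigma2, ll = llPrev, iter = it)
  }
  # robust one-way fit: every target point should sit near the aligned
  # source. A saturating Geman-McClure penalty keeps gross outliers from
  # dominating while still resolving near-symmetric pose ambiguities
  # (small systematic mismatches, e.g. a misaligned seam, stay below the
  # saturation scale and are fully counted)
  d2x <- cpp_pdist2(X, X)
  diag(d2x) <- Inf
  cScale <- 2 * median(sqrt(apply(d2x, 1, min)))
  score <- function(state) {
    Sa <- sweep(S %*% t(state$R) * state$s, 2, state$t, "+")
    dd <- cpp_nn(X, Sa)$distance
    mean(dd^2 / (dd^2 + cScale^2))
  }
  cands <- lapply(initRotations(S, X, init), function(R0) {
    st <- list(R = R0, s = s0, t = c(0, 0, 0), ll = -Inf)
    st$sigma2 <- mean(cpp_pdist2(sweep(Y %*% t(R0) * s0, 2, st$t, "+"),
                                 X)) / 3
    emSteps(st, min(30L, maxIter))
  })
  bestState <- cands[[which.min(vapply(cands, score, 1))]]
  bestState <- emSteps(bestState, maxIter)
  # full transform in world coordinates: x -> s R (x - cs) + t_ + ct
  full <- similarityTransform(
    bestState$R,
    bestState$t + ct - bestState$s * as.vector(bestState$R %*% cs),
    bestState$s)
  aligned <- applySimilarity(full, source)
  list(transform = full, aligned = aligned,
       rmse = mutualNNRMSE(aligned, target), iterations = bestState$iter,
       fit = score(bestState))
}

# RMSE over mutual nearest-neighbour pairs, so deliberately missing
# regions are not penalised
mutualNNRMSE <- function(A, B) {
  ab <- cpp_nn(A, B)
  ba <- cpp_nn(B, A)
  mutual <- which(ba$index[ab$index] == seq_len(nrow(A)))
  if (!length(mutual)) return(Inf)
  sqrt(mean(ab$distance[mutual]^2))
}

#' TMM parameters
#'
#' @param nComponents mixture components; default half the source nodes.
#' @param maxIter EM iteration cap (default 150).
#' @param dof Student's-t degrees of freedom (default 3: heavy tails for
#'   outlier robustness; the value is configurable).
#' @param tol relative log-likelihood change for convergence.
#' @param outlierWeight uniform-component weight.
#' @return list of class `"tmmParams"`.
#' @export
tmmParams <- function(nComponents = NULL, maxIter = 150L, dof = 3,
                      tol = 1e-6, outlierWeight = 0.1) {
  stopifnot(dof > 0)
  structure(list(nComponents = nComponents, maxIter = as.integer(maxIter),
                 dof = dof, tol = tol, outlierWeight = outlierWeight),
            class = "tmmParams")
}

#' Robust rigid/similarity registration with a Student's-t mixture
#'
#' Fits, by expectation-maximisation, a Student's-t mixture centred on
#' the similarity-transformed source points to the target cloud. The
#' heavy-tailed components down-weight outliers and missing regions,
#' which is what makes the alignment robust when one shape lacks parts of
#' the other. Both clouds are centred internally before EM. Candidate
#' initialisations from principal-axis alignment make large rotations
#' recoverable; the best run by mutual-nearest RMSE is returned.
#'
#' @param source,target n x 3 point matrices (or [SurfaceMesh-class]
#'   objects, whose vertices are used).
#' @param params a [tmmParams] list.
#' @param init `"pca"` (default) or `"identity"`.
#' @return list with `transform` (similarityTransform mapping source onto
#'   target), `aligned` source points, `rmse` (mutual nearest pairs) and
#'   `iterations`.
#' @export
tmmRegister <- function(source, target, params = tmmParams(),
                        init = c("pca", "identity")) {
  init <- match.arg(init)
  source <- asPoints(source)
  target <- asPoints(target)
  M <- if (is.null(params$nComponents)) ceiling(nrow(source) / 2)
       else params$nComponents
  emRegister(source, target, M, params$maxIter, params$tol, params$dof,
             "student", params$outlierWeight, init)
}

#' Coherent-point-drift style Gaussian mixture registration
#'
#' Similarity-transform variant with an explicit uniform outlier
#' component; same contract as [tmmRegister].
#'
#' @inheritParams tmmRegister
#' @param nComponents mixture components (default: every source point,
#'   the classic formulation).
#' @param maxIter iteration cap.
#' @param outlierWeight uniform-component weight.
#' @param tol relative log-likelihood tolerance.
#' @export
cpdRegister <- function(source, target, nComponents = NULL,
                        maxIter = 150L, outlierWeight = 0.1, tol = 1e-6,
                        init = c("pca", "identity")) {
  init <- match.arg(init)
  source <- asPoints(source)
  target <- asPoints(target)
  M <- if (is.null(nComponents)) nrow(source) else nComponents
  emRegister(source, target, M, maxIter, tol, NA, "gaussian",
             outlierWeight, init)
}

asPoints <- function(x) {
  if (is(x, "SurfaceMesh")) return(x@vertices)
  if (is(x, "SurfaceMap")) return(x@mesh@vertices)
  rbindMatrix(x)
}

#' Iterative closest point registration
#'
#' Classic nearest-neighbour plus similarity-Procrustes iteration; the
#' objective is monotonically non-increasing but the method can stop in a
#' local minimum under large rotations, which the reported RMSE exposes.
#'
#' @inheritParams tmmRegister
#' @param maxIter iteration cap.
#' @param tol relative RMSE change for convergence.
#' @return list with `transform`, `aligned`, `rmse`, `iterations`.
#' @export
icpRegister <- function(source, target, maxIter = 100L, tol = 1e-8) {
  source <- asPoints(source)
  target <- asPoints(target)
  if (!nrow(source) || !nrow(target)) stop("empty point cloud")
  cur <- source
  total <- similarityTransform()
  rmsePrev <- Inf
  for (it in seq_len(maxIter)) {
    nn <- cpp_nn(cur, target)
    rmse <- sqrt(mean(nn$distance^2))
    if (!is.finite(rmse)) break
    P <- matrix(0, nrow(cur), nrow(target))
    P[cbind(seq_len(nrow(cur)), nn$index)] <- 1
    tr <- weightedSimilarity(target, cur, P)
    if (tr$scale <= 1e-7) break   # degenerate collapse; report as-is
    cur <- applySimilarity(tr, cur)
    total <- composeSimilarity(tr, total)
    if (is.finite(rmsePrev) && rmsePrev - rmse < tol * rmsePrev) break
    rmsePrev <- rmse
  }
  list(transform = total, aligned = cur,
       rmse = mutualNNRMSE(cur, target), iterations = it)
}

#' Remove atlas regions without live correspondence
#'
#' After rigid alignment, atlas nodes farther than `threshold` from every
#' live node are removed together with their incident faces, producing
#' the cut atlas used for mask morphing. The removal record allows
#' reconstruction.
#'
#' @param atlasMesh,liveMesh aligned [SurfaceMesh-class] objects.
#' @param threshold distance in micrometres; default 1.5 times the median
#'   nearest-neighbour spacing of the live mesh. A looser cut retains
#'   atlas margin beyond the live boundary, which the subsequent mask
#'   morph fills by spurious tangential stretching, so the cut is kept
#'   tight.
#' @return list with `mesh` (cut atlas), `removedNodes` (original
#'   indices), `nodeMap` (old index -> new index, NA for removed), and
#'   `threshold`.
#' @export
cutUnmatched <- function(atlasMesh, liveMesh, threshold = NULL) {
  A <- atlasMesh@vertices
  L <- liveMesh@vertices
  if (is.null(threshold)) {
    d2 <- cpp_pdist2(L, L)
    diag(d2) <- Inf
    threshold <- 1.5 * median(sqrt(apply(d2, 1, min)))
  }
  if (threshold <= 0) stop("threshold must be positive")
  nn <- cpp_nn(A, L)
  keep <- nn$distance <= threshold
  if (all(keep))
    return(list(mesh = atlasMesh, removedNodes = integer(),
                nodeMap = seq_len(nrow(A)), threshold = threshold))
  nodeMap <- rep(NA_integer_, nrow(A))
  nodeMap[keep] <- seq_len(sum(keep))
  Fo <- atlasMesh@faces
  fok <- keep[Fo[, 1]] & keep[Fo[, 2]] & keep[Fo[, 3]]
  Fn <- matrix(nodeMap[Fo[fok, , drop = FALSE]], ncol = 3)
  list(mesh = surfaceMesh(A[keep, , drop = FALSE], Fn,
                          provenance = c(atlasMesh@provenance,
                                         list(atlasCut = threshold))),
       removedNodes = which(!keep), nodeMap = nodeMap,
       threshold = threshold)
}

#' Nearest-centroid face-to-face matching
#'
#' Maps every source face to the target face with the nearest centroid
#' (many-to-one allowed), resolving point-density differences between two
#' meshes of the same geometry.
#'
#' @param sourceMesh,targetMesh [SurfaceMesh-class] in one coordinate
#'   frame.
#' @return data.frame with `sourceFace`, `targetFace`, `distance` (um).
#' @export
faceToFaceMatch <- function(sourceMesh, targetMesh) {
  if (!nrow(sourceMesh@faces) || !nrow(targetMesh@faces))
    stop("empty mesh")
  cs <- faceCentroids(sourceMesh)
  ct <- faceCentroids(targetMesh)
  nn <- cpp_nn(cs, ct)
  data.frame(sourceFace = seq_len(nrow(cs)), targetFace = nn$index,
             distance = nn$distance)
}
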