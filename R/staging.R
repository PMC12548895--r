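#' @include mesh.R registration.R
NULL

#' Construct and validate a landmark set
#'
#' Seven anatomical landmarks: pt1/pt2 span the width `w`, pt3/pt4 the
#' height `h`, pt5/pt6 flank pt7 for the landmark angle. Stored as a
#' 7 x 3 matrix with rownames pt1..pt7 (micrometres).
#'
#' @param coords 7 x 3 numeric matrix, rows pt1..pt7.
#' @param replicateCount how many manual placements were medianed.
#' @return the validated matrix with attribute `replicateCount`.
#' @export
landmarkSet <- function(coords, replicateCount = 1L) {
  coords <- rbindMatrix(coords)
  if (nrow(coords) != 7L) stop("exactly 7 landmarks required")
  rownames(coords) <- paste0("pt", 1:7)
  if (vnorm(coords[1, ] - coords[2, ]) < 1e-12)
    stop("pt1 and pt2 coincide")
  if (vnorm(coords[3, ] - coords[4, ]) < 1e-12)
    stop("pt3 and pt4 coincide")
  cr <- crossProd3(coords[5, ] - coords[7, ], coords[6, ] - coords[7, ])
  if (vnorm(cr) < 1e-12) stop("pt5, pt6, pt7 are collinear")
  attr(coords, "replicateCount") <- as.integer(replicateCount)
  coords
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Coordinate-wise median of replicate landmark placements
#'
#' Suppresses single-placement error when landmarks are selected several
#' times (three in routine use).
#'
#' @param replicates list of landmark sets (see [landmarkSet]).
#' @return a [landmarkSet] of medians.
#' @export
medianLandmarks <- function(replicates) {
  if (!length(replicates)) stop("at least one replicate required")
  if (length(unique(vapply(replicates, nrow, 1L))) != 1L)
    stop("inconsistent landmark counts across replicates")
  arr <- simplify2array(replicates)   # 7 x 3 x nrep
  med <- apply(arr, c(1, 2), median)
  landmarkSet(med, replicateCount = length(replicates))
}

#' Axis intersection point of a mesh (pt7)
#'
#' Area-weighted principal component analysis of the mesh nodes (each
#' node weighted by one third of its incident face areas, because faces
#' are not equally sized) defines the longitudinal axis; pt7 is the
#' surface point where that axis, oriented by `orientationHint`, exits
#' the mesh. When the two leading eigenvalues are within 1 percent the
#' axis is ambiguous and a hint is required.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param orientationHint optional 3-vector selecting the axis direction.
#' @return list with `point` (pt7), `axis` (unit vector) and `centre`.
#' @export
axisPoint <- function(mesh, orientationHint = NULL) {
  V <- mesh@vertices
  F <- mesh@faces
  fa <- triArea(V, F)
  w <- numeric(nrow(V))
  for (k in 1:3) {
    s <- rowsum(fa / 3, F[, k])
    w[as.integer(rownames(s))] <- w[as.integer(rownames(s))] + s
  }
  w <- w / sum(w)
  cen <- colSums(V * w)
  Xc <- sweep(V, 2, cen)
  Cw <- t(Xc) %*% (Xc * w)
  eg <- eigen(Cw, symmetric = TRUE)
  if ((eg$values[1] - eg$values[2]) / eg$values[1] < 0.01 &&
      is.null(orientationHint))
    stop("ambiguous principal axis; supply orientationHint")
  axis <- eg$vectors[, 1]
  if (!is.null(orientationHint) && sum(axis * orientationHint) < 0)
    axis <- -axis
  if (is.null(orientationHint) && axis[which.max(abs(axis))] < 0)
    axis <- -axis
  hit <- rayMeshExit(cen, axis, V, F)
  list(point = hit, axis = axis, centre = cen)
}

# farthest intersection of the ray cen + t*axis (t > 0) with the mesh
# (Moller-Trumbore); falls back to the farthest node projection
rayMeshExit <- function(origin, dir, V, F) {
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(v0, 2, origin, "-") * -1
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- (dir[1] * q[, 1] + dir[2] * q[, 2] + dir[3] * q[, 3]) / a
  t_ <- rowSums(e2 * q) / a
  hitOk <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t_ > 0
  if (any(hitOk)) {
    tmax <- max(t_[hitOk])
    return(origin + tmax * dir)
  }
  proj <- sweep(V, 2, origin, "-") %*% dir
  V[which.max(proj), ]
}

#' Morphometric features from a landmark set
#'
#' Width `w = |pt1 - pt2|`, height `h = |pt3 - pt4|`, span
#' `s = |pt5 - pt6|` (a working definition: only h/w is used for
#' staging), and the landmark angle at pt7 subtended by pt5 and pt6.
#' Ratios normalise out specimen size.
#'
#' @param landmarks a [landmarkSet].
#' @return list with `w`, `h`, `s`, `thetaLm` (degrees), `hOverW`,
#'   `hOverS`.
#' @export
computeFeatures <- function(landmarks) {
  lm <- landmarkSet(landmarks,
                    replicateCount =
                      attr(landmarks, "replicateCount") %||% 1L)
  w <- vnorm(lm[1, ] - lm[2, ])
  h <- vnorm(lm[3, ] - lm[4, ])
  s <- vnorm(lm[5, ] - lm[6, ])
  if (s < 1e-12) stop("pt5 and pt6 coincide")
  a <- lm[5, ] - lm[7, ]
  b <- lm[6, ] - lm[7, ]
  ct <- sum(a * b) / (vnorm(a) * vnorm(b))
  thetaLm <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  list(w = w, h = h, s = s, thetaLm = thetaLm,
       hOverW = h / w, hOverS = h / s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Propagate landmarks through a TransformSet
#'
#' Landmarks are annotated once at the anchor frame and carried to every
#' other frame by the motion profile, so per-frame features require no
#' re-annotation.
#'
#' @param landmarks a [landmarkSet] at the anchor frame.
#' @param tset a [TransformSet-class].
#' @return list of per-frame landmark sets.
#' @export
propagateLandmarks <- function(landmarks, tset) {
  n <- tset@nFrames
  a <- tset@anchor
  out <- vector("list", n)
  out[[a]] <- landmarks
  cur <- landmarks
  if (a < n)
    for (f in a:(n - 1L)) {
      cur <- propagatePoints(cur, tset, f, f + 1L)
      out[[f + 1L]] <- landmarkSet(cur)
    }
  cur <- landmarks
  if (a > 1L)
    for (f in a:2L) {
      cur <- propagatePoints(cur, tset, f, f - 1L)
      out[[f - 1L]] <- landmarkSet(cur)
    }
  out
}

#' Correlate a candidate staging feature against a reference parameter
#'
#' Ordinary least squares of the reference staging parameter on the
#' feature; the coefficient of determination ranks candidate features.
#'
#' @param featureValues,referenceValues paired per-specimen scalars.
#' @return list with `r2`, `pValue`, `slope`, `intercept`, `n`.
#' @export
featureReferenceCorrelation <- function(featureValues, referenceValues) {
  if (length(featureValues) != length(referenceValues))
    stop("paired samples required")
  if (length(featureValues) < 3L) stop("need n >= 3")
  if (sd(featureValues) < 1e-12) stop("zero variance in feature")
  fit <- lm(referenceValues ~ featureValues)
  sm <- summary(fit)
  list(r2 = sm$r.squared,
       pValue = sm$coefficients["featureValues", "Pr(>|t|)"],
       slope = coef(fit)[["featureValues"]],
       intercept = coef(fit)[["(Intercept)"]],
       n = length(featureValues))
}

#' Shapiro-Wilk normality check per group
#'
#' Small per-group samples motivate an explicit normality check before
#' modelling each group as a Gaussian; fitting proceeds regardless and
#' the results are reported for the record. Groups with fewer than 3
#' values are skipped with a warning.
#'
#' @param values named list: group label -> numeric vector (3 <= n <= 50
#'   per tested group).
#' @return data.frame with `group`, `n`, `W`, `pValue` (NA when skipped).
#' @export
checkNormality <- function(values) {
  out <- lapply(names(values), function(g) {
    v <- values[[g]]
    if (length(v) < 3L) {
      warning("group ", g, " skipped (n < 3)")
      return(data.frame(group = g, n = length(v), W = NA_real_,
                        pValue = NA_real_))
    }
    sw <- shapiro.test(v)
    data.frame(group = g, n = length(v), W = unname(sw$statistic),
               pValue = sw$p.value)
  })
  do.call(rbind, out)
}

#' Fit the Gaussian-mixture staging model
#'
#' One normal component per atlas group over the staging feature (h/w),
#' parameterised by the per-group sample mean and standard deviation;
#' equal priors (group sizes are small and no prior information exists).
#' Groups are ordered by mean.
#'
#' @param calibration named list: group label -> numeric h/w values
#'   (n >= 2 per group, >= 2 groups).
#' @param boundaryThreshold posterior cutoff applied to uncertain
#'   first/last frames (default 0.75).
#' @param sigmaFloor lower bound for a group standard deviation.
#' @return A [StagingModel-class].
#' @export
fitStagingModel <- function(calibration, boundaryThreshold = 0.75,
                            sigmaFloor = 1e-6) {
  if (length(calibration) < 2L) stop("need at least 2 groups")
  if (anyDuplicated(names(calibration))) stop("overlapping group labels")
  if (any(vapply(calibration, length, 1L) < 2L))
    stop("each group needs n >= 2")
  mu <- vapply(calibration, mean, 1)
  sigma <- vapply(calibration, sd, 1)
  if (any(sigma < sigmaFloor)) {
    warning("zero-variance group(s); sd floored at ", sigmaFloor)
    sigma <- pmax(sigma, sigmaFloor)
  }
  ord <- order(mu)
  k <- length(mu)
  new("StagingModel", groups = names(calibration)[ord], mu = unname(mu[ord]),
      sigma = unname(sigma[ord]), priors = rep(1 / k, k),
      boundaryThreshold = boundaryThreshold)
}

#' Stage a feature trajectory against the atlas groups
#'
#' Computes per-frame posterior probabilities over the atlas groups from
#' the mixture model and assigns each frame to the maximum-posterior
#' group. The maximal leading and trailing runs of frames sharing the
#' first (respectively last) assigned group are treated as uncertain
#' boundary frames: they stay assigned only when their posterior exceeds
#' the model's boundary threshold. Per group, the single frame with the
#' highest posterior is flagged as the representative frame (ties break
#' towards the earlier frame).
#'
#' @param features numeric vector of per-frame h/w values.
#' @param model a [StagingModel-class].
#' @return data.frame with `frame`, `group` (label or "unassigned"),
#'   `posterior` (max posterior), `representative`, plus a `"posteriors"`
#'   attribute (frames x groups matrix).
#' @export
stageSequence <- function(features, model) {
  n <- length(features)
  k <- length(model@groups)
  post <- matrix(0, n, k, dimnames = list(NULL, model@groups))
  finite <- is.finite(features)
  for (j in seq_len(k))
    post[finite, j] <- model@priors[j] *
      dnorm(features[finite], model@mu[j], model@sigma[j])
  rs <- rowSums(post)
  ok <- finite & rs > 0
  post[ok, ] <- post[ok, , drop = FALSE] / rs[ok]
  post[!ok, ] <- NA_real_
  lab <- rep("unassigned", n)
  pmax_ <- rep(NA_real_, n)
  lab[ok] <- model@groups[max.col(post[ok, , drop = FALSE],
                                  ties.method = "first")]
  pmax_[ok] <- apply(post[ok, , drop = FALSE], 1, max)
  # uncertain boundary runs: leading frames sharing the first assigned
  # group and trailing frames sharing the last
  assigned <- which(lab != "unassigned")
  if (length(assigned)) {
    firstGroup <- lab[assigned[1]]
    i <- assigned[1]
    while (i <= n && lab[i] == firstGroup) {
      if (!is.na(pmax_[i]) && pmax_[i] <= model@boundaryThreshold)
        lab[i] <- "unassigned"
      i <- i + 1L
    }
    lastGroup <- lab[assigned[length(assigned)]]
    i <- assigned[length(assigned)]
    while (i >= 1L && lab[i] == lastGroup) {
      if (!is.na(pmax_[i]) && pmax_[i] <= model@boundaryThreshold)
        lab[i] <- "unassigned"
      i <- i - 1L
    }
  }
  rep_ <- rep(FALSE, n)
  for (g in model@groups) {
    idx <- which(lab == g)
    if (length(idx))
      rep_[idx[which.max(pmax_[idx])]] <- TRUE
  }
  out <- data.frame(frame = seq_len(n), group = lab, posterior = pmax_,
                    representative = rep_)
  attr(out, "posteriors") <- post
  out
}

#' Landmark CSV I/O
#'
#' Long format: columns `specimen`, `replicate`, `name` (pt1..pt7), `x`,
#' `y`, `z` in micrometres.
#'
#' @param path CSV file.
#' @return named list (by specimen) of lists of landmark sets (one per
#'   replicate).
#' @export
readLandmarksCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "replicate", "name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (sp in unique(df$specimen)) {
    reps <- list()
    dsp <- df[df$specimen == sp, ]
    for (r in sort(unique(dsp$replicate))) {
      dr <- dsp[dsp$replicate == r, ]
      dr <- dr[match(paste0("pt", 1:7), dr$name), ]
      reps[[length(reps) + 1L]] <-
        landmarkSet(as.matrix(dr[, c("x", "y", "z")]))
    }
    out[[as.character(sp)]] <- reps
  }
  out
}

#' Staging model JSON I/O
#'
#' @param model a [StagingModel-class] (write) / path (read).
#' @param path file path.
#' @return path invisibly (write); [StagingModel-class] (read).
#' @export
writeStagingModel <- function(model, path) {
  jsonlite::write_json(
    list(groups = model@groups, mu = model@mu, sigma = model@sigma,
         priors = model@priors, boundaryThreshold = model@boundaryThreshold),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeStagingModel
#' @export
readStagingModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("StagingModel", groups = j$groups, mu = j$mu, sigma = j$sigma,
      priors = j$priors, boundaryThreshold = j$boundaryThreshold[1])
}
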