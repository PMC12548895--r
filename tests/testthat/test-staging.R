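test_that("landmark validation and replicate medians", {
  lm <- landmarkSet(exampleLandmarks())
  expect_equal(rownames(lm), paste0("pt", 1:7))
  bad <- exampleLandmarks(); bad[2, ] <- bad[1, ]
  expect_error(landmarkSet(bad), "pt1 and pt2")
  coll <- exampleLandmarks()
  coll[5, ] <- c(0, 0, 0); coll[6, ] <- c(1, 1, 1); coll[7, ] <- c(2, 2, 2)
  expect_error(landmarkSet(coll), "collinear")
  # three replicates with an outlier: the median suppresses it
  base <- exampleLandmarks()
  shifted <- base + 0.1
  outlier <- base; outlier[3, ] <- outlier[3, ] + 50
  med <- medianLandmarks(list(base, shifted, outlier))
  expect_equal(med[3, ], shifted[3, ], tolerance = 1e-12)
  expect_equal(attr(med, "replicateCount"), 3L)
  expect_identical(unclass(medianLandmarks(list(base)))[1:21],
                   unclass(landmarkSet(base))[1:21])
  expect_error(medianLandmarks(list()), "at least one")
})

test_that("morphometric features match their definitions", {
  lm <- landmarkSet(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0), c(0, 2, 0),
                          c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  ft <- computeFeatures(lm)
  expect_equal(ft$hOverW, 1)
  expect_equal(ft$thetaLm, 90)
  lm2 <- landmarkSet(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 0, 0), c(0, 6, 0),
                           c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  expect_equal(computeFeatures(lm2)$hOverW, 1.5)
})

test_that("features are rigid-invariant; ratios scale-invariant", {
  set.seed(1)
  lm <- landmarkSet(matrix(rnorm(21, sd = 4), 7, 3))
  f0 <- computeFeatures(lm)
  R <- rotMat(rnorm(3), runif(1, 0, pi))
  lmR <- landmarkSet(sweep(lm %*% t(R), 2, c(3, -1, 2), "+"))
  fR <- computeFeatures(lmR)
  expect_equal(fR$hOverW, f0$hOverW, tolerance = 1e-10)
  expect_equal(fR$thetaLm, f0$thetaLm, tolerance = 1e-8)
  fS <- computeFeatures(landmarkSet(lm * 3.7))
  expect_equal(fS$hOverW, f0$hOverW, tolerance = 1e-10)
  expect_equal(fS$hOverS, f0$hOverS, tolerance = 1e-10)
})

test_that("axis point finds the elongation apex; spheres are ambiguous", {
  p <- sceneParams()
  msh <- sceneMesh(p, 0.8)       # elongated near-tube
  ap <- axisPoint(msh, orientationHint = c(0, 0, 1))
  truth <- surfacePoint(p, 1, 0.5, 0.8)
  expect_lt(vnorm3(ap$point - truth), 2 * max(p$radius1 * 0.35, 2))
  # axis is close to the tube axis (z)
  expect_gt(abs(ap$axis[3]), 0.95)
  sph <- maskToMesh(ballMask(31L, 10))
  expect_error(axisPoint(sph), "ambiguous")
  # elongated box with +x hint lands on the +x end
  box <- gridMesh(10)
  V <- vertices(box); V[, 1] <- V[, 1] * 5
  box <- surfaceMesh(V, faces(box))
  ap2 <- axisPoint(box, orientationHint = c(1, 0, 0))
  expect_gt(ap2$point[1], 0.9 * max(V[, 1]))
})

test_that("landmark propagation keeps ratios under similarity flows", {
  lm <- sceneLandmarks(sceneParams(), 0.3)
  tset <- identityTset(5, dim = c(64L, 64L, 64L))
  out <- propagateLandmarks(lm, tset)
  expect_length(out, 5)
  for (f in 1:5)
    expect_equal(computeFeatures(out[[f]])$hOverW,
                 computeFeatures(lm)$hOverW, tolerance = 1e-9)
})

test_that("feature-reference regression returns R2 and p-values", {
  x <- seq(0.5, 3, length.out = 20)
  # an exact linear relation makes summary.lm grumble; that is the point
  fit <- suppressWarnings(featureReferenceCorrelation(x, 2 * x))
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, 2)
  set.seed(2)
  nullFits <- replicate(20, {
    featureReferenceCorrelation(rnorm(50), rnorm(50))$r2
  })
  expect_lt(mean(nullFits > 0.2), 0.2)
  expect_error(featureReferenceCorrelation(rep(1, 10), rnorm(10)),
               "zero variance")
  expect_error(featureReferenceCorrelation(1:2, 1:2), "n >= 3")
})

test_that("Shapiro-Wilk screening is calibrated and detects bimodality", {
  expect_warning(out <- checkNormality(list(a = c(1, 2), b = rnorm(10))),
                 "skipped")
  expect_true(is.na(out$W[out$group == "a"]))
  set.seed(3)
  # type-I calibration at alpha = 0.05 on small normal samples
  rej <- mean(replicate(2000, shapiro.test(rnorm(6))$p.value < 0.05))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  bim <- c(rnorm(20, -4, 0.5), rnorm(20, 4, 0.5))
  expect_lt(checkNormality(list(g = bim))$pValue, 0.01)
})

test_that("staging model fitting recovers per-group parameters", {
  cal <- list(Gr2 = c(0.9, 1.0, 1.1), Gr3 = c(1.9, 2.0, 2.1))
  m <- fitStagingModel(cal)
  expect_equal(m@mu, c(1, 2))
  expect_equal(m@priors, c(0.5, 0.5))
  expect_error(fitStagingModel(list(a = 1:3)), "2 groups")
  expect_warning(fitStagingModel(list(a = c(1, 1), b = c(2, 2.1))),
                 "floored")
  set.seed(4)
  mus <- seq(1, 3, length.out = 5)
  cal2 <- setNames(lapply(mus, function(m) rnorm(6, m, 0.1)),
                   paste0("G", 1:5))
  m2 <- fitStagingModel(cal2)
  expect_true(all(abs(m2@mu - mus) < 2 * 0.1 / sqrt(6) * 2))
})

test_that("staging assigns frames and applies the boundary rule", {
  m <- fitStagingModel(list(Gr2 = c(0.95, 1.0, 1.05),
                            Gr3 = c(1.95, 2.0, 2.05),
                            Gr4 = c(2.95, 3.0, 3.05)))
  st <- stageSequence(c(1.0, 2.0, 3.0), m)
  expect_equal(st$group, c("Gr2", "Gr3", "Gr4"))
  expect_true(all(st$posterior > 0.99))
  expect_true(all(st$representative))
  # posteriors sum to one
  post <- attr(st, "posteriors")
  expect_equal(rowSums(post), rep(1, 3))
  # an uncertain first frame (posterior <= 0.75) becomes unassigned
  mid <- mean(m@mu[1:2])
  st2 <- stageSequence(c(mid, 2.0, 3.0), m)
  expect_equal(st2$group[1], "unassigned")
  # non-finite features are flagged unassigned
  st3 <- stageSequence(c(NA, 2.0), m)
  expect_equal(st3$group[1], "unassigned")
  # representative frame is the highest-posterior frame per group (use a
  # wide-sigma model so posteriors do not saturate)
  mW <- fitStagingModel(list(Gr2 = c(0.8, 1.0, 1.2), Gr3 = c(1.8, 2.0, 2.2)))
  st4 <- stageSequence(c(1.4, 1.0), mW)
  expect_equal(st4$group, c("Gr2", "Gr2"))
  expect_equal(which(st4$representative), 2L)
})

test_that("well-separated groups are recovered for >= 95% of frames", {
  set.seed(5)
  sigma <- 0.1
  mus <- seq(1, by = 4 * sigma, length.out = 5)   # 4-sigma separation
  cal <- setNames(lapply(mus, function(m) rnorm(6, m, sigma)),
                  paste0("Gr", 2:6))
  model <- fitStagingModel(cal)
  gen <- rep(seq_along(mus), each = 60)
  feats <- rnorm(length(gen), mus[gen], sigma)
  st <- stageSequence(feats, model)
  assigned <- st$group != "unassigned"
  hit <- st$group[assigned] == paste0("Gr", 2:6)[gen[assigned]]
  expect_gte(mean(hit) * mean(assigned), 0.95)
})

test_that("staging model JSON round trip", {
  m <- fitStagingModel(list(Gr2 = c(0.9, 1.1), Gr3 = c(1.9, 2.1)))
  path <- tempfile(fileext = ".json")
  writeStagingModel(m, path)
  back <- readStagingModel(path)
  expect_equal(back@mu, m@mu)
  expect_equal(back@sigma, m@sigma)
  expect_equal(back@groups, m@groups)
})

test_that("landmark CSV reader groups specimens and replicates", {
  df <- expand.grid(replicate = 1:2, name = paste0("pt", 1:7))
  df$specimen <- "e01"
  set.seed(6)
  df$x <- rnorm(14); df$y <- rnorm(14); df$z <- rnorm(14)
  path <- tempfile(fileext = ".csv")
  write.csv(df[, c("specimen", "replicate", "name", "x", "y", "z")], path,
            row.names = FALSE)
  got <- readLandmarksCSV(path)
  expect_named(got, "e01")
  expect_length(got$e01, 2)
  expect_equal(rownames(got$e01[[1]]), paste0("pt", 1:7))
})
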