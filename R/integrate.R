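#' @include fatemap.R validation.R
NULL

#' Integrate a fragmented cohort through the full pipeline
#'
#' Runs the complete integration strategy on a cohort of specimens with
#' overlapping stage windows: stages every specimen by its landmark h/w
#' trajectory against the atlas staging model, projects every staged
#' frame into atlas space, computes each specimen's native stepwise
#' deformation maps, links the stages with a chain of correspondences
#' (averaging across specimens for the cumulative deformation; a single
#' most-complete specimen per transition for the fate map), and returns
#' the cumulative deformation and the Dynamic Atlas.
#'
#' @param cohort a `"syntheticCohort"` (or an equivalently structured
#'   list of specimens with `shapes`, `landmarks`, `stages`, `id`,
#'   `uRange`).
#' @param atlas a `"syntheticAtlas"` (shapes + calibration).
#' @param regPar,tmmPar projection parameters.
#' @param smoothingRadius geodesic smoothing radius (um) for the
#'   deformation maps.
#' @param smoothedJ use smoothed deformation values in the step means.
#' @param verbose print progress.
#' @return list with `model` (the staging model), `staging` (per
#'   specimen), `surfaceMaps` (specimen -> stage label -> SurfaceMap),
#'   `deformationMaps`, `hooks`, `chain`, `stepMeans`, `cumulative`,
#'   `fateMap`, `eye` (reference specimen/stage and point uv if known).
#' @export
integrateCohort <- function(cohort, atlas, regPar = regParams(),
                            tmmPar = tmmParams(), smoothingRadius = 5,
                            smoothedJ = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  nStages <- length(atlas$shapes)
  labels <- vapply(atlas$shapes, function(s) s$stage, "")
  model <- fitStagingModel(atlas$calibration)

  ## 1. stage every specimen
  staging <- lapply(cohort$specimens, function(sp) {
    hw <- vapply(sp$landmarks, function(lm) computeFeatures(lm)$hOverW, 1)
    stageSequence(hw, model)
  })
  names(staging) <- vapply(cohort$specimens, `[[`, "", "id")

  ## 2. project every representative staged frame
  surfaceMaps <- list()
  for (i in seq_along(cohort$specimens)) {
    sp <- cohort$specimens[[i]]
    st <- staging[[i]]
    reps <- st[st$representative, ]
    maps <- list()
    for (k in seq_len(nrow(reps))) {
      g <- match(reps$group[k], labels)
      if (is.na(g)) next
      say(sp$id, " frame ", reps$frame[k], " -> ", reps$group[k])
      live <- liveShapeFrame(sp$shapes, reps$frame[k])
      maps[[labels[g]]] <- projectToAtlas(live, atlas$shapes[[g]],
                                          regPar = regPar, tmmPar = tmmPar,
                                          specimen = sp$id,
                                          frame = reps$frame[k])
    }
    surfaceMaps[[sp$id]] <- maps
  }

  ## 3. native stepwise deformation per specimen per staged transition
  deformationMaps <- list()
  for (i in seq_along(cohort$specimens)) {
    sp <- cohort$specimens[[i]]
    st <- staging[[i]]
    reps <- st[st$representative, ]
    gIdx <- match(reps$group, labels)
    ord <- order(gIdx)
    reps <- reps[ord, ]
    gIdx <- gIdx[ord]
    dm <- list()
    for (k in seq_len(max(0, nrow(reps) - 1L))) {
      if (gIdx[k + 1L] != gIdx[k] + 1L) next
      dm[[as.character(gIdx[k])]] <-
        deformationMap(liveShapeFrame(sp$shapes, reps$frame[k]),
                       liveShapeFrame(sp$shapes, reps$frame[k + 1L]),
                       smoothingRadius = smoothingRadius,
                       interval = labels[c(gIdx[k], gIdx[k] + 1L)])
    }
    deformationMaps[[sp$id]] <- dm
  }

  ## 4. hooks: per transition, specimens with SurfaceMaps at both ends
  hooks <- list()
  for (i in seq_along(cohort$specimens)) {
    sp <- cohort$specimens[[i]]
    maps <- surfaceMaps[[sp$id]]
    for (g in seq_len(nStages - 1L)) {
      if (!is.null(maps[[labels[g]]]) && !is.null(maps[[labels[g + 1L]]]))
        hooks[[length(hooks) + 1L]] <-
          list(specimen = sp$id, from = g, to = g + 1L,
               smapFrom = maps[[labels[g]]],
               smapTo = maps[[labels[g + 1L]]],
               span = diff(sp$uRange %||% c(0, 1)))
    }
  }

  ## 5. eye: the specimen with the widest staged coverage, central window
  nMapped <- vapply(surfaceMaps, length, 1L)
  centre <- vapply(cohort$specimens, function(sp) mean(sp$stages), 1)
  eyeIdx <- order(-nMapped, abs(centre - (nStages + 1) / 2))[1]
  eyeSpec <- cohort$specimens[[eyeIdx]]
  eyeStages <- match(names(surfaceMaps[[eyeSpec$id]]), labels)
  eyeStage <- eyeStages[ceiling(length(eyeStages) / 2)]
  eyeMap <- surfaceMaps[[eyeSpec$id]][[labels[eyeStage]]]
  chain <- buildChain(eyeMap@mesh@vertices, eyeStage, hooks, nStages,
                      mode = "average")

  ## 6. mean stepwise deformation and cumulative products
  stepMeans <- list()
  for (g in seq_len(nStages - 1L)) {
    if (!chain$covered[g + 1L]) next
    embryoMaps <- list()
    for (id in names(deformationMaps)) {
      dm <- deformationMaps[[id]][[as.character(g)]]
      if (is.null(dm)) next
      embryoMaps[[length(embryoMaps) + 1L]] <-
        list(map = dm, smapTo = surfaceMaps[[id]][[labels[g + 1L]]])
    }
    if (!length(embryoMaps)) next
    stepMeans[[as.character(g)]] <-
      meanStepwiseDeformation(chain, g, embryoMaps, smoothed = smoothedJ)
  }
  gs <- as.integer(names(stepMeans))
  cumulative <- if (length(stepMeans))
    cumulativeDeformation(stepMeans, interval = c(min(gs), max(gs) + 1L))
  else NULL

  ## 7. fate map: single most-complete specimen per transition
  pathHooks <- list()
  for (g in seq_len(nStages - 1L)) {
    hg <- Filter(function(h) h$from == g, hooks)
    if (!length(hg)) next
    spans <- vapply(hg, function(h) h$span %||% 1, 1)
    pathHooks[[length(pathHooks) + 1L]] <- hg[[which.max(spans)]]
  }
  fateMap <- tryCatch(
    buildFateMap(eyeMap@mesh@vertices, eyeStage, pathHooks, nStages),
    error = function(e) {
      warning("fate map build failed: ", conditionMessage(e))
      NULL
    })

  list(model = model, staging = staging, surfaceMaps = surfaceMaps,
       deformationMaps = deformationMaps, hooks = hooks, chain = chain,
       stepMeans = stepMeans, cumulative = cumulative, fateMap = fateMap,
       eye = list(specimen = eyeSpec$id, stage = eyeStage,
                  uv = eyeSpec$uv, index = eyeIdx))
}
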