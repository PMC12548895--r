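#' @include synthetic.R validation.R mapping.R
NULL

pipelineStages <- c("simulate", "render", "preprocess", "register",
                    "mesh", "deformation")

#' Validate a pipeline configuration
#'
#' Schema, path and parameter-range checks for a YAML pipeline
#' configuration; never runs any computation. A configuration is a list
#' with `seed`, `output` (directory) and `stages` (ordered list of
#' `{name, params}` blocks).
#'
#' @param config a list or a path to a YAML file.
#' @return list with `valid` (logical) and `problems` (character).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      return(list(valid = FALSE,
                  problems = paste("config file not found:", config)))
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  stages <- config$stages %||% list()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    nm <- st$name %||% "<missing>"
    if (!nm %in% pipelineStages) {
      sugg <- pipelineStages[which.min(utils::adist(nm, pipelineStages))]
      problems <- c(problems,
                    sprintf("stage %d: unknown name '%s' (did you mean '%s'?)",
                            i, nm, sugg))
      next
    }
    p <- st$params %||% list()
    if (nm == "register") {
      if (!is.null(p$lambda) && p$lambda < 0)
        problems <- c(problems,
                      sprintf("stage %d (register): lambda must be >= 0", i))
      if (!is.null(p$levels) && p$levels < 1)
        problems <- c(problems,
                      sprintf("stage %d (register): levels must be >= 1", i))
    }
    if (nm == "preprocess" && !is.null(p$sigma) && p$sigma < 0)
      problems <- c(problems,
                    sprintf("stage %d (preprocess): sigma must be >= 0", i))
    if (!is.null(p$input) && !file.exists(p$input) &&
        !any(vapply(stages[seq_len(i - 1)], function(s)
          identical(s$params$output, p$input), TRUE)))
      problems <- c(problems,
                    sprintf("stage %d (%s): input not found: %s",
                            i, nm, p$input))
  }
  if (!is.null(config$seed) && (!is.numeric(config$seed) ||
                                config$seed != round(config$seed)))
    problems <- c(problems, "seed must be an integer")
  list(valid = length(problems) == 0L, problems = problems)
}

#' Run a configured pipeline
#'
#' Executes the stages in order, writing every stage's outputs and a
#' provenance JSON (inputs, parameters, seed, package version) under the
#' configured output directory. Existing stage outputs are reused so
#' partial runs resume. The first failing stage aborts with its name.
#'
#' @param config list or YAML path (see [validateConfig]).
#' @param quiet suppress progress messages.
#' @return invisibly, a list of per-stage results / output paths.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  chk <- validateConfig(config)
  if (!chk$valid)
    stop("invalid configuration:\n  ",
         paste(chk$problems, collapse = "\n  "))
  outDir <- config$output %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message(...)
  state <- list()
  results <- list()
  provenance <- list(seed = seed,
                     version = as.character(utils::packageVersion("morphomap")),
                     stages = list())
  for (st in config$stages %||% list()) {
    nm <- st$name
    p <- st$params %||% list()
    say("stage: ", nm)
    res <- tryCatch(switch(nm,
      simulate = {
        sp <- do.call(sceneParams, p[names(p) %in% names(formals(sceneParams))])
        state$scene <- makeScene(sp, seed)
        list(frames = sp$nFrames)
      },
      render = {
        r <- renderStack(state$scene)
        state$stack <- r$stack
        state$tracks <- r$tracks
        path <- file.path(outDir, p$output %||% "stack.tif")
        writeHyperstack(r$stack, path)
        write.csv(r$tracks, file.path(outDir, "tracks.csv"),
                  row.names = FALSE)
        list(stack = path)
      },
      preprocess = {
        stk <- if (!is.null(p$input))
          loadHyperstack(p$input, nFrames = p$nFrames,
                         voxelSize = p$voxelSize %||% c(1, 1, 1))
        else state$stack
        stk <- resampleIsotropic(stk)
        state$stack <- preprocessHyperstack(stk, sigma = p$sigma %||% 0.5)
        list(dims = dim(state$stack@data))
      },
      register = {
        rp <- regParams(gridSpacing = p$gridSpacing %||% 10,
                        lambda = p$lambda %||% 0.01,
                        tol = p$tol %||% 1e-8,
                        maxIter = p$maxIter %||% 100L,
                        levels = p$levels %||% 4L)
        state$tset <- registerSequence(state$stack, rp,
                                       bidirectional =
                                         p$bidirectional %||% TRUE)
        list(anchor = state$tset@anchor)
      },
      mesh = {
        msh <- if (!is.null(p$mask))
          maskToMesh(readMask(p$mask))
        else liveShapeFrame(state$scene$shapes,
                            state$scene$shapes@anchorFrame)
        msh <- smoothMesh(msh, p$alpha %||% 0.9, p$iterations %||% 5L)
        state$mesh <- msh
        if (!is.null(state$tset))
          state$liveShape <- propagateMesh(msh, state$tset)
        writePLY(msh, file.path(outDir, p$output %||% "shape.ply"))
        list(nodes = nrow(msh@vertices))
      },
      deformation = {
        lss <- state$liveShape %||% state$scene$shapes
        dm <- deformationMap(liveShapeFrame(lss, p$from %||% 1L),
                             liveShapeFrame(lss, p$to %||% nFrames(lss)),
                             smoothingRadius = p$smoothingRadius %||% 20)
        write.csv(deformationTable(dm),
                  file.path(outDir, p$output %||% "deformation.csv"),
                  row.names = FALSE)
        state$deformation <- dm
        list(medianJ = median(dm@J, na.rm = TRUE))
      }),
      error = function(e)
        stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
             call. = FALSE))
    results[[nm]] <- res
    provenance$stages[[length(provenance$stages) + 1L]] <-
      list(name = nm, params = p, result = res)
  }
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
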