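#' @include registration.R synthetic.R
NULL

trackFrame <- function(tracks, f) {
  tr <- tracks[tracks$frame == f & !tracks$dividing, ]
  list(pos = as.matrix(tr[, c("x", "y", "z")]), cell = tr$cell)
}

#' Stepwise propagation error against ground-truth tracks
#'
#' For every consecutive frame pair, each ground-truth position is
#' propagated one step through the matching pairwise field and compared
#' to the next ground-truth position (Euclidean distance, micrometres).
#' Below the anchor the backward fields are used (later frame propagated
#' to the earlier one). Dividing cells are excluded; cells missing a
#' frame are skipped and counted.
#'
#' @param tracks data.frame with `cell`, `frame`, `x`, `y`, `z`,
#'   `dividing`.
#' @param tset a [TransformSet-class].
#' @return list of class `"errorReport"`: `perPoint` (cell, frame pair,
#'   error), `perFrame` summaries, `overall` (mean/median/sd), `skipped`.
#' @export
stepwiseError <- function(tracks, tset) {
  a <- tset@anchor
  n <- tset@nFrames
  rows <- list()
  skipped <- 0L
  addPair <- function(fRef, fTarget, field) {
    gRef <- trackFrame(tracks, fRef)
    gTar <- trackFrame(tracks, fTarget)
    common <- intersect(gRef$cell, gTar$cell)
    skipped <<- skipped + length(setdiff(gRef$cell, common))
    if (!length(common)) return()
    pr <- transformPoints(field, gRef$pos[match(common, gRef$cell), ,
                                          drop = FALSE])
    err <- rowNorms(pr[, 1:3, drop = FALSE] -
                    gTar$pos[match(common, gTar$cell), , drop = FALSE])
    rows[[length(rows) + 1L]] <<-
      data.frame(cell = common, pair = min(fRef, fTarget), error = err)
  }
  if (a < n)
    for (f in a:(n - 1L)) addPair(f, f + 1L, tset@forward[[f - a + 1L]])
  if (a > 1L)
    for (f in a:2L) addPair(f, f - 1L, tset@backward[[a - f + 1L]])
  perPoint <- do.call(rbind, rows)
  summariseErrors(perPoint, "pair", skipped)
}

summariseErrors <- function(perPoint, by, skipped = 0L) {
  perFrame <- do.call(rbind, lapply(split(perPoint, perPoint[[by]]),
    function(d) data.frame(frame = d[[by]][1], mean = mean(d$error),
                           median = median(d$error), sd = sd(d$error),
                           n = nrow(d))))
  structure(list(perPoint = perPoint, perFrame = perFrame,
                 overall = list(mean = mean(perPoint$error),
                                median = median(perPoint$error),
                                sd = sd(perPoint$error)),
                 skipped = skipped),
            class = "errorReport")
}

#' Accumulated propagation error from the anchor
#'
#' The anchor-frame ground-truth positions are propagated sequentially
#' outward and compared to the ground truth at every frame. Also reports
#' the error normalised by each cell's true displacement over the same
#' span, and the least-squares slope of the per-frame median error
#' against time.
#'
#' @param tracks ground-truth tracks (see [stepwiseError]).
#' @param tset a [TransformSet-class].
#' @param timeStep minutes per frame (for the slope).
#' @return an `"errorReport"` with extra fields `normalized` (data.frame)
#'   and `slope` (um per minute).
#' @export
accumulatedError <- function(tracks, tset, timeStep = 1) {
  a <- tset@anchor
  n <- tset@nFrames
  g0 <- trackFrame(tracks, a)
  rows <- list()
  run <- function(dir) {
    cur <- g0$pos
    fs <- if (dir > 0) seq(a, n - 1L) else seq(a, 2L)
    if (dir > 0 && a >= n) return()
    if (dir < 0 && a <= 1L) return()
    for (f in fs) {
      nxt <- f + dir
      cur <- propagatePoints(cur, tset, f, nxt)[, 1:3, drop = FALSE]
      gt <- trackFrame(tracks, nxt)
      common <- intersect(g0$cell, gt$cell)
      i0 <- match(common, g0$cell)
      err <- rowNorms(cur[i0, , drop = FALSE] -
                      gt$pos[match(common, gt$cell), , drop = FALSE])
      disp <- rowNorms(gt$pos[match(common, gt$cell), , drop = FALSE] -
                       g0$pos[i0, , drop = FALSE])
      rows[[length(rows) + 1L]] <<-
        data.frame(cell = common, frame = nxt, error = err,
                   displacement = disp)
    }
  }
  run(+1L)
  run(-1L)
  perPoint <- do.call(rbind, rows)
  rep_ <- summariseErrors(perPoint, "frame")
  rep_$perPoint$time <- abs(rep_$perPoint$frame - a) * timeStep
  ok <- perPoint$displacement > 1e-9
  rep_$normalized <- data.frame(cell = perPoint$cell[ok],
                                frame = perPoint$frame[ok],
                                value = perPoint$error[ok] /
                                  perPoint$displacement[ok])
  med <- rep_$perFrame
  med$time <- abs(med$frame - a) * timeStep
  rep_$slope <- if (nrow(med) >= 2L)
    unname(coef(lm(median ~ time, data = med))[2]) else NA_real_
  rep_$anchor <- a
  rep_
}

#' Misregistration rate at a diameter threshold
#'
#' Fraction of point-frames whose error exceeds the average cell
#' diameter (20 micrometres by default).
#'
#' @param report an `"errorReport"`.
#' @param diameter threshold in micrometres.
#' @return numeric fraction in \[0, 1\].
#' @export
misregistrationRate <- function(report, diameter = 20) {
  if (!nrow(report$perPoint)) stop("empty error report")
  mean(report$perPoint$error > diameter)
}

#' Write an error report as CSV plus a JSON summary
#'
#' @param report an `"errorReport"`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
writeErrorReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$perPoint, file.path(dir, "errors.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(overall = report$overall,
                            perFrame = report$perFrame,
                            slope = report$slope %||% NULL),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Accuracy / cost sweep across registration resolutions
#'
#' Registers the stack at each resolution fraction (grid spacing per
#' [downscaleForRegistration]) and reports error statistics and wall
#' time. Times are informational only.
#'
#' @param stack single-channel [Hyperstack-class].
#' @param tracks ground-truth tracks.
#' @param fractions resolution fractions.
#' @param params base [regParams]; grid spacing stays at its physical
#'   value.
#' @return data.frame with one row per fraction.
#' @export
resolutionSweep <- function(stack, tracks,
                            fractions = c(0.10, 0.15, 0.20, 0.25),
                            params = regParams()) {
  out <- lapply(fractions, function(fr) {
    tm <- system.time({
      ds <- downscaleForRegistration(stack, fr)
      tset <- registerSequence(ds$stack, params)
      sw <- stepwiseError(tracks, tset)
      ac <- accumulatedError(tracks, tset, stack@timeStep)
    })
    data.frame(fraction = fr, gridVoxels = ds$gridVoxels,
               meanStepwise = sw$overall$mean,
               medianStepwise = sw$overall$median,
               maxAccumulated = max(ac$perFrame$mean),
               misregistration = misregistrationRate(ac),
               wallTime = unname(tm["elapsed"]))
  })
  do.call(rbind, out)
}

#' Coherent-flow versus cell-mixing control
#'
#' Compares accumulated tracking error between a coherently moving
#' tissue and a mixing tissue (random tangential walks): per-interval
#' median errors are binned in time and fitted by least squares; the
#' slope ratio quantifies how much faster error accumulates under
#' mixing. Also compares the displacement-normalised errors.
#'
#' @param coherentTracks,mixingTracks ground-truth track tables.
#' @param tsetC,tsetM matching [TransformSet-class] objects.
#' @param timeStep minutes per frame.
#' @param binMinutes time bin width for the median fits (default 20).
#' @return list with `slopeCoherent`, `slopeMixing`, `ratio`,
#'   `normalizedCoherent`, `normalizedMixing`.
#' @export
mixingControl <- function(coherentTracks, mixingTracks, tsetC, tsetM,
                          timeStep = 1, binMinutes = 20) {
  fitSlope <- function(rep_) {
    pp <- rep_$perPoint
    if (length(unique(pp$time)) < 3L)
      stop("span too short for a slope fit (< 3 intervals)")
    bin <- floor(pp$time / binMinutes) * binMinutes + binMinutes / 2
    med <- tapply(pp$error, bin, median)
    x <- as.numeric(names(med))
    unname(coef(lm(med ~ x))[2])
  }
  repC <- accumulatedError(coherentTracks, tsetC, timeStep)
  repM <- accumulatedError(mixingTracks, tsetM, timeStep)
  sc <- fitSlope(repC)
  sm <- fitSlope(repM)
  list(slopeCoherent = sc, slopeMixing = sm, ratio = sm / sc,
       normalizedCoherent = mean(repC$normalized$value),
       normalizedMixing = mean(repM$normalized$value))
}
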