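#' Define a synthetic landscape + survey scenario
#'
#' The defaults describe the study system the package was built to emulate:
#' a rugged limestone-mountain scree field of roughly 1 km extent surveyed
#' at 10 m resolution, with a strongly unbalanced survey (7 presences, 37
#' absences) in which presences concentrate in concave microsites — cells
#' with LOW topographic position index, where avalanche snow and meltwater
#' collect.
#'
#' @param nrows,ncols grid dimensions (>= 16 each; default 96 x 96).
#' @param cellsize cell edge in meters (default 10).
#' @param reliefSd standard deviation of the random relief in meters
#'   (default 25, a strongly dissected scree slope at this scale).
#' @param correlationLength Gaussian smoothing scale in cells (default 5,
#'   i.e. 50 m gully-and-rib structure).
#' @param rampGrad regional gradient c(gx, gy) in m/m added to the field
#'   (default c(0.25, 0.35): a mountainside rising to the north-east, so
#'   slopes drain mostly south-west and no cell is perfectly flat).
#' @param baseElevation mean elevation, meters (default 1900, alpine scree
#'   belt).
#' @param nPresence,nAbsence survey sizes (defaults 7 and 37).
#' @param effectPredictor which predictor drives presence placement
#'   (default `"tpi"`; `"none"` for a null scenario).
#' @param effectBeta logistic coefficient on the z-scored predictor
#'   (default 3; positive = presences at low values).
#' @param seed RNG seed.
#' @return a [Scenario-class].
#' @export
scenario <- function(nrows = 96L, ncols = 96L, cellsize = 10,
                     reliefSd = 25, correlationLength = 5,
                     rampGrad = c(0.25, 0.35), baseElevation = 1900,
                     nPresence = 7L, nAbsence = 37L,
                     effectPredictor = "tpi", effectBeta = 3,
                     seed = 1L) {
  new("Scenario",
      nrows = as.integer(nrows), ncols = as.integer(ncols),
      cellsize = as.numeric(cellsize), reliefSd = as.numeric(reliefSd),
      correlationLength = as.numeric(correlationLength),
      rampGrad = as.numeric(rampGrad),
      baseElevation = as.numeric(baseElevation),
      nPresence = as.integer(nPresence), nAbsence = as.integer(nAbsence),
      effectPredictor = effectPredictor,
      effectBeta = as.numeric(effectBeta), seed = as.integer(seed))
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: %d x %d cells @ %g m, relief sd %g m, corr. length %g cells\n",
              object@nrows, object@ncols, object@cellsize, object@reliefSd,
              object@correlationLength))
  cat(sprintf("  survey: %d presences / %d absences; effect: %s (beta = %g); seed %d\n",
              object@nPresence, object@nAbsence, object@effectPredictor,
              object@effectBeta, object@seed))
  invisible(object)
})

#' Serialise / restore a Scenario as JSON
#'
#' Every simulated fixture carries its scenario for provenance.
#'
#' @param sc a [Scenario-class].
#' @param path output (input) JSON path.
#' @return `writeScenario`: `path` invisibly; `readScenario`: a
#'   [Scenario-class].
#' @export
writeScenario <- function(sc, path) {
  stopifnot(is(sc, "Scenario"))
  fields <- sapply(slotNames(sc), function(s) slot(sc, s), simplify = FALSE)
  jsonlite::write_json(fields, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  f <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scenario, f[c("nrows", "ncols", "cellsize", "reliefSd",
                        "correlationLength", "rampGrad", "baseElevation",
                        "nPresence", "nAbsence", "effectPredictor",
                        "effectBeta", "seed")])
}

# Separable Gaussian smoothing of a padded white-noise field. The kernel is
# truncated at 4 sigma; padding by the truncation radius keeps the smoothing
# exact (no edge shrinkage) and perfectly reproducible for a given seed.
.smoothedNoise <- function(nrows, ncols, sigma) {
  m <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-m, m), sd = sigma)
  k <- k / sum(k)
  noise <- matrix(stats::rnorm((nrows + 2 * m) * (ncols + 2 * m)),
                  nrows + 2 * m, ncols + 2 * m)
  bandMatrix <- function(nOut, nIn) {
    A <- matrix(0, nOut, nIn)
    for (i in seq_len(nOut)) A[i, i:(i + 2 * m)] <- k
    A
  }
  A <- bandMatrix(nrows, nrows + 2 * m)
  B <- bandMatrix(ncols, ncols + 2 * m)
  A %*% noise %*% t(B)
}

#' Generate a synthetic DEM from a scenario
#'
#' Relief is a spatially autocorrelated Gaussian random field: white noise
#' smoothed with an isotropic Gaussian kernel of scale
#' `correlationLength` cells (truncated at 4 sigma), centred and rescaled
#' so the sample standard deviation equals `reliefSd` exactly, then offset
#' by `baseElevation` and tilted by the regional ramp `rampGrad`.
#' Deterministic given the scenario seed.
#'
#' @param scenario a [Scenario-class].
#' @param ... unused.
#' @return an [ElevationGrid-class] with origin (0, 0).
#' @name generateDem
NULL

#' @rdname generateDem
setMethod("generateDem", "Scenario", function(scenario, ...) {
  sc <- scenario
  validObject(sc)
  field <- .withSeed(sc@seed,
                     .smoothedNoise(sc@nrows, sc@ncols, sc@correlationLength))
  if (sc@reliefSd > 0) {
    s <- stats::sd(as.vector(field))
    field <- (field - mean(field)) / s * sc@reliefSd
  } else {
    field[] <- 0
  }
  h <- sc@cellsize
  xc <- (col(field) - 0.5) * h           # cell-center x
  yc <- (sc@nrows - row(field) + 0.5) * h  # cell-center y (row 1 = north)
  z <- field + sc@baseElevation + sc@rampGrad[1] * xc + sc@rampGrad[2] * yc
  elevationGrid(z, cellsize = h, xOrigin = 0, yOrigin = 0)
})

#' Place survey points on a synthetic landscape
#'
#' Presence cells are drawn without replacement from the stack's valid
#' (interior) cells with probability proportional to
#' `plogis(-effectBeta * z)`, where `z` is the z-score of the effect
#' predictor over valid cells — so a positive `effectBeta` concentrates
#' presences where the predictor is LOW (e.g. concave, low-TPI microsites).
#' Absences are drawn uniformly from the remaining valid cells. Points are
#' returned at cell centers; no cell is used twice and no border cell is
#' ever used (border cells have no predictor values).
#'
#' @param stack the [PredictorStack-class] computed from the scenario's DEM.
#' @param scenario the same [Scenario-class].
#' @param seed optional seed override (defaults to `scenario@seed + 1` so
#'   the survey draw is independent of the relief draw).
#' @param ... unused.
#' @return an [OccurrenceSet-class] with exactly
#'   `nPresence + nAbsence` points.
#' @name placeOccurrences
NULL

#' @rdname placeOccurrences
setMethod("placeOccurrences", signature("PredictorStack", "Scenario"),
          function(stack, scenario, seed = NULL, ...) {
  sc <- scenario
  validObject(sc)
  if (is.null(seed)) seed <- sc@seed + 1L
  valid <- !is.na(stack@layers[[1]])
  for (l in stack@layers) valid <- valid & !is.na(l)
  eligible <- which(valid)
  nNeed <- sc@nPresence + sc@nAbsence
  if (length(eligible) < nNeed)
    stop(sprintf("only %d eligible cells for %d points",
                 length(eligible), nNeed))
  if (sc@effectPredictor == "none" || sc@effectBeta == 0) {
    w <- rep(1, length(eligible))
  } else {
    v <- stack@layers[[sc@effectPredictor]][eligible]
    z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    w <- stats::plogis(-sc@effectBeta * z)
  }
  drawn <- .withSeed(seed, {
    pres <- sample(eligible, sc@nPresence, prob = w)
    rest <- setdiff(eligible, pres)
    abs_ <- sample(rest, sc@nAbsence)
    list(pres = pres, abs = abs_)
  })
  d <- dim(stack)
  h <- stack@cellsize
  cellXY <- function(idx) {
    r <- (idx - 1L) %% d[1] + 1L
    c_ <- (idx - 1L) %/% d[1] + 1L
    list(x = stack@xOrigin + (c_ - 0.5) * h,
         y = stack@yOrigin + (d[1] - r + 0.5) * h)
  }
  p <- cellXY(drawn$pres); a <- cellXY(drawn$abs)
  occurrenceSet(x = c(p$x, a$x), y = c(p$y, a$y),
                status = c(rep(1L, sc@nPresence), rep(0L, sc@nAbsence)),
                crsNote = "synthetic projected grid, meters, origin (0,0)")
})

#' Canned synthetic study: limestone-mountain scree fixture
#'
#' One call builds the full synthetic analogue of the motivating field
#' study under the default [scenario()]: an autocorrelated mountain relief,
#' its six-predictor stack, and a 7-presence / 37-absence survey whose
#' presences are concentrated in concave (low-TPI) cells and whose other
#' predictors carry no injected effect.
#'
#' @param seed RNG seed for relief and survey.
#' @return list with elements `dem` ([ElevationGrid-class]), `stack`
#'   ([PredictorStack-class]), `occurrences` ([OccurrenceSet-class]) and
#'   `scenario` ([Scenario-class]).
#' @examples
#' fx <- makeParnassosLike(seed = 7)
#' presenceCount(fx$occurrences)
#' @export
makeParnassosLike <- function(seed = 1L) {
  sc <- scenario(seed = as.integer(seed))
  dem <- generateDem(sc)
  stack <- computePredictorStack(dem)
  occ <- placeOccurrences(stack, sc)
  list(dem = dem, stack = stack, occurrences = occ, scenario = sc)
}

#' Write a synthetic fixture to disk
#'
#' Writes `dem.asc`, `occurrences.csv` and `scenario.json` under `dir`.
#'
#' @param fixture list from [makeParnassosLike()] (or any list with `dem`,
#'   `occurrences`, `scenario`).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAsc(fixture$dem, file.path(dir, "dem.asc"))
  writeOccurrences(fixture$occurrences, file.path(dir, "occurrences.csv"))
  writeScenario(fixture$scenario, file.path(dir, "scenario.json"))
  invisible(dir)
}
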