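#' @import methods
NULL

#' ElevationGrid: a projected, square-celled elevation raster
#'
#' The central raster container of the package. Elevations are stored as a
#' numeric matrix with row 1 at the NORTH edge (the usual north-up raster
#' layout); missing cells are `NA` internally and are mapped to the
#' `nodata` sentinel only on disk. Coordinates must be projected and metric
#' (meters); geographic (longitude/latitude) grids are rejected at read time
#' because 3x3 window distances would be meaningless.
#'
#' @slot values numeric matrix of elevations in meters, row 1 = north.
#' @slot cellsize edge length of the (square) cells, meters.
#' @slot xOrigin,yOrigin coordinates of the LOWER-LEFT corner of the grid,
#'   meters.
#' @slot nodata sentinel written for missing cells on export; never equal to
#'   a valid elevation.
#'
#' @seealso [elevationGrid()], [readAsc()], [writeAsc()]
#' @exportClass ElevationGrid
setClass("ElevationGrid",
  representation(
    values = "matrix",
    cellsize = "numeric",
    xOrigin = "numeric",
    yOrigin = "numeric",
    nodata = "numeric"
  ),
  prototype(
    values = matrix(numeric(0), 0, 0),
    cellsize = 1, xOrigin = 0, yOrigin = 0, nodata = -9999
  )
)

setValidity("ElevationGrid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  for (s in c("cellsize", "xOrigin", "yOrigin", "nodata")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("%s must be a single finite number", s))
  }
  if (length(object@cellsize) == 1L && is.finite(object@cellsize) &&
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be > 0")
  if (length(object@nodata) == 1L && is.finite(object@nodata) &&
      any(object@values == object@nodata, na.rm = TRUE))
    msg <- c(msg, "nodata sentinel collides with a valid elevation; use NA for missing cells")
  if (length(msg)) msg else TRUE
})

#' PredictorStack: six terrain layers aligned with their source DEM
#'
#' Holds the six topographic predictors (`tri`, `tpi`, `roughness`, `slope`,
#' `aspect`, `flowdir`) derived from one [ElevationGrid-class]. Every layer
#' has the shape, cell size and origin of the source DEM; border cells and
#' any cell whose 3x3 window touches a missing cell are `NA` in every layer,
#' so all layers share an identical support.
#'
#' @slot layers named list of numeric matrices, names exactly the six
#'   predictor names.
#' @slot cellsize,xOrigin,yOrigin,nodata geometry copied from the source DEM.
#' @slot provenance list recording how the stack was computed (parameters,
#'   source dimensions).
#'
#' @seealso [computePredictorStack()]
#' @exportClass PredictorStack
setClass("PredictorStack",
  representation(
    layers = "list",
    cellsize = "numeric",
    xOrigin = "numeric",
    yOrigin = "numeric",
    nodata = "numeric",
    provenance = "list"
  )
)

setValidity("PredictorStack", function(object) {
  msg <- character(0)
  if (!identical(names(object@layers), PREDICTOR_NAMES))
    msg <- c(msg, sprintf("layers must be named exactly: %s",
                          paste(PREDICTOR_NAMES, collapse = ", ")))
  dims <- lapply(object@layers, dim)
  if (length(dims) && length(unique(dims)) != 1L)
    msg <- c(msg, "all layers must share one shape")
  if (length(msg)) msg else TRUE
})

#' OccurrenceSet: labelled presence/absence survey points
#'
#' Surveyed point locations in the DEM's projected coordinate system, each
#' labelled present (1) or absent (0) for the focal species. The habitat
#' analysis this package was built around is the unbalanced case typical of
#' targeted surveys of rare plants: a handful of presences against several
#' dozen visited-but-unoccupied sites.
#'
#' @slot records data.frame with columns `id` (character, unique),
#'   `x`, `y` (meters) and `status` (integer 0/1).
#' @slot crsNote free-text note on the coordinate reference system.
#'
#' @seealso [occurrenceSet()], [readOccurrences()]
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(records = "data.frame", crsNote = "character"),
  prototype(crsNote = "projected metric coordinates")
)

setValidity("OccurrenceSet", function(object) {
  r <- object@records
  msg <- character(0)
  need <- c("id", "x", "y", "status")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id))
    msg <- c(msg, "occurrence ids must be unique")
  if (!all(r$status %in% c(0L, 1L)))
    msg <- c(msg, "status must be strictly binary (0 = absence, 1 = presence)")
  if (!all(is.finite(r$x)) || !all(is.finite(r$y)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' ResamplingResult: outcome of the balanced resampling test for one predictor
#'
#' @slot predictor predictor name.
#' @slot presenceMean arithmetic mean of the predictor at presence points.
#' @slot nullMeans the B resampled means forming the null distribution.
#' @slot ciLow,ciHigh percentile confidence-interval bounds at level
#'   1 - alpha.
#' @slot significant `TRUE` iff the presence mean falls outside the interval.
#' @slot direction `"lower"`, `"higher"` or `"none"`, matching which bound is
#'   crossed.
#' @slot B number of resamples; for the exhaustive oracle, the number of
#'   enumerated subsets.
#' @slot alpha complement of the confidence level (0.05 for a 95% CI).
#' @slot seed RNG seed used (NA for the exhaustive oracle).
#' @slot nullMode `"pooled"`, `"absences"` or `"exhaustive-*"`; how the null
#'   draws were made.
#'
#' @seealso [balancedResamplingTest()], [exhaustiveNull()]
#' @exportClass ResamplingResult
setClass("ResamplingResult",
  representation(
    predictor = "character",
    presenceMean = "numeric",
    nullMeans = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    significant = "logical",
    direction = "character",
    B = "integer",
    alpha = "numeric",
    seed = "integer",
    nullMode = "character"
  )
)

setValidity("ResamplingResult", function(object) {
  msg <- character(0)
  if (object@ciLow > object@ciHigh)
    msg <- c(msg, "ciLow must be <= ciHigh")
  out <- object@presenceMean < object@ciLow || object@presenceMean > object@ciHigh
  if (!identical(out, object@significant))
    msg <- c(msg, "significant must equal CI exclusion of the presence mean")
  dir <- if (object@presenceMean < object@ciLow) "lower"
         else if (object@presenceMean > object@ciHigh) "higher" else "none"
  if (!identical(dir, object@direction))
    msg <- c(msg, "direction inconsistent with which bound is crossed")
  if (length(object@nullMeans) != object@B)
    msg <- c(msg, "length(nullMeans) must equal B")
  if (length(msg)) msg else TRUE
})

#' ThreatAssessment: IUCN criterion-B2 quantities and category
#'
#' @slot aooKm2 area of occupancy on the IUCN occupancy grid, km^2.
#' @slot aooMinKm2 minimum AOO over a 4x4 set of grid-origin offsets
#'   (reported because AOO depends on where the occupancy grid is anchored);
#'   `NA` unless requested.
#' @slot eooKm2 extent of occurrence (convex-hull area), km^2.
#' @slot nLocations number of locations under the separation rule used.
#' @slot sepKm the separation distance that defined a location, km.
#' @slot continuingDecline whether continuing decline (condition b) holds.
#' @slot category `"CR"`, `"EN"`, `"VU"` or `"not-threatened-under-B2"`.
#' @slot rationale text listing the thresholds that fired.
#'
#' @seealso [assessThreat()], [criterionB2()]
#' @exportClass ThreatAssessment
setClass("ThreatAssessment",
  representation(
    aooKm2 = "numeric",
    aooMinKm2 = "numeric",
    eooKm2 = "numeric",
    nLocations = "integer",
    sepKm = "numeric",
    continuingDecline = "logical",
    category = "character",
    rationale = "character"
  ),
  prototype(aooMinKm2 = NA_real_)
)

setValidity("ThreatAssessment", function(object) {
  msg <- character(0)
  if (object@aooKm2 < 0 || object@eooKm2 < 0)
    msg <- c(msg, "areas must be non-negative")
  if (!object@category %in% c("CR", "EN", "VU", "not-threatened-under-B2"))
    msg <- c(msg, "unknown category")
  if (length(msg)) msg else TRUE
})

#' Scenario: parameters of a synthetic landscape + survey
#'
#' Describes one simulated study: a spatially autocorrelated relief (Gaussian
#' random field), an optional regional ramp, and a presence/absence survey in
#' which presences are concentrated where one chosen predictor is LOW
#' (positive `effectBeta` pulls presences towards low predictor values, the
#' concave-microsite mechanism hypothesised for scree endemics).
#'
#' @slot nrows,ncols grid dimensions (cells).
#' @slot cellsize cell edge, meters.
#' @slot reliefSd standard deviation of the relief, meters.
#' @slot correlationLength Gaussian smoothing scale of the relief, cells.
#' @slot rampGrad length-2 numeric, regional gradient (m elevation per m) in
#'   x and y added to the random field.
#' @slot baseElevation mean elevation added to the field, meters.
#' @slot nPresence,nAbsence survey sizes.
#' @slot effectPredictor one of the six predictor names, or `"none"`.
#' @slot effectBeta logistic coefficient on the z-scored predictor
#'   (scale-free; positive concentrates presences at low values).
#' @slot seed RNG seed.
#'
#' @seealso [scenario()], [generateDem()], [placeOccurrences()]
#' @exportClass Scenario
setClass("Scenario",
  representation(
    nrows = "integer", ncols = "integer", cellsize = "numeric",
    reliefSd = "numeric", correlationLength = "numeric",
    rampGrad = "numeric", baseElevation = "numeric",
    nPresence = "integer", nAbsence = "integer",
    effectPredictor = "character", effectBeta = "numeric",
    seed = "integer"
  )
)

setValidity("Scenario", function(object) {
  msg <- character(0)
  if (object@nrows < 16L || object@ncols < 16L)
    msg <- c(msg, "grid must be at least 16 x 16")
  if (object@reliefSd < 0) msg <- c(msg, "reliefSd must be >= 0")
  if (object@correlationLength <= 0) msg <- c(msg, "correlationLength must be > 0")
  if (length(object@rampGrad) != 2L) msg <- c(msg, "rampGrad must have length 2")
  if (!object@effectPredictor %in% c(PREDICTOR_NAMES, "none"))
    msg <- c(msg, "effectPredictor must be one of the six predictors or 'none'")
  nInterior <- (object@nrows - 2L) * (object@ncols - 2L)
  if (object@nPresence + object@nAbsence > nInterior)
    msg <- c(msg, "nPresence + nAbsence exceeds the number of interior cells")
  if (object@nPresence < 1L || object@nAbsence < 1L)
    msg <- c(msg, "need at least one presence and one absence")
  if (length(msg)) msg else TRUE
})
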