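## Six 3x3-neighbourhood topographic predictors, computed with explicit
## shifted-matrix stencils (no terrain library in the computation path).
##
## Conventions shared by all layers:
##  * row 1 of the matrix is the NORTH edge of the grid;
##  * border cells, and any cell whose 3x3 window touches a missing cell,
##    are NA in every layer, so all six layers have identical support;
##  * adding a constant to the DEM changes nothing; scaling it by c > 0
##    scales tri/tpi/roughness by c and leaves aspect/flowdir unchanged.

.checkTerrainInput <- function(dem) {
  stopifnot(is(dem, "ElevationGrid"))
  validObject(dem)
  d <- dim(dem@values)
  if (d[1] < 3L || d[2] < 3L)
    stop(sprintf("terrain operations need at least a 3x3 grid, got %dx%d",
                 d[1], d[2]))
  invisible(dem)
}

# Neighbour of every cell at row offset dr, col offset dc (NA beyond edges).
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# The 8 Moore neighbours in D8 code order (1=E, then clockwise: SE S SW W NW
# N NE). Row offsets are in matrix space, so +1 row = one cell SOUTH.
.D8 <- data.frame(
  code = c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L),
  dr   = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
  dc   = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
)

.neighbourArray <- function(m) {
  lapply(seq_len(nrow(.D8)), function(i) .shift(m, .D8$dr[i], .D8$dc[i]))
}

# NA out every cell whose 3x3 window is incomplete (border or missing data).
.windowMask <- function(m, nbrs) {
  bad <- is.na(m)
  for (n in nbrs) bad <- bad | is.na(n)
  bad
}

#' Terrain Ruggedness Index (TRI)
#'
#' Mean absolute elevation difference between a cell and its 8 Moore
#' neighbours, in meters. High values mark rugged, broken terrain.
#'
#' @param dem an [ElevationGrid-class] (at least 3x3).
#' @param ... unused.
#' @return numeric matrix aligned with `dem`; border/nodata-adjacent cells
#'   are `NA`.
#' @examples
#' bump <- elevationGrid(matrix(c(1,1,1, 1,2,1, 1,1,1), 3, 3))
#' tri(bump)[2, 2]  # 1
#' @name tri
NULL

#' @rdname tri
setMethod("tri", "ElevationGrid", function(dem, ...) {
  .checkTerrainInput(dem)
  m <- dem@values
  nbrs <- .neighbourArray(m)
  acc <- matrix(0, nrow(m), ncol(m))
  for (n in nbrs) acc <- acc + abs(m - n)
  acc <- acc / 8
  acc[.windowMask(m, nbrs)] <- NA_real_
  acc
})

#' Topographic Position Index (TPI)
#'
#' Center-cell elevation minus the mean elevation of the 8 Moore neighbours,
#' in meters. Negative values mark cells lower than their surroundings
#' (valleys, concavities) — the microsites where snow and moisture collect on
#' scree slopes; positive values mark ridges and local highs.
#'
#' @inheritParams tri
#' @return numeric matrix aligned with `dem`.
#' @name tpi
NULL

#' @rdname tpi
setMethod("tpi", "ElevationGrid", function(dem, ...) {
  .checkTerrainInput(dem)
  m <- dem@values
  nbrs <- .neighbourArray(m)
  acc <- matrix(0, nrow(m), ncol(m))
  for (n in nbrs) acc <- acc + n
  out <- m - acc / 8
  out[.windowMask(m, nbrs)] <- NA_real_
  out
})

#' Roughness
#'
#' Elevation spread — maximum minus minimum — over the full 3x3 window
#' (center included), in meters.
#'
#' @inheritParams tri
#' @return numeric matrix aligned with `dem`.
#' @name roughness
NULL

#' @rdname roughness
setMethod("roughness", "ElevationGrid", function(dem, ...) {
  .checkTerrainInput(dem)
  m <- dem@values
  nbrs <- .neighbourArray(m)
  hi <- m; lo <- m
  for (n in nbrs) { hi <- pmax(hi, n); lo <- pmin(lo, n) }
  out <- hi - lo
  out[.windowMask(m, nbrs)] <- NA_real_
  out
})

# Horn (1981) 8-neighbour weighted gradients; returns list(p, q, mask) where
# p = dz/dx (east positive) and q = dz/dy (north positive), in rise/run.
.hornGradients <- function(dem) {
  m <- dem@values; h <- dem@cellsize
  nbrs <- .neighbourArray(m)
  names(nbrs) <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")
  p <- ((nbrs$NE + 2 * nbrs$E + nbrs$SE) -
        (nbrs$NW + 2 * nbrs$W + nbrs$SW)) / (8 * h)
  q <- ((nbrs$NW + 2 * nbrs$N + nbrs$NE) -
        (nbrs$SW + 2 * nbrs$S + nbrs$SE)) / (8 * h)
  list(p = p, q = q, mask = .windowMask(m, nbrs))
}

#' Slope
#'
#' Steepest-descent gradient angle `atan(sqrt(p^2 + q^2))` from Horn's
#' (1981) 8-neighbour weighted finite differences, the common raster
#' default. A `zevenbergenThorne` flag switches to the 4-neighbour central
#' differences of Zevenbergen & Thorne (1987).
#'
#' @inheritParams tri
#' @param units `"degrees"` (default) or `"radians"`.
#' @param zevenbergenThorne use central differences of the 4 edge neighbours
#'   instead of Horn's stencil.
#' @return numeric matrix aligned with `dem`.
#' @name slope
NULL

.gradients <- function(dem, zevenbergenThorne = FALSE) {
  if (!zevenbergenThorne) return(.hornGradients(dem))
  m <- dem@values; h <- dem@cellsize
  nbrs <- .neighbourArray(m)
  names(nbrs) <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")
  list(p = (nbrs$E - nbrs$W) / (2 * h),
       q = (nbrs$N - nbrs$S) / (2 * h),
       mask = .windowMask(m, nbrs))
}

#' @rdname slope
setMethod("slope", "ElevationGrid",
          function(dem, units = c("degrees", "radians"),
                   zevenbergenThorne = FALSE, ...) {
  .checkTerrainInput(dem)
  units <- match.arg(units)
  g <- .gradients(dem, zevenbergenThorne)
  out <- atan(sqrt(g$p^2 + g$q^2))
  if (units == "degrees") out <- out * 180 / pi
  out[g$mask] <- NA_real_
  out
})

#' Aspect
#'
#' Compass direction of steepest descent in degrees clockwise from grid
#' north, in [0, 360). Cells with gradient magnitude below `flatTol`
#' (rise/run) have no defined downslope direction and are `NA`.
#'
#' @inheritParams slope
#' @param flatTol gradient-magnitude tolerance below which a cell counts as
#'   flat (default 1e-9 rise/run).
#' @return numeric matrix aligned with `dem`.
#' @name aspect
NULL

#' @rdname aspect
setMethod("aspect", "ElevationGrid",
          function(dem, flatTol = 1e-9, zevenbergenThorne = FALSE, ...) {
  .checkTerrainInput(dem)
  g <- .gradients(dem, zevenbergenThorne)
  # downslope vector is (-p, -q); azimuth measured clockwise from north (+y)
  out <- (atan2(-g$p, -g$q) * 180 / pi) %% 360
  out[sqrt(g$p^2 + g$q^2) < flatTol] <- NA_real_
  out[g$mask] <- NA_real_
  out
})

#' D8 flow direction
#'
#' The single-neighbour (D8) drainage direction: each cell points at the
#' Moore neighbour with the greatest distance-weighted drop
#' (drop / inter-cell distance, diagonal distance `cellsize * sqrt(2)`).
#' Codes are powers of two laid out
#' \preformatted{ 32  64 128
#'  16   .   1
#'   8   4   2 }
#' (1 = east, then clockwise). In a pit (all neighbours higher) the cell
#' points at the smallest rise; ties are broken by the smallest code, so a
#' perfectly flat neighbourhood yields 1 (east).
#'
#' @inheritParams tri
#' @param distanceWeighting divide drops by inter-cell distance (default
#'   `TRUE`); with `FALSE` raw drops are compared.
#' @return integer-valued numeric matrix of D8 codes aligned with `dem`.
#' @name flowdir
NULL

#' @rdname flowdir
setMethod("flowdir", "ElevationGrid",
          function(dem, distanceWeighting = TRUE, ...) {
  .checkTerrainInput(dem)
  m <- dem@values; h <- dem@cellsize
  best <- matrix(-Inf, nrow(m), ncol(m))
  code <- matrix(NA_real_, nrow(m), ncol(m))
  mask <- matrix(FALSE, nrow(m), ncol(m)) | is.na(m)
  # ascending code order + strict improvement = smallest code wins ties
  for (i in seq_len(nrow(.D8))) {
    n <- .shift(m, .D8$dr[i], .D8$dc[i])
    mask <- mask | is.na(n)
    d <- if (distanceWeighting && .D8$dr[i] != 0L && .D8$dc[i] != 0L)
           h * sqrt(2) else h
    drop <- (m - n) / d
    take <- !is.na(drop) & drop > best
    best[take] <- drop[take]
    code[take] <- .D8$code[i]
  }
  code[mask] <- NA_real_
  code
})

#' Compute all six topographic predictors
#'
#' Builds a [PredictorStack-class] with the layers `tri`, `tpi`,
#' `roughness`, `slope`, `aspect` and `flowdir`, all aligned cell-for-cell
#' with the source DEM and sharing one support (border and nodata-adjacent
#' cells are `NA` everywhere).
#'
#' @inheritParams tri
#' @param slopeUnits units for the slope layer.
#' @param distanceWeighting passed to [flowdir()].
#' @param zevenbergenThorne passed to [slope()] and [aspect()].
#' @param flatTol passed to [aspect()].
#' @return a [PredictorStack-class].
#' @examples
#' dem <- generateDem(scenario(seed = 1))
#' stk <- computePredictorStack(dem)
#' predictorNames(stk)
#' @name computePredictorStack
NULL

#' @rdname computePredictorStack
setMethod("computePredictorStack", "ElevationGrid",
          function(dem, slopeUnits = "degrees", distanceWeighting = TRUE,
                   zevenbergenThorne = FALSE, flatTol = 1e-9, ...) {
  .checkTerrainInput(dem)
  layers <- list(
    tri = tri(dem),
    tpi = tpi(dem),
    roughness = roughness(dem),
    slope = slope(dem, units = slopeUnits,
                  zevenbergenThorne = zevenbergenThorne),
    aspect = aspect(dem, flatTol = flatTol,
                    zevenbergenThorne = zevenbergenThorne),
    flowdir = flowdir(dem, distanceWeighting = distanceWeighting)
  )
  new("PredictorStack",
      layers = layers,
      cellsize = dem@cellsize, xOrigin = dem@xOrigin, yOrigin = dem@yOrigin,
      nodata = dem@nodata,
      provenance = list(
        sourceDim = dim(dem@values),
        slopeUnits = slopeUnits,
        slopeAlgorithm = if (zevenbergenThorne) "zevenbergen-thorne" else "horn",
        distanceWeighting = distanceWeighting,
        flatTol = flatTol
      ))
})

#' @rdname predictorLayer
#' @param x a [PredictorStack-class].
#' @param name one of `"tri"`, `"tpi"`, `"roughness"`, `"slope"`,
#'   `"aspect"`, `"flowdir"`.
#' @return `predictorLayer`: the named layer matrix; `predictorNames`: the
#'   six layer names.
#' @name predictorLayer
setMethod("predictorLayer", "PredictorStack", function(x, name) {
  name <- match.arg(name, PREDICTOR_NAMES)
  x@layers[[name]]
})

#' @rdname predictorLayer
setMethod("predictorNames", "PredictorStack", function(x) names(x@layers))

#' @export
setMethod("dim", "PredictorStack", function(x) dim(x@layers[[1]]))

setMethod("show", "PredictorStack", function(object) {
  d <- dim(object)
  cat(sprintf("PredictorStack: %d rows x %d cols, cellsize %g m\n",
              d[1], d[2], object@cellsize))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
  cat(sprintf("  slope algorithm: %s; shared support: %d valid cell(s)\n",
              object@provenance$slopeAlgorithm,
              sum(!is.na(object@layers[[1]]))))
  invisible(object)
})

#' Write the six predictor layers as .asc files
#'
#' Writes `<name>.asc` for each layer plus `provenance.json` into `dir`.
#'
#' @param stack a [PredictorStack-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePredictorStack <- function(stack, dir) {
  stopifnot(is(stack, "PredictorStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack@layers)) {
    writeAsc(stack@layers[[nm]], file.path(dir, paste0(nm, ".asc")),
             cellsize = stack@cellsize, xOrigin = stack@xOrigin,
             yOrigin = stack@yOrigin, nodata = stack@nodata)
  }
  jsonlite::write_json(stack@provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a predictor stack written by [writePredictorStack()]
#'
#' @param dir directory holding the six `.asc` layers.
#' @return a [PredictorStack-class].
#' @export
readPredictorStack <- function(dir) {
  grids <- lapply(PREDICTOR_NAMES, function(nm) {
    f <- file.path(dir, paste0(nm, ".asc"))
    if (!file.exists(f)) stop("missing predictor layer: ", f)
    readAsc(f)
  })
  names(grids) <- PREDICTOR_NAMES
  g1 <- grids[[1]]
  provFile <- file.path(dir, "provenance.json")
  prov <- if (file.exists(provFile))
    jsonlite::read_json(provFile, simplifyVector = TRUE) else list()
  new("PredictorStack",
      layers = lapply(grids, gridValues),
      cellsize = cellSize(g1), xOrigin = gridOrigin(g1)[["x"]],
      yOrigin = gridOrigin(g1)[["y"]], nodata = nodataValue(g1),
      provenance = prov)
}
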