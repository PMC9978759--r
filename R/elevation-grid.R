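#' Construct an ElevationGrid
#'
#' @param values numeric matrix of elevations (meters), row 1 = north edge.
#'   Cells equal to `nodata` are converted to `NA` internally.
#' @param cellsize square cell edge length in meters (> 0).
#' @param xOrigin,yOrigin coordinates of the lower-left corner (meters).
#' @param nodata sentinel used for missing cells when writing to disk.
#'
#' @return an [ElevationGrid-class] object.
#' @examples
#' dem <- elevationGrid(matrix(runif(25), 5, 5), cellsize = 10)
#' dim(dem)
#' @export
elevationGrid <- function(values, cellsize = 1, xOrigin = 0, yOrigin = 0,
                          nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[values == nodata] <- NA_real_
  new("ElevationGrid", values = values, cellsize = as.numeric(cellsize),
      xOrigin = as.numeric(xOrigin), yOrigin = as.numeric(yOrigin),
      nodata = as.numeric(nodata))
}

#' Grid accessors
#'
#' `gridValues` returns the value matrix (row 1 = north; `NA` marks missing
#' cells), `cellSize` the cell edge length in meters, `gridOrigin` the
#' lower-left corner `c(x, y)`, and `nodataValue` the on-disk sentinel.
#'
#' @param x an [ElevationGrid-class] or [PredictorStack-class].
#' @param ... unused.
#' @return see description.
#' @name gridValues
#' @aliases cellSize gridOrigin nodataValue
NULL

#' @rdname gridValues
setMethod("gridValues", "ElevationGrid", function(x, ...) x@values)

#' @rdname gridValues
setMethod("cellSize", "ElevationGrid", function(x) x@cellsize)

#' @rdname gridValues
setMethod("gridOrigin", "ElevationGrid",
          function(x) c(x = x@xOrigin, y = x@yOrigin))

#' @rdname gridValues
setMethod("nodataValue", "ElevationGrid", function(x) x@nodata)

#' @rdname gridValues
setMethod("cellSize", "PredictorStack", function(x) x@cellsize)

#' @rdname gridValues
setMethod("gridOrigin", "PredictorStack",
          function(x) c(x = x@xOrigin, y = x@yOrigin))

#' @rdname gridValues
setMethod("nodataValue", "PredictorStack", function(x) x@nodata)

#' @export
setMethod("dim", "ElevationGrid", function(x) dim(x@values))

setMethod("show", "ElevationGrid", function(object) {
  d <- dim(object@values)
  v <- object@values
  cat(sprintf("ElevationGrid: %d rows x %d cols, cellsize %g m\n",
              d[1], d[2], object@cellsize))
  cat(sprintf("  lower-left corner: (%g, %g)\n", object@xOrigin, object@yOrigin))
  if (length(v)) {
    cat(sprintf("  elevation range: [%g, %g] m, %d missing cell(s)\n",
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)),
                sum(is.na(v))))
  }
  invisible(object)
})

## ---- ESRI ASCII grid I/O ---------------------------------------------------

#' Read an ESRI ASCII grid (.asc)
#'
#' Parses the standard six-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`; the last is optional) followed by row-major values,
#' north-up. Values equal to the nodata sentinel become `NA`.
#'
#' Grids that look geographic (cell size below 0.01 with an origin inside
#' lon/lat bounds) are rejected: terrain predictors need projected metric
#' coordinates.
#'
#' @param path path to the .asc file.
#' @return an [ElevationGrid-class].
#' @export
readAsc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  nHeader <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated .asc file: ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      if (length(parts) != 2L) stop("malformed .asc header line: ", line)
      hdr[[key]] <- as.numeric(parts[2])
      nHeader <- nHeader + 1L
    } else {
      seek(con, pos)
      break
    }
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop(".asc header missing ", k)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  h <- hdr$cellsize
  if (!is.finite(h) || h <= 0) stop("cellsize must be > 0")
  # xllcenter/yllcenter give the center of the lower-left cell
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
        else if (!is.null(hdr$xllcenter)) hdr$xllcenter - h / 2
        else stop(".asc header missing xllcorner/xllcenter")
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
        else if (!is.null(hdr$yllcenter)) hdr$yllcenter - h / 2
        else stop(".asc header missing yllcorner/yllcenter")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  if (h < 0.01 && abs(x0) <= 360 && abs(y0) <= 90)
    stop("grid appears to be in geographic (lon/lat) coordinates; ",
         "project it to a metric CRS first")
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf(".asc body has %d values, expected %d x %d = %d",
                 length(vals), nr, nc, nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  elevationGrid(m, cellsize = h, xOrigin = x0, yOrigin = y0, nodata = nodata)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' Values are written with 17 significant digits so that a read/write cycle
#' reproduces every double bit-exactly. `NA` cells are written as the grid's
#' nodata sentinel.
#'
#' @param grid an [ElevationGrid-class] (or a bare matrix, in which case the
#'   remaining geometry arguments are used).
#' @param path output path.
#' @param cellsize,xOrigin,yOrigin,nodata geometry, only used when `grid` is
#'   a bare matrix.
#' @return `path`, invisibly.
#' @export
writeAsc <- function(grid, path, cellsize = 1, xOrigin = 0, yOrigin = 0,
                     nodata = -9999) {
  if (is(grid, "ElevationGrid")) {
    m <- grid@values; h <- grid@cellsize
    x0 <- grid@xOrigin; y0 <- grid@yOrigin; nd <- grid@nodata
  } else {
    m <- as.matrix(grid); h <- cellsize; x0 <- xOrigin; y0 <- yOrigin
    nd <- nodata
  }
  fmt <- function(v) sprintf("%.17g", v)
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %s", fmt(x0)),
    sprintf("yllcorner %s", fmt(y0)),
    sprintf("cellsize %s", fmt(h)),
    sprintf("NODATA_value %s", fmt(nd))
  )
  body <- apply(m, 1L, function(row) {
    row[is.na(row)] <- nd
    paste(fmt(row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
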