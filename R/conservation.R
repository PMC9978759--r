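## IUCN criterion-B2 quantities: area of occupancy on the standard 2 x 2 km
## occupancy grid, extent of occurrence as a convex-hull area, locations by
## single-linkage grouping, and the B2 threshold table (conditions (a)
## number of locations and (b) continuing decline).

.presenceXY <- function(points) {
  if (is(points, "OccurrenceSet")) {
    r <- points@records
    r <- r[r$status == 1L, , drop = FALSE]
    if (nrow(r) == 0L) stop("no presence points")
    cbind(x = r$x, y = r$y)
  } else {
    m <- as.matrix(points)
    if (ncol(m) != 2L) stop("points must be a 2-column matrix or OccurrenceSet")
    colnames(m) <- c("x", "y")
    m
  }
}

#' Area of occupancy (AOO)
#'
#' Number of distinct occupied cells of a `cellKm` x `cellKm` grid anchored
#' at the coordinate origin, times the cell area. The IUCN default is a
#' 2 x 2 km grid. Because AOO depends on where that grid is anchored,
#' `originShiftMin = TRUE` additionally minimises over a 4 x 4 set of
#' origin offsets (quarter-cell steps) and returns both values.
#'
#' @param points presence points: an [OccurrenceSet-class] (presences used)
#'   or a 2-column matrix of metric x, y.
#' @param cellKm occupancy-grid cell edge in km (default 2).
#' @param originShiftMin also compute the minimum over shifted grid
#'   origins.
#' @return `aoo` in km^2; if `originShiftMin`, a named vector
#'   `c(aoo = ..., aoo_min = ...)`.
#' @examples
#' aoo(cbind(c(500, 900, 5000), c(500, 900, 500)))  # 2 cells -> 8 km^2
#' @export
aoo <- function(points, cellKm = 2, originShiftMin = FALSE) {
  xy <- .presenceXY(points)
  stopifnot(cellKm > 0)
  cell <- cellKm * 1000
  countCells <- function(ox, oy) {
    keys <- paste(floor((xy[, 1] - ox) / cell),
                  floor((xy[, 2] - oy) / cell))
    length(unique(keys))
  }
  a <- countCells(0, 0) * cellKm^2
  if (!originShiftMin) return(a)
  offsets <- (0:3) / 4 * cell
  counts <- outer(offsets, offsets,
                  Vectorize(function(ox, oy) countCells(ox, oy)))
  c(aoo = a, aoo_min = min(counts) * cellKm^2)
}

#' Extent of occurrence (EOO)
#'
#' Area of the convex hull around the points, via the shoelace formula,
#' in km^2. Fewer than 3 non-collinear points give 0.
#'
#' @inheritParams aoo
#' @return EOO in km^2.
#' @export
eoo <- function(points) {
  xy <- .presenceXY(points)
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  n <- length(hull)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2 / 1e6
}

#' Count locations by single-linkage grouping
#'
#' Points closer than `sepKm` are linked; connected components of that
#' graph are locations. The true IUCN "location" is threat-defined; a
#' distance rule is a proxy, so the separation used must be reported
#' alongside the count.
#'
#' @inheritParams aoo
#' @param sepKm separation distance in km (> 0); pairs strictly closer
#'   than this are linked.
#' @return integer number of locations.
#' @export
countLocations <- function(points, sepKm = 1) {
  xy <- .presenceXY(points)
  stopifnot(sepKm > 0)
  n <- nrow(xy)
  if (n == 1L) return(1L)
  sep <- sepKm * 1000
  d <- as.matrix(stats::dist(xy))
  # union-find over the strict-inequality adjacency
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] < sep) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' IUCN criterion-B2 category from AOO, locations and decline
#'
#' Implements the B2 threshold table with conditions (a) number of
#' locations and (b) continuing decline:
#' CR if AOO < 10 km^2, exactly 1 location and decline;
#' EN if AOO < 500 km^2, <= 5 locations and decline;
#' VU if AOO < 2000 km^2, <= 10 locations and decline;
#' otherwise not threatened under B2.
#'
#' @param aooKm2 area of occupancy, km^2.
#' @param nLocations number of locations.
#' @param continuingDecline logical, condition (b).
#' @return list with `category` and `rationale` (which thresholds fired).
#' @examples
#' criterionB2(9, 5, TRUE)$category   # "EN"
#' criterionB2(9, 1, TRUE)$category   # "CR"
#' @export
criterionB2 <- function(aooKm2, nLocations, continuingDecline) {
  stopifnot(is.finite(aooKm2), is.finite(nLocations),
            is.logical(continuingDecline))
  fired <- character(0)
  category <- "not-threatened-under-B2"
  if (continuingDecline) {
    if (aooKm2 < 10 && nLocations == 1) {
      category <- "CR"
      fired <- c("B2: AOO < 10 km^2", "B2a: 1 location", "B2b: continuing decline")
    } else if (aooKm2 < 500 && nLocations <= 5) {
      category <- "EN"
      fired <- c(sprintf("B2: AOO = %g km^2 < 500 km^2", aooKm2),
                 sprintf("B2a: %d location(s) <= 5", nLocations),
                 "B2b: continuing decline")
    } else if (aooKm2 < 2000 && nLocations <= 10) {
      category <- "VU"
      fired <- c(sprintf("B2: AOO = %g km^2 < 2000 km^2", aooKm2),
                 sprintf("B2a: %d location(s) <= 10", nLocations),
                 "B2b: continuing decline")
    }
  }
  if (category == "not-threatened-under-B2")
    fired <- "no B2 threshold combination met"
  list(category = category, rationale = fired)
}

#' Full criterion-B2 threat assessment from presence points
#'
#' Computes AOO (with the origin-shift minimum for reference), EOO,
#' the location count at the stated separation, and the resulting B2
#' category.
#'
#' @inheritParams aoo
#' @param sepKm location separation in km (reported in the result).
#' @param continuingDecline condition (b); the package cannot infer
#'   decline, the analyst asserts it.
#' @return a [ThreatAssessment-class].
#' @export
assessThreat <- function(points, cellKm = 2, sepKm = 1,
                         continuingDecline = TRUE) {
  a <- aoo(points, cellKm = cellKm, originShiftMin = TRUE)
  e <- eoo(points)
  nl <- countLocations(points, sepKm = sepKm)
  verdict <- criterionB2(a[["aoo"]], nl, continuingDecline)
  new("ThreatAssessment",
      aooKm2 = a[["aoo"]], aooMinKm2 = a[["aoo_min"]], eooKm2 = e,
      nLocations = as.integer(nl), sepKm = sepKm,
      continuingDecline = continuingDecline,
      category = verdict$category, rationale = verdict$rationale)
}

setMethod("show", "ThreatAssessment", function(object) {
  cat("ThreatAssessment (IUCN criterion B2)\n")
  cat(sprintf("  AOO: %g km^2 (origin-shift minimum %g km^2)\n",
              object@aooKm2, object@aooMinKm2))
  cat(sprintf("  EOO: %g km^2\n", object@eooKm2))
  cat(sprintf("  locations: %d (separation %g km)\n",
              object@nLocations, object@sepKm))
  cat(sprintf("  continuing decline: %s\n", object@continuingDecline))
  cat(sprintf("  category: %s\n", object@category))
  for (r in object@rationale) cat("    -", r, "\n")
  invisible(object)
})
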