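#' Construct an OccurrenceSet
#'
#' @param x,y point coordinates in the DEM's projected metric CRS.
#' @param status binary vector, 1 = presence, 0 = absence.
#' @param id optional unique ids (default `occ-1 ... occ-n`).
#' @param crsNote free-text CRS note.
#' @return an [OccurrenceSet-class].
#' @examples
#' occ <- occurrenceSet(x = c(5, 15), y = c(5, 15), status = c(1, 0))
#' presenceCount(occ)
#' @export
occurrenceSet <- function(x, y, status, id = NULL,
                          crsNote = "projected metric coordinates") {
  n <- length(x)
  if (is.null(id)) id <- sprintf("occ-%d", seq_len(n))
  rec <- data.frame(id = as.character(id), x = as.numeric(x),
                    y = as.numeric(y), status = as.integer(status),
                    stringsAsFactors = FALSE)
  new("OccurrenceSet", records = rec, crsNote = crsNote)
}

#' @rdname occurrenceSet
#' @param x an OccurrenceSet (for the accessors).
#' @name occurrenceSet
setMethod("occurrenceRecords", "OccurrenceSet", function(x) x@records)

#' @rdname occurrenceSet
setMethod("presenceCount", "OccurrenceSet",
          function(x) sum(x@records$status == 1L))

#' @rdname occurrenceSet
setMethod("absenceCount", "OccurrenceSet",
          function(x) sum(x@records$status == 0L))

#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@records))

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d point(s) (%d presence, %d absence)\n",
              nrow(object@records), presenceCount(object),
              absenceCount(object)))
  cat("  CRS:", object@crsNote, "\n")
  invisible(object)
})

#' Read presence/absence points from CSV
#'
#' Expects a header with columns `x`, `y` and `status` (an optional `id`
#' column is honoured). Malformed rows are reported with their line numbers
#' (header = line 1).
#'
#' @param path CSV file path.
#' @param crsNote free-text CRS note attached to the result.
#' @return an [OccurrenceSet-class].
#' @export
readOccurrences <- function(path,
                            crsNote = "projected metric coordinates") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("occurrence file is empty: ", path)
  need <- c("x", "y", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence CSV is missing column(s): ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # data row i sits on file line i + 1
  bad <- !df$status %in% c(0, 1) | is.na(df$status)
  if (any(bad))
    stop("non-binary status on line(s) ", paste(line[bad], collapse = ", "),
         " of ", path)
  badXY <- !is.finite(df$x) | !is.finite(df$y)
  if (any(badXY))
    stop("non-numeric coordinates on line(s) ",
         paste(line[badXY], collapse = ", "), " of ", path)
  id <- if ("id" %in% names(df)) as.character(df$id)
        else sprintf("occ-%d", seq_len(nrow(df)))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate occurrence id(s): ", paste(dup, collapse = ", "))
  }
  occurrenceSet(df$x, df$y, df$status, id = id, crsNote = crsNote)
}

#' Write an OccurrenceSet as CSV
#'
#' @param occ an [OccurrenceSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  stopifnot(is(occ, "OccurrenceSet"))
  utils::write.csv(occ@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Map points to (row, col) of the grid. Cells are half-open
# [x0 + (c-1)h, x0 + c*h) x [corresponding y band), so every in-extent point
# belongs to exactly one cell and points on the top/right outer edge are out
# of extent. Row 1 is the north edge.
.pointToCell <- function(x, y, nrows, ncols, cellsize, xOrigin, yOrigin) {
  col <- floor((x - xOrigin) / cellsize) + 1
  rowFromBottom <- floor((y - yOrigin) / cellsize) + 1
  row <- nrows - rowFromBottom + 1
  inExtent <- col >= 1 & col <= ncols & rowFromBottom >= 1 &
    rowFromBottom <= nrows
  data.frame(row = as.integer(row), col = as.integer(col),
             inExtent = inExtent)
}

#' Extract predictor values at occurrence points
#'
#' Maps each point to the grid cell containing it (half-open cell intervals
#' anchored at the lower-left corner) and returns one row per retained
#' occurrence with the six predictor values and the status label. Points
#' falling on cells where any predictor is missing (borders, nodata
#' neighbourhoods) are dropped with a warning under `policy = "drop"`, or
#' raise an error under `policy = "error"`.
#'
#' @param stack a [PredictorStack-class].
#' @param occ an [OccurrenceSet-class]; all points must lie inside the grid
#'   extent.
#' @param policy `"drop"` (default) or `"error"` for rows with missing
#'   predictor values.
#' @return a `data.frame` ("predictor table") with columns `id`, `status`,
#'   and the six predictors.
#' @export
extractAtPoints <- function(stack, occ, policy = c("drop", "error")) {
  stopifnot(is(stack, "PredictorStack"), is(occ, "OccurrenceSet"))
  policy <- match.arg(policy)
  rec <- occ@records
  d <- dim(stack)
  cells <- .pointToCell(rec$x, rec$y, d[1], d[2], stack@cellsize,
                        stack@xOrigin, stack@yOrigin)
  if (any(!cells$inExtent)) {
    bad <- rec$id[!cells$inExtent]
    stop("point(s) outside the grid extent: ", paste(bad, collapse = ", "))
  }
  idx <- cbind(cells$row, cells$col)
  tab <- data.frame(id = rec$id, status = rec$status,
                    stringsAsFactors = FALSE)
  for (nm in names(stack@layers)) tab[[nm]] <- stack@layers[[nm]][idx]
  incomplete <- !stats::complete.cases(tab[PREDICTOR_NAMES])
  if (any(incomplete)) {
    who <- paste(tab$id[incomplete], collapse = ", ")
    if (policy == "error")
      stop("missing predictor values at point(s): ", who)
    warning(sprintf("dropped %d point(s) with missing predictor values: %s",
                    sum(incomplete), who))
    tab <- tab[!incomplete, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
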