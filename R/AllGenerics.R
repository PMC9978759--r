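#' @rdname tri
#' @export
setGeneric("tri", function(dem, ...) standardGeneric("tri"))

#' @rdname tpi
#' @export
setGeneric("tpi", function(dem, ...) standardGeneric("tpi"))

#' @rdname roughness
#' @export
setGeneric("roughness", function(dem, ...) standardGeneric("roughness"))

#' @rdname slope
#' @export
setGeneric("slope", function(dem, ...) standardGeneric("slope"))

#' @rdname aspect
#' @export
setGeneric("aspect", function(dem, ...) standardGeneric("aspect"))

#' @rdname flowdir
#' @export
setGeneric("flowdir", function(dem, ...) standardGeneric("flowdir"))

#' @rdname computePredictorStack
#' @export
setGeneric("computePredictorStack",
           function(dem, ...) standardGeneric("computePredictorStack"))

#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x, ...) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname gridValues
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridValues
#' @export
setGeneric("nodataValue", function(x) standardGeneric("nodataValue"))

#' @rdname occurrenceSet
#' @export
setGeneric("occurrenceRecords", function(x) standardGeneric("occurrenceRecords"))

#' @rdname occurrenceSet
#' @export
setGeneric("presenceCount", function(x) standardGeneric("presenceCount"))

#' @rdname occurrenceSet
#' @export
setGeneric("absenceCount", function(x) standardGeneric("absenceCount"))

#' @rdname predictorLayer
#' @export
setGeneric("predictorLayer", function(x, name) standardGeneric("predictorLayer"))

#' @rdname predictorLayer
#' @export
setGeneric("predictorNames", function(x) standardGeneric("predictorNames"))

#' @rdname generateDem
#' @export
setGeneric("generateDem", function(scenario, ...) standardGeneric("generateDem"))

#' @rdname placeOccurrences
#' @export
setGeneric("placeOccurrences",
           function(stack, scenario, ...) standardGeneric("placeOccurrences"))
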