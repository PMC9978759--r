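## End-to-end orchestration: DEM -> predictor stack -> extraction ->
## balanced resampling test -> (optional) IUCN B2 assessment, with every
## artifact written to disk and enough provenance to re-run byte-for-byte.

#' Build a validated pipeline configuration
#'
#' @param demPath path to the input DEM (.asc).
#' @param pointsPath path to the occurrence CSV (x, y, status).
#' @param outputDir directory for all artifacts.
#' @param predictors subset of the six predictor names to report (all by
#'   default; the stack is always computed in full so supports match).
#' @param B,alpha,seed resampling-test parameters.
#' @param null,replace,correction,circularAspect passed to
#'   [runAllPredictors()].
#' @param slopeUnits,distanceWeighting,zevenbergenThorne terrain options.
#' @param iucn `NULL` to skip the threat assessment, or a list with
#'   elements `cellKm`, `sepKm`, `continuingDecline`.
#' @param quiet suppress progress messages.
#' @return a validated config (classed list).
#' @export
pipelineConfig <- function(demPath, pointsPath, outputDir,
                           predictors = PREDICTOR_NAMES,
                           B = 10000L, alpha = 0.05, seed = 1L,
                           null = "pooled", replace = FALSE,
                           correction = "none", circularAspect = FALSE,
                           slopeUnits = "degrees",
                           distanceWeighting = TRUE,
                           zevenbergenThorne = FALSE,
                           iucn = list(cellKm = 2, sepKm = 1,
                                       continuingDecline = TRUE),
                           quiet = FALSE) {
  bad <- setdiff(predictors, PREDICTOR_NAMES)
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(B) || B < 1) stop("B must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  null <- match.arg(null, c("pooled", "absences"))
  correction <- match.arg(correction, c("none", "bonferroni"))
  if (!is.null(iucn)) {
    need <- c("cellKm", "sepKm", "continuingDecline")
    miss <- setdiff(need, names(iucn))
    if (length(miss))
      stop("iucn config missing: ", paste(miss, collapse = ", "))
  }
  structure(list(
    demPath = demPath, pointsPath = pointsPath, outputDir = outputDir,
    predictors = predictors, B = as.integer(B), alpha = alpha,
    seed = as.integer(seed), null = null, replace = replace,
    correction = correction, circularAspect = circularAspect,
    slopeUnits = slopeUnits, distanceWeighting = distanceWeighting,
    zevenbergenThorne = zevenbergenThorne, iucn = iucn, quiet = quiet
  ), class = "screeNichePipelineConfig")
}

.pipelineLog <- function(quiet, ...) if (!quiet) message("[scree-niche] ", ...)

#' Run the full habitat-analysis pipeline
#'
#' Stages: read DEM, compute the six-predictor stack, read occurrences,
#' extract predictor values at the points, run the balanced resampling test
#' per predictor, and (optionally) assess IUCN criterion B2 on the presence
#' points. Artifacts written under `outputDir`: the six predictor layers
#' (`predictors/`), the extracted table (`table.tsv`), the per-predictor
#' null-mean samples (`null_means.tsv`, for redrawing density plots), and
#' `report.json`. Re-running with identical inputs and config reproduces
#' the report byte-for-byte.
#'
#' @param config from [pipelineConfig()], or a path to a JSON/YAML config
#'   file with the same field names.
#' @return the report, invisibly (a list mirroring `report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "screeNichePipelineConfig"))
  q <- config$quiet
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  .pipelineLog(q, "stage 1/5: reading DEM ", config$demPath)
  dem <- tryCatch(readAsc(config$demPath),
                  error = function(e) stop("stage 'dem': ", conditionMessage(e)))

  .pipelineLog(q, "stage 2/5: computing predictor stack")
  stack <- tryCatch(
    computePredictorStack(dem, slopeUnits = config$slopeUnits,
                          distanceWeighting = config$distanceWeighting,
                          zevenbergenThorne = config$zevenbergenThorne),
    error = function(e) stop("stage 'predictors': ", conditionMessage(e)))
  writePredictorStack(stack, file.path(config$outputDir, "predictors"))

  .pipelineLog(q, "stage 3/5: reading and extracting occurrences")
  occ <- tryCatch(readOccurrences(config$pointsPath),
                  error = function(e) stop("stage 'occurrences': ",
                                           conditionMessage(e)))
  dropped <- character(0)
  table <- withCallingHandlers(
    tryCatch(extractAtPoints(stack, occ, policy = "drop"),
             error = function(e) stop("stage 'extract': ",
                                      conditionMessage(e))),
    warning = function(w) {
      dropped <<- c(dropped, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  utils::write.table(table, file.path(config$outputDir, "table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  .pipelineLog(q, "stage 4/5: balanced resampling test (B = ", config$B, ")")
  results <- tryCatch(
    runAllPredictors(table, B = config$B, alpha = config$alpha,
                     seed = config$seed, null = config$null,
                     replace = config$replace,
                     correction = config$correction,
                     circularAspect = config$circularAspect),
    error = function(e) stop("stage 'test': ", conditionMessage(e)))
  results <- results[config$predictors]
  nulls <- data.frame(lapply(results, function(r) r@nullMeans),
                      check.names = FALSE)
  utils::write.table(nulls, file.path(config$outputDir, "null_means.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  threat <- NULL
  if (!is.null(config$iucn)) {
    .pipelineLog(q, "stage 5/5: IUCN criterion-B2 assessment")
    threat <- tryCatch(
      assessThreat(occ, cellKm = config$iucn$cellKm,
                   sepKm = config$iucn$sepKm,
                   continuingDecline = config$iucn$continuingDecline),
      error = function(e) stop("stage 'iucn': ", conditionMessage(e)))
  } else .pipelineLog(q, "stage 5/5: IUCN assessment skipped")

  report <- list(
    software = list(package = "screeNiche",
                    version = as.character(utils::packageVersion("screeNiche"))),
    config = unclass(config)[setdiff(names(config), "quiet")],
    inputs = list(
      dem_md5 = unname(tools::md5sum(config$demPath)),
      points_md5 = unname(tools::md5sum(config$pointsPath)),
      n_points = length(occ),
      n_presence = presenceCount(occ),
      n_absence = absenceCount(occ),
      n_rows_retained = nrow(table),
      dropped_rows = dropped
    ),
    results = lapply(results, function(r) list(
      predictor = r@predictor, presence_mean = r@presenceMean,
      ci_low = r@ciLow, ci_high = r@ciHigh,
      significant = r@significant, direction = r@direction,
      B = r@B, alpha = r@alpha, seed = r@seed, null_mode = r@nullMode
    )),
    iucn = if (is.null(threat)) NULL else list(
      aoo_km2 = threat@aooKm2, aoo_min_km2 = threat@aooMinKm2,
      eoo_km2 = threat@eooKm2, n_locations = threat@nLocations,
      sep_km = threat@sepKm,
      continuing_decline = threat@continuingDecline,
      category = threat@category, rationale = threat@rationale
    )
  )
  jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  .pipelineLog(q, "done; report at ",
               file.path(config$outputDir, "report.json"))
  invisible(report)
}

#' Read a pipeline config from JSON or YAML
#'
#' Field names match the arguments of [pipelineConfig()]. YAML files need
#' the `yaml` package.
#'
#' @param path config file (.json, .yaml or .yml).
#' @return a validated config.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(fields), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, fields)
}
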