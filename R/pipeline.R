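# field schema used to validate configs and normalise types so that a
# JSON round-trip reproduces the object exactly
.configSchema <- list(
  nHC = c("integer", 1L), nMSPRL = c("integer", 1L), nMSNoPRL = c("integer", 1L),
  effectSize = c("double", 1L), prlBoost = c("double", 1L),
  subjectSD = c("double", 1L), noiseCV = c("double", 1L),
  prlCountRange = c("integer", 2L), nonPrlCountRange = c("integer", 2L),
  lesionRadiusRange = c("double", 2L), nStreamlines = c("integer", 1L),
  gridDim = c("integer", 3L), gridSpacing = c("double", 3L),
  seed = c("integer", 1L), tStar = c("double", 1L),
  selectFraction = c("double", 1L), sweep = c("logical", 1L),
  alpha = c("double", 1L), exclusionDistance = c("double", 1L))

normalizePipelineConfig <- function(config) {
  for (f in names(.configSchema)) {
    if (is.null(config[[f]]))
      stop("pipeline config is missing required field '", f, "'",
           call. = FALSE)
    spec <- .configSchema[[f]]
    v <- config[[f]]
    if (length(v) != as.integer(spec[2]))
      stop("pipeline config field '", f, "' must have length ", spec[2],
           call. = FALSE)
    if (!is.numeric(v) && !is.logical(v))
      stop("pipeline config field '", f, "' must be ",
           if (spec[1] == "logical") "logical" else "numeric", call. = FALSE)
    config[[f]] <- switch(spec[1], integer = as.integer(v),
                          double = as.numeric(v), logical = as.logical(v))
  }
  config[names(.configSchema)]
}

#' Create, read or write a pipeline configuration
#'
#' A pipeline configuration bundles the cohort-generation parameters (see
#' \code{\link{CohortConfig}}) with the analysis parameters of
#' \code{\link{analyzeCohort}}. It is a plain named list with a fixed schema,
#' serialised to JSON; reading a written config reproduces it exactly, and a
#' config with a missing or malformed field is rejected with an error naming
#' the field.
#'
#' @param nHC,nMSPRL,nMSNoPRL,effectSize,prlBoost,subjectSD,noiseCV,
#'   prlCountRange,nonPrlCountRange,lesionRadiusRange,nStreamlines,gridDim,
#'   gridSpacing,seed cohort parameters, as in \code{\link{CohortConfig}}.
#' @param tStar,selectFraction,sweep,alpha,exclusionDistance analysis
#'   parameters, as in \code{\link{analyzeCohort}}.
#' @return a validated named list.
#' @export
pipelineConfig <- function(nHC = 11L, nMSPRL = 26L, nMSNoPRL = 18L,
                           effectSize = 0.3, prlBoost = 0.5,
                           subjectSD = 0.03, noiseCV = 0.05,
                           prlCountRange = c(1L, 5L),
                           nonPrlCountRange = c(2L, 6L),
                           lesionRadiusRange = c(3, 6), nStreamlines = 400L,
                           gridDim = c(32L, 32L, 16L),
                           gridSpacing = c(2, 2, 2), seed = 1L, tStar = 20,
                           selectFraction = 0.5, sweep = FALSE, alpha = 0.05,
                           exclusionDistance = 1) {
  normalizePipelineConfig(list(
    nHC = nHC, nMSPRL = nMSPRL, nMSNoPRL = nMSNoPRL, effectSize = effectSize,
    prlBoost = prlBoost, subjectSD = subjectSD, noiseCV = noiseCV,
    prlCountRange = prlCountRange, nonPrlCountRange = nonPrlCountRange,
    lesionRadiusRange = lesionRadiusRange, nStreamlines = nStreamlines,
    gridDim = gridDim, gridSpacing = gridSpacing, seed = seed, tStar = tStar,
    selectFraction = selectFraction, sweep = sweep, alpha = alpha,
    exclusionDistance = exclusionDistance))
}

#' @rdname pipelineConfig
#' @param config a pipeline configuration list.
#' @param path a \code{.json} file.
#' @export
writePipelineConfig <- function(config, path) {
  config <- normalizePipelineConfig(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  normalizePipelineConfig(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Extract the cohort-generation part of a pipeline configuration
#'
#' @param config a pipeline configuration list.
#' @return the corresponding \linkS4class{CohortConfig}.
#' @export
asCohortConfig <- function(config) {
  config <- normalizePipelineConfig(config)
  CohortConfig(nHC = config$nHC, nMSPRL = config$nMSPRL,
               nMSNoPRL = config$nMSNoPRL, effectSize = config$effectSize,
               prlBoost = config$prlBoost, subjectSD = config$subjectSD,
               noiseCV = config$noiseCV, prlCountRange = config$prlCountRange,
               nonPrlCountRange = config$nonPrlCountRange,
               lesionRadiusRange = config$lesionRadiusRange,
               nStreamlines = config$nStreamlines, gridDim = config$gridDim,
               gridSpacing = config$gridSpacing, seed = config$seed)
}

#' Persist a synthetic cohort to disk
#'
#' Writes the shared tractogram (\code{tractogram.tck}), the anatomy and
#' analysis masks (NIfTI), the frame-schedule sidecar, per-subject dynamic
#' PET series (\code{pet/<id>_pet.nii.gz} + shared \code{schedule.json}),
#' per-subject lesion masks for MS subjects
#' (\code{lesions/<id>_prl.nii.gz}, \code{<id>_nonprl.nii.gz}),
#' per-HC white-matter masks, the subject table (\code{subjects.csv}) and the
#' generating \linkS4class{CohortConfig} as JSON provenance.
#'
#' @param cohort an \linkS4class{MSCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  grid <- grid3d(cohort)
  for (d in file.path(dir, c(".", "pet", "lesions", "masks")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  writeTractogram(cohort@tractogram, file.path(dir, "tractogram.tck"))
  writeVolume(cohort@wmMask, grid, file.path(dir, "masks", "wm.nii.gz"))
  writeVolume(cohort@grayMask, grid, file.path(dir, "masks", "gray.nii.gz"))
  writeVolume(cohort@brainMask, grid, file.path(dir, "masks", "brain.nii.gz"))
  writeVolume(cohort@exclusionMask, grid,
              file.path(dir, "masks", "exclusion.nii.gz"))
  for (i in seq_along(cohort@hcWMMasks))
    writeVolume(cohort@hcWMMasks[[i]], grid,
                file.path(dir, "masks", sprintf("hc%02d_wm.nii.gz", i)))
  writeFrameSchedule(cohort@schedule, file.path(dir, "schedule.json"))
  for (id in names(cohort@dynamics))
    writeVolume(cohort@dynamics[[id]]@data, grid,
                file.path(dir, "pet", paste0(id, "_pet.nii.gz")))
  for (id in names(cohort@lesions)) {
    les <- cohort@lesions[[id]]
    writeVolume(prlMask(les), grid,
                file.path(dir, "lesions", paste0(id, "_prl.nii.gz")))
    writeVolume(nonPrlMask(les), grid,
                file.path(dir, "lesions", paste0(id, "_nonprl.nii.gz")))
  }
  utils::write.csv(cohort@subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  cfg <- cohort@config
  prov <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(prov) <- slotNames(cfg)
  jsonlite::write_json(prov, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the simulation-to-statistics pipeline and persist the outputs
#'
#' Stages: \emph{simulate} (generate and write the cohort), then the analysis
#' stages of \code{\link{analyzeCohort}} (\emph{masks}, \emph{disrupt},
#' \emph{quantify}, \emph{normalize}, \emph{analyze}). Each stage start is
#' appended to \code{pipeline.log}; a stage failure halts the run with an
#' error naming the stage. Outputs under \code{outDir}: the cohort under
#' \code{cohort/}, the resolved configuration (\code{config.json}), the
#' analysis mask, per-subject global summaries (\code{global.csv}),
#' per-subject per-stratum summaries (\code{strata.csv}) and the tidy
#' statistics table (\code{results.csv}). Given the same configuration the
#' run is fully reproducible.
#'
#' @param config a pipeline configuration (list or path to its JSON file).
#' @param outDir output directory (created if needed).
#' @param verbose also print log lines to the console.
#' @return the \code{\link{analyzeCohort}} result list, invisibly, with the
#'   cohort attached as \code{$cohort}.
#' @export
runPipeline <- function(config, outDir, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- normalizePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "pipeline.log")
  cat("", file = logPath)
  logLine <- function(stage, msg = "started") {
    line <- sprintf("[%s] stage %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = logPath, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    logLine(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  writePipelineConfig(config, file.path(outDir, "config.json"))
  cohort <- stage("simulate", {
    co <- generateCohort(asCohortConfig(config))
    writeCohort(co, file.path(outDir, "cohort"))
    co
  })
  res <- stage("analyze", analyzeCohort(
    cohort, tStar = config$tStar, selectFraction = config$selectFraction,
    sweep = config$sweep, alpha = config$alpha,
    exclusionDistance = config$exclusionDistance, onStage = logLine))
  stage("write-results", {
    writeVolume(res$analysisMask, grid3d(cohort),
                file.path(outDir, "analysis_mask.nii.gz"))
    utils::write.csv(res$global, file.path(outDir, "global.csv"),
                     row.names = FALSE)
    utils::write.csv(res$strata, file.path(outDir, "strata.csv"),
                     row.names = FALSE)
    utils::write.csv(res$results, file.path(outDir, "results.csv"),
                     row.names = FALSE)
  })
  logLine("done", "pipeline complete")
  res$cohort <- cohort
  invisible(res)
}
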