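#' Run the full statistical battery on stratum summaries
#'
#' Reproduces the study's subject-level comparisons on a table of per-subject
#' per-stratum mean z-scores: (i) group contrasts of global mean DVR between
#' HC and the MS groups (ANCOVA on age and sex); (ii) PRL-positive versus
#' PRL-negative ANCOVA of stratum-mean z-DVR per disruption stratum
#' (covariates age, sex, EDSS, MS subtype); (iii) paired t-tests of
#' PRL-disrupted versus non-PRL-disrupted strata within PRL-positive
#' patients; (iv) EDSS linear models per stratum for PRL-positive,
#' PRL-negative and all MS patients (covariates age, sex, MS subtype).
#' Benjamini-Hochberg adjustment is applied within each correction family
#' (one family per analysis, strata pooled; sweep-bin analyses form their own
#' families), recorded in the \code{family} column. Models that cannot be fit
#' (e.g. empty strata, constant groups) yield NA rows annotated in
#' \code{note} instead of aborting the battery.
#'
#' @param strataSummaries data.frame with columns \code{subject_id},
#'   \code{mask_type} (all / prl / non_prl), \code{stratum}, \code{mean_z},
#'   \code{n_voxels} (MS subjects).
#' @param subjects subject table (id, group, prl_positive, age, sex, edss,
#'   ms_type).
#' @param globalSummaries optional data.frame with \code{subject_id} and
#'   \code{mean_dvr} for every subject, enabling the HC contrasts.
#' @param alpha significance level used for the \code{rejected} flag.
#' @return a data.frame of tidy results (one row per contrast x stratum), the
#'   sweep rows carrying families prefixed \code{"sweep_"}.
#' @export
runGroupAnalysis <- function(strataSummaries, subjects,
                             globalSummaries = NULL, alpha = 0.05) {
  res <- list()
  ms <- subjects[subjects$group == "MS", , drop = FALSE]

  trySafe <- function(expr, analysis, mask, stratum, family) {
    row <- tryCatch(expr, error = function(e)
      statRow(analysis, mask, stratum, NA_character_, family = family,
              note = paste("skipped:", conditionMessage(e))))
    row$analysis <- analysis
    row$mask_type <- mask
    row$stratum <- stratum
    row$family <- family
    row
  }

  # (i) global DVR: HC vs MS groups, ANCOVA on age + sex
  if (!is.null(globalSummaries)) {
    g <- merge(subjects, globalSummaries, by.x = "id", by.y = "subject_id")
    g$subgroup <- ifelse(g$group == "HC", "HC",
                         ifelse(g$prl_positive, "MS_PRL", "MS_noPRL"))
    contrasts <- list(
      ms_vs_hc = c("HC", "MS_PRL", "MS_noPRL"),
      prlpos_vs_hc = c("HC", "MS_PRL"),
      prlneg_vs_hc = c("HC", "MS_noPRL"),
      prlpos_vs_prlneg = c("MS_PRL", "MS_noPRL"))
    for (nm in names(contrasts)) {
      sub <- g[g$subgroup %in% contrasts[[nm]], , drop = FALSE]
      grp <- if (nm == "ms_vs_hc") factor(sub$group, c("HC", "MS"))
             else factor(sub$subgroup, contrasts[[nm]])
      res[[length(res) + 1L]] <- trySafe(
        ancova(sub$mean_dvr, grp, sub[, c("age", "sex")]),
        paste0("global_dvr_", nm), "all", "global", "global_dvr")
    }
  }

  ss <- strataSummaries
  trio <- c("none", "low", "high")
  sweepLabs <- intersect(sweepBinLabels(), unique(ss$stratum))

  strataAncova <- function(strata, family) {
    for (s in strata) {
      rows <- ss[ss$mask_type == "all" & ss$stratum == s, , drop = FALSE]
      m <- merge(ms, rows, by.x = "id", by.y = "subject_id")
      m <- m[!is.na(m$mean_z), , drop = FALSE]
      res[[length(res) + 1L]] <<- trySafe(
        ancova(m$mean_z, factor(ifelse(m$prl_positive, "PRL+", "PRL-"),
                                c("PRL-", "PRL+")),
               m[, c("age", "sex", "edss", "ms_type")]),
        "prl_status_ancova", "all", s, family)
    }
  }

  strataPaired <- function(strata, family) {
    prlIds <- ms$id[ms$prl_positive]
    for (s in strata) {
      xp <- ss[ss$mask_type == "prl" & ss$stratum == s, , drop = FALSE]
      xn <- ss[ss$mask_type == "non_prl" & ss$stratum == s, , drop = FALSE]
      x <- xp$mean_z[match(prlIds, xp$subject_id)]
      y <- xn$mean_z[match(prlIds, xn$subject_id)]
      res[[length(res) + 1L]] <<- trySafe(
        pairedTTest(x, y), "paired_prl_vs_nonprl", "prl_vs_non_prl", s,
        family)
    }
  }

  strataEdss <- function(strata, familyPrefix) {
    groups <- list(prlpos = ms$prl_positive, prlneg = !ms$prl_positive,
                   all_ms = rep(TRUE, nrow(ms)))
    for (gnm in names(groups)) {
      family <- paste0(familyPrefix, gnm)
      for (s in strata) {
        rows <- ss[ss$mask_type == "all" & ss$stratum == s, , drop = FALSE]
        m <- merge(ms[groups[[gnm]], , drop = FALSE], rows,
                   by.x = "id", by.y = "subject_id")
        m <- m[!is.na(m$mean_z), , drop = FALSE]
        res[[length(res) + 1L]] <<- trySafe(
          edssAssociation(m$mean_z, m), paste0("edss_", gnm), "all", s,
          family)
      }
    }
  }

  strataAncova(trio, "prl_status_by_stratum")
  strataPaired(trio, "paired_prl_vs_nonprl")
  strataEdss(trio, "edss_")
  if (length(sweepLabs)) {
    strataAncova(sweepLabs, "sweep_prl_status")
    strataPaired(sweepLabs, "sweep_paired")
    strataEdss(sweepLabs, "sweep_edss_")
  }

  out <- do.call(rbind, res)
  rownames(out) <- NULL
  for (fam in unique(out$family)) {
    sel <- which(out$family == fam & !is.na(out$p))
    if (length(sel)) out$p_adj[sel] <- bhAdjust(out$p[sel])
  }
  out$rejected <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

#' Analyse a synthetic cohort end to end
#'
#' Runs the complete quantification pipeline on an \linkS4class{MSCohort}:
#' tractogram voxelization, per-subject disruption maps for the all-lesion,
#' PRL and non-PRL masks, supervised-cluster reference extraction, voxelwise
#' Logan DVR maps on the analysis mask (group WM mask from the HC masks,
#' minus voxels within \code{exclusionDistance} mm of ventricles/cortex),
#' HC-referenced z-scoring, disruption-stratified per-subject means, and the
#' statistical battery of \code{\link{runGroupAnalysis}}.
#'
#' @param cohort an \linkS4class{MSCohort}.
#' @param tStar Logan start time, minutes.
#' @param selectFraction reference-pool fraction for
#'   \code{\link{extractReferenceTAC}}.
#' @param sweep also compute the 0.1-step disruption-level sweep.
#' @param alpha significance level for the \code{rejected} flag.
#' @param exclusionDistance partial-volume guard band, mm.
#' @param onStage optional callback taking a stage name, invoked as each
#'   pipeline stage starts (used by \code{\link{runPipeline}} for logging).
#' @return a list: \code{subjects}, \code{global} (per-subject mean DVR and
#'   mean z), \code{strata} (per-subject per-stratum summaries),
#'   \code{results} (tidy statistics), \code{analysisMask}, \code{dvrMaps},
#'   \code{zMaps}.
#' @export
analyzeCohort <- function(cohort, tStar = 20, selectFraction = 0.5,
                          sweep = FALSE, alpha = 0.05,
                          exclusionDistance = 1, onStage = NULL) {
  note <- function(s) if (!is.null(onStage)) onStage(s)
  grid <- grid3d(cohort)
  subj <- cohort@subjects
  classes <- defaultKineticClasses(cohort@schedule)
  note("masks")
  groupWM <- buildGroupWMMask(cohort@hcWMMasks, grid)
  analysisMask <- excludeBoundary(groupWM@mask, cohort@exclusionMask, grid,
                                  exclusionDistance)
  if (!any(analysisMask))
    stop("analysis mask is empty after boundary exclusion", call. = FALSE)
  note("disrupt")
  voxelIndex <- voxelizeTractogram(cohort@tractogram)

  note("quantify")
  dvrMaps <- lapply(subj$id, function(id) {
    dyn <- cohort@dynamics[[id]]
    ref <- extractReferenceTAC(dyn, cohort@brainMask, classes, selectFraction)
    computeDVRMap(dyn, ref, tStar = tStar, mask = analysisMask)
  })
  names(dvrMaps) <- subj$id

  hcIds <- subj$id[subj$group == "HC"]
  msIds <- subj$id[subj$group == "MS"]
  hcMaps <- dvrMaps[hcIds]

  globalDf <- data.frame(
    subject_id = subj$id,
    mean_dvr = vapply(dvrMaps, function(m)
      mean(m@values[analysisMask], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)

  note("normalize")
  zMaps <- lapply(msIds, function(id) zscoreMap(dvrMaps[[id]], hcMaps,
                                                analysisMask))
  names(zMaps) <- msIds
  globalDf$mean_z <- NA_real_
  globalDf$mean_z[match(msIds, globalDf$subject_id)] <-
    vapply(zMaps, function(z) mean(z@z, na.rm = TRUE), numeric(1))

  maskOf <- function(les, type) switch(type,
    all = allLesions(les), prl = prlMask(les), non_prl = nonPrlMask(les))
  strataRows <- list()
  for (id in msIds) {
    les <- cohort@lesions[[id]]
    for (type in c("all", "prl", "non_prl")) {
      dm <- computeDisruptionMap(cohort@tractogram, maskOf(les, type),
                                 voxelIndex = voxelIndex)
      st <- stratifyDisruption(dm, sweep = sweep)
      sm <- stratifiedMeanZ(zMaps[[id]], st)
      sm$subject_id <- id
      sm$mask_type <- type
      strataRows[[length(strataRows) + 1L]] <- sm
    }
  }
  strataDf <- do.call(rbind, strataRows)
  strataDf <- strataDf[, c("subject_id", "mask_type", "stratum", "mean_z",
                           "n_voxels")]
  rownames(strataDf) <- NULL

  note("analyze")
  results <- runGroupAnalysis(strataDf, subj, globalSummaries = globalDf,
                              alpha = alpha)
  list(subjects = subj, global = globalDf, strata = strataDf,
       results = results, analysisMask = analysisMask, dvrMaps = dvrMaps,
       zMaps = zMaps)
}
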