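# End-to-end experiment orchestration: cohort simulation -> shift
# estimation -> traffic-light protocol -> daily planning -> intrafraction
# and interfraction dose accumulation -> counterfactual re-planning ->
# cohort reporting. Failures are isolated per patient: one failing
# patient is logged and excluded, the run continues.

#' Experiment configuration
#'
#' Bundles the cohort, registration, protocol and plan settings plus the
#' master seed behind two scale presets: `"smoke"` (2 patients on a 24^3
#' grid, single-run registrations) for liveness checks, and `"default"`
#' (8 patients on a 48^3 grid, median of 3 repeats).
#'
#' @param scale `"smoke"` or `"default"`
#' @param seed master seed; every random stream derives from it
#' @param nPatients override the preset patient count
#' @param shiftSource `"estimated"` (registration-derived shifts drive
#'   the protocol) or `"ground_truth"`
#' @param largeMoverFraction mixture weight of large movers
#' @param writeVolumes also write accumulated dose volumes as NIfTI
#' @param cohort optional [cohortConfig()] override
#' @param registration optional [registrationSettings()] override
#' @param protocol optional [trafficLightConfig()] override
#' @param plan optional [planSpec()] override
#' @return list of class `ExperimentConfig`
#' @export
experimentConfig <- function(scale = c("smoke", "default"), seed = 1L,
                             nPatients = NULL,
                             shiftSource = c("estimated", "ground_truth"),
                             largeMoverFraction = 0.1,
                             writeVolumes = FALSE,
                             cohort = NULL, registration = NULL,
                             protocol = NULL, plan = NULL) {
  scale <- match.arg(scale)
  shiftSource <- match.arg(shiftSource)
  preset <- switch(scale,
    smoke = list(nPatients = 2L, gridShape = c(24L, 24L, 24L),
                 gridSpacing = 5,
                 reg = registrationSettings(levels = 2L,
                                            iterations = c(20L, 8L),
                                            refineIterations = 6L,
                                            nRepeats = 1L)),
    default = list(nPatients = 4L, gridShape = c(48L, 48L, 48L),
                   gridSpacing = 2.5,
                   reg = registrationSettings(nRepeats = 3L)))
  if (is.null(nPatients)) nPatients <- preset$nPatients
  if (is.null(cohort))
    cohort <- cohortConfig(nPatients = nPatients,
                           largeMoverFraction = largeMoverFraction,
                           seed = seed)
  if (is.null(registration)) registration <- preset$reg
  if (is.null(protocol)) protocol <- trafficLightConfig()
  if (is.null(plan)) plan <- planSpec()
  structure(list(scale = scale, seed = as.integer(seed),
                 gridShape = preset$gridShape,
                 gridSpacing = preset$gridSpacing,
                 shiftSource = shiftSource, writeVolumes = writeVolumes,
                 cohort = cohort, registration = registration,
                 protocol = protocol, plan = plan),
            class = "ExperimentConfig")
}

#' Estimate the per-session CTV shifts by registration
#'
#' Registers MR1-MR2, MR2-MR3 and MR3-MR4 and averages each field over
#' the CTV of its fixed image, yielding the adapt-to-position shift
#' (`s12`), shift 1 (`shift1`, the MR2-MR3 residual), shift 2 (`shift2`,
#' MR3-MR4), and the cumulative MR1-MR3 shift (`s13 = s12 + shift1`).
#'
#' @param session a [FractionSession-class]
#' @param settings a [registrationSettings()]
#' @return list with `s12`, `s13`, `shift1`, `shift2` (mm, LR/AP/SI)
#' @export
estimateSessionShifts <- function(session,
                                  settings = registrationSettings()) {
  ctv1 <- mask(session@labels, "ctv")
  ctv2 <- mask(session@labelsAt$MR2, "ctv")
  ctv3 <- mask(session@labelsAt$MR3, "ctv")
  f12 <- registerDeformable(session@images$MR1, session@images$MR2, settings)
  f23 <- registerDeformable(session@images$MR2, session@images$MR3, settings)
  f34 <- registerDeformable(session@images$MR3, session@images$MR4, settings)
  s12 <- estimateCtvShift(f12, ctv1)
  shift1 <- estimateCtvShift(f23, ctv2)
  shift2 <- estimateCtvShift(f34, ctv3)
  list(s12 = s12, s13 = s12 + shift1, shift1 = shift1, shift2 = shift2)
}

# ground-truth counterpart from the generating motions
.groundTruthSessionShifts <- function(session) {
  t12 <- session@motions$MR1_MR2$translation
  t23 <- session@motions$MR2_MR3$translation
  t34 <- session@motions$MR3_MR4$translation
  list(s12 = t12, s13 = t12 + t23, shift1 = t23, shift2 = t34)
}

.shiftsToRecords <- function(patientId, shiftsByFraction, source) {
  rows <- list()
  for (fx in seq_along(shiftsByFraction)) {
    sh <- shiftsByFraction[[fx]]
    for (iv in c("shift1", "shift2")) {
      v <- as.numeric(sh[[iv]])
      rows[[length(rows) + 1L]] <- data.frame(
        patient = patientId, fraction = fx, interval = iv,
        dx_lr = v[1], dy_ap = v[2], dz_si = v[3], source = source)
    }
  }
  shiftRecords(do.call(rbind, rows))
}

# full dosimetry for one patient under a given per-fraction plan list;
# the displacement fields depend only on the images, so they are
# computed once and shared between the delivered and counterfactual
# scenarios
.patientFields <- function(sessions, config, seed) {
  list(intra = lapply(seq_along(sessions), function(fx)
         sessionFields(sessions[[fx]], config$registration,
                       seed = .substreamSeed(seed, 830, fx))),
       inter = interfractionFields(sessions, config$registration,
                                   seed = .substreamSeed(seed, 840)))
}

.accumulatePatient <- function(sessions, plans, config, fields) {
  fractionDoses <- lapply(seq_along(sessions), function(fx)
    accumulateIntrafraction(sessions[[fx]], plans[[fx]]$atp1,
                            plans[[fx]]$atp2, config$registration,
                            fields = fields$intra[[fx]]))
  accumulateInterfraction(fractionDoses, sessions, config$registration,
                          fields = fields$inter)
}

# run one patient end to end; returns list(metrics row, state, records)
.runPatient <- function(patient, config) {
  sessions <- patient$sessions
  pid <- patient$patientId
  seedP <- .substreamSeed(config$seed, 850, pid)
  gt <- lapply(sessions, .groundTruthSessionShifts)
  est <- if (config$shiftSource == "estimated")
    lapply(sessions, estimateSessionShifts, settings = config$registration)
  else gt
  recEst <- .shiftsToRecords(pid, est,
                             if (config$shiftSource == "estimated")
                               "estimated" else "ground_truth")
  recGt <- .shiftsToRecords(pid, gt, "ground_truth")
  state <- applyProtocol(recEst, config$protocol,
                         nFractions = length(sessions))
  margins <- activeMargins(state)
  plans <- lapply(seq_along(sessions), function(fx)
    sessionPlans(sessions[[fx]], margins[[fx]], config$plan, est[[fx]]))
  fields <- .patientFields(sessions, config, seedP)
  actual <- .accumulatePatient(sessions, plans, config, fields)
  counterfactual <- NULL
  if (state$switched) {
    cfPlans <- replanCounterfactual(sessions, state, est, config$plan, plans)
    counterfactual <- .accumulatePatient(sessions, cfPlans, config, fields)
  }
  row <- data.frame(patient = pid, largeMover = patient$largeMover,
                    switched = state$switched,
                    switchFraction = if (is.na(state$switchFraction)) NA_integer_
                                     else state$switchFraction,
                    ctv_d99 = actual$metrics$ctv_d99,
                    ctv_d95 = actual$metrics$ctv_d95,
                    rectum_d1cc = actual$metrics$rectum_d1cc,
                    bladder_d5cc = actual$metrics$bladder_d5cc,
                    cf_ctv_d99 = if (is.null(counterfactual)) NA_real_
                                 else counterfactual$metrics$ctv_d99,
                    cf_ctv_d95 = if (is.null(counterfactual)) NA_real_
                                 else counterfactual$metrics$ctv_d95)
  list(row = row, state = state, recordsEstimated = recEst,
       recordsGroundTruth = recGt, actual = actual,
       counterfactual = counterfactual)
}

#' Run a full simulated experiment
#'
#' Simulates the cohort, runs shift estimation, the traffic-light
#' protocol, daily planning, intrafraction and interfraction dose
#' accumulation, and (for switching patients) the counterfactual
#' re-planning with tight margins; writes the report bundle if `outdir`
#' is given. Fully deterministic given the config seed. Per-patient
#' failures are caught, logged and excluded.
#'
#' @param config an [experimentConfig()]
#' @param outdir optional output directory for the report bundle (shift
#'   CSVs, protocol traces, per-patient metrics, cohort summary,
#'   scenario comparison, cumulative shift table, provenance manifest)
#' @return list of class `ExperimentResult` with `perPatient` (metrics
#'   data.frame), `summary` ([summarizeCohort()]), `comparison`
#'   ([compareScenarios()] or NULL), `errorStats`, `records`, `states`,
#'   `failures`
#' @export
runExperiment <- function(config = experimentConfig(), outdir = NULL) {
  grid <- voxelGrid(config$gridShape, spacing = config$gridSpacing)
  cohort <- simulateCohort(config$cohort, grid)
  results <- list(); failures <- list()
  for (p in cohort) {
    r <- tryCatch(.runPatient(p, config), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[as.character(p$patientId)]] <- conditionMessage(r)
      warning("patient ", p$patientId, " failed: ", conditionMessage(r))
    } else results[[as.character(p$patientId)]] <- r
  }
  if (length(results) == 0) stop("all patients failed")
  perPatient <- do.call(rbind, lapply(results, `[[`, "row"))
  rownames(perPatient) <- NULL
  recEst <- shiftRecords(do.call(rbind, lapply(results, function(r)
    as.data.frame(r$recordsEstimated))))
  recGt <- shiftRecords(do.call(rbind, lapply(results, function(r)
    as.data.frame(r$recordsGroundTruth))))
  errorStats <- cohortErrorStats(recEst)
  summary <- summarizeCohort(perPatient)
  comparison <- if (any(perPatient$switched))
    compareScenarios(perPatient) else NULL
  out <- structure(list(perPatient = perPatient, summary = summary,
                        comparison = comparison, errorStats = errorStats,
                        records = list(estimated = recEst,
                                       groundTruth = recGt),
                        states = lapply(results, `[[`, "state"),
                        failures = failures, config = config),
                   class = "ExperimentResult")
  if (!is.null(outdir)) .writeReportBundle(out, results, outdir)
  out
}

.writeReportBundle <- function(result, patientResults, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeShiftRecords(result$records$estimated,
                    file.path(outdir, "shifts_estimated.csv"))
  writeShiftRecords(result$records$groundTruth,
                    file.path(outdir, "shifts_ground_truth.csv"))
  utils::write.csv(result$perPatient,
                   file.path(outdir, "per_patient_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary$bySubgroup,
                   file.path(outdir, "cohort_summary.csv"), row.names = FALSE)
  utils::write.csv(shiftCumulativeTable(result$records$estimated),
                   file.path(outdir, "shift_cumulative.csv"),
                   row.names = FALSE)
  if (!is.null(result$comparison))
    utils::write.csv(result$comparison$perPatient,
                     file.path(outdir, "scenario_comparison.csv"),
                     row.names = FALSE)
  trace <- unlist(lapply(names(result$states), function(pid)
    .formatProtocolTrace(pid, result$states[[pid]])))
  writeLines(trace, file.path(outdir, "protocol_trace.txt"))
  cfg <- result$config
  manifest <- list(
    seed = cfg$seed, scale = cfg$scale, shiftSource = cfg$shiftSource,
    gridShape = cfg$gridShape, gridSpacing = cfg$gridSpacing,
    nPatients = cfg$cohort$nPatients,
    nRepeats = cfg$registration$nRepeats,
    prescriptionGy = cfg$plan$prescriptionGy,
    totalGy = cfg$plan$totalGy,
    packageVersion = as.character(utils::packageVersion("subfracdose")),
    rVersion = R.version.string,
    failures = result$failures)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(cfg$writeVolumes)) {
    for (pid in names(patientResults)) {
      writeVolume(patientResults[[pid]]$actual$totalDose,
                  file.path(outdir, sprintf("accumulated_dose_p%s.nii.gz",
                                            pid)))
    }
  }
  invisible(outdir)
}

#' Compare delivered and counterfactual scenarios
#'
#' For patients with a protocol switch, tabulates the accumulated CTV
#' D99% under the delivered treatment (large margins after the switch)
#' and under counterfactual tight-margin re-planning, in two panels:
#' the delivered scenario and the re-planned scenario, with per-patient
#' deltas, subgroup medians/IQRs, and the number of patients meeting the
#' coverage threshold in each.
#'
#' @param perPatient the per-patient metrics table of
#'   [runExperiment()] (columns `ctv_d99` and `cf_ctv_d99`); or pass two
#'   separate tables via `counterfactual`
#' @param counterfactual optional second table with matching `patient`
#'   and `ctv_d99` columns
#' @param thresholdGy coverage threshold (Gy)
#' @return list of class `ScenarioComparison` with `perPatient`,
#'   `panels`, `passCounts`
#' @export
compareScenarios <- function(perPatient, counterfactual = NULL,
                             thresholdGy = 34.4) {
  if (!is.null(counterfactual)) {
    if (!setequal(perPatient$patient, counterfactual$patient))
      stop("actual and counterfactual patient sets do not match")
    m <- merge(perPatient[c("patient", "ctv_d99")],
               setNames(counterfactual[c("patient", "ctv_d99")],
                        c("patient", "cf_ctv_d99")), by = "patient")
  } else {
    m <- perPatient[!is.na(perPatient$cf_ctv_d99),
                    c("patient", "ctv_d99", "cf_ctv_d99")]
  }
  if (nrow(m) == 0) stop("no matched switching patients to compare")
  m$delta_d99 <- m$ctv_d99 - m$cf_ctv_d99
  panels <- rbind(
    data.frame(panel = "A_delivered_large_margins",
               t(.medianIqr(m$ctv_d99))),
    data.frame(panel = "B_replanned_tight_margins",
               t(.medianIqr(m$cf_ctv_d99))))
  passCounts <- list(
    delivered = sum(m$ctv_d99 >= thresholdGy),
    replanned_tight = sum(m$cf_ctv_d99 >= thresholdGy),
    n = nrow(m))
  structure(list(perPatient = m, panels = panels, passCounts = passCounts,
                 thresholdGy = thresholdGy),
            class = "ScenarioComparison")
}

#' @export
print.ScenarioComparison <- function(x, ...) {
  cat("Scenario comparison (", x$passCounts$n, " switching patients)\n",
      sep = "")
  for (i in seq_len(nrow(x$panels)))
    cat(sprintf("  %s: median D99%% %.1f Gy (IQR: %.1f - %.1f)\n",
                x$panels$panel[i], x$panels$median[i], x$panels$q25[i],
                x$panels$q75[i]))
  cat(sprintf("  above %.1f Gy: delivered %d/%d, re-planned tight %d/%d\n",
              x$thresholdGy, x$passCounts$delivered, x$passCounts$n,
              x$passCounts$replanned_tight, x$passCounts$n))
  invisible(x)
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult: ", nrow(x$perPatient), " patients (",
      sum(x$perPatient$switched), " switched), scale '", x$config$scale,
      "', seed ", x$config$seed, "\n", sep = "")
  print(x$summary)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
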