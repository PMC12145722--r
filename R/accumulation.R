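# Warp-and-sum dose accumulation and DVH evaluation.
#
# Dose maps are warped by pull-back interpolation without Jacobian or
# energy rescaling: dose is treated as an intensive per-voxel quantity
# and the delivered maps are warped directly into the reference frame.
# Intrafraction accumulation registers MR3 and MR4 to MR1 and sums the
# warped first- and second-subfraction doses (the first-subfraction dose
# is associated with MR3 anatomy, acquired during its delivery, to avoid
# under-estimating residual shifts). Interfraction accumulation registers
# the MR1 scans of fractions 2..n to the MR1 scan of fraction 1 with the
# contour-guided engine and sums the warped intrafraction doses.

#' Warp a dose map through a displacement field
#'
#' Pull-back trilinear interpolation of the dose onto the fixed frame.
#'
#' @param dose a [DoseGrid-class]
#' @param field a [DisplacementField-class] on the same grid
#' @return warped [DoseGrid-class]
#' @export
warpDose <- function(dose, field) {
  w <- warpImage(scalarImage(dose@grid, dose@data), field)
  doseGrid(dose@grid, pmax(w@data, 0))
}

#' Intrafraction dose accumulation for one session
#'
#' Registers MR3 and MR4 to MR1 (median-of-repeats), warps the
#' first and second subfraction dose maps through the respective fields,
#' and sums them on the MR1 frame.
#'
#' @param session a [FractionSession-class]
#' @param atp1Dose,atp2Dose [DoseGrid-class] subfraction doses (delivered
#'   while the anatomy was at MR3 and MR4 respectively)
#' @param settings a [registrationSettings()]
#' @param seed seed for the repeat jitter
#' @param fields optional precomputed [sessionFields()] (the
#'   registrations depend only on the images, so counterfactual dose
#'   scenarios can reuse them)
#' @return [DoseGrid-class] on MR1, with a `provenance` attribute
#'   (repeat count, registration warnings)
#' @export
accumulateIntrafraction <- function(session, atp1Dose, atp2Dose,
                                    settings = registrationSettings(),
                                    seed = 1L, fields = NULL) {
  g <- session@images$MR1@grid
  fld <- if (!is.null(fields)) fields
  else sessionFields(session, settings, seed)
  total <- warpDose(atp1Dose, fld[[1]])@data + warpDose(atp2Dose, fld[[2]])@data
  out <- doseGrid(g, total)
  attr(out, "provenance") <- list(
    nRepeats = settings$nRepeats,
    warnings = vapply(fld, function(f) isTRUE(f@log$warning), logical(1)))
  out
}

#' Intrafraction registration fields of a session
#'
#' Median-of-repeats registrations of MR3 and MR4 to MR1.
#' @param session a [FractionSession-class]
#' @param settings a [registrationSettings()]
#' @param seed seed for the repeat jitter
#' @return list of two [DisplacementField-class] (MR1 to MR3, MR1 to MR4)
#' @export
sessionFields <- function(session, settings = registrationSettings(),
                          seed = 1L) {
  g <- session@images$MR1@grid
  lapply(c("MR3", "MR4"), function(mr) {
    medianOfRepeats(function(init)
      registerDeformable(session@images$MR1, session@images[[mr]], settings,
                         init = init),
      grid = g, nRepeats = settings$nRepeats,
      seed = .substreamSeed(seed, session@fraction, match(mr, c("MR3", "MR4"))),
      jitterSdMm = settings$jitterSdMm)
  })
}

#' Interfraction registration fields onto the fraction-1 frame
#'
#' Contour-guided, median-of-repeats registrations of each later
#' fraction's MR1 to the fraction-1 MR1, with guidance restricted to the
#' ring around the tight-margin PTV.
#' @param sessions list of [FractionSession-class]
#' @param settings a [registrationSettings()]
#' @param ringExtentMm passed to [makeRing()]
#' @param seed seed for the repeat jitter
#' @return list of [DisplacementField-class], element 1 is NULL
#'   (fraction 1 is the reference)
#' @export
interfractionFields <- function(sessions,
                                settings = registrationSettings(),
                                ringExtentMm = c(20, 20, 10), seed = 1L) {
  ref <- sessions[[1]]
  g <- ref@images$MR1@grid
  labs1 <- ref@labels
  ptv <- expandMargin(mask(labs1, "ctv"), marginSpec("tight"), g)
  ring <- makeRing(ptv, g, ringExtentMm)
  organs <- c("bladder", "prostate", "rectum")
  flds <- vector("list", length(sessions))
  if (length(sessions) > 1) for (k in 2:length(sessions)) {
    guidance <- list(
      fixed = setNames(lapply(organs, function(o) mask(labs1, o)), organs),
      moving = setNames(lapply(organs, function(o)
        mask(sessions[[k]]@labels, o)), organs),
      ring = ring)
    flds[[k]] <- medianOfRepeats(function(init)
      registerContourGuided(ref@images$MR1, sessions[[k]]@images$MR1,
                            guidance, settings, init = init),
      grid = g, nRepeats = settings$nRepeats,
      seed = .substreamSeed(seed, 820, k), jitterSdMm = settings$jitterSdMm)
  }
  flds
}

#' Interfraction dose accumulation onto the fraction-1 frame
#'
#' Registers the MR1 scan of every later fraction to the fraction-1 MR1
#' with the contour-guided engine (guidance restricted to the ring around
#' the PTV), warps each fraction's intrafraction dose and sums. DVH
#' metrics and constraint flags are evaluated on the fraction-1
#' structures.
#'
#' @param fractionDoses list of [DoseGrid-class], one per fraction, each
#'   on its own fraction's MR1 frame
#' @param sessions list of [FractionSession-class] (same order)
#' @param settings a [registrationSettings()]
#' @param constraints a [constraintSet()]
#' @param ringExtentMm passed to [makeRing()]
#' @param seed seed for repeat jitter
#' @param fields optional precomputed [interfractionFields()]
#' @return list of class `AccumulationResult`: `totalDose`
#'   ([DoseGrid-class] on fraction-1 MR1), `perFraction` (warped
#'   [DoseGrid-class] list), `metrics`, `constraintFlags`, `provenance`
#' @export
accumulateInterfraction <- function(fractionDoses, sessions,
                                    settings = registrationSettings(),
                                    constraints = constraintSet(),
                                    ringExtentMm = c(20, 20, 10),
                                    seed = 1L, fields = NULL) {
  stopifnot(length(fractionDoses) >= 1,
            length(fractionDoses) == length(sessions))
  ref <- sessions[[1]]
  g <- ref@images$MR1@grid
  labs1 <- ref@labels
  if (is.null(fields))
    fields <- interfractionFields(sessions, settings, ringExtentMm, seed)
  warped <- vector("list", length(sessions))
  warned <- logical(length(sessions))
  warped[[1]] <- fractionDoses[[1]]
  if (length(sessions) > 1) for (k in 2:length(sessions)) {
    warned[k] <- isTRUE(fields[[k]]@log$warning)
    warped[[k]] <- warpDose(fractionDoses[[k]], fields[[k]])
  }
  total <- Reduce(`+`, lapply(warped, function(d) d@data))
  totalDose <- doseGrid(g, total)
  metrics <- list(
    ctv_d99 = dvhQuery(totalDose, mask(labs1, "ctv"), "D99%"),
    ctv_d95 = dvhQuery(totalDose, mask(labs1, "ctv"), "D95%"),
    rectum_d1cc = dvhQuery(totalDose, mask(labs1, "rectum"), "D1cc"),
    bladder_d5cc = dvhQuery(totalDose, mask(labs1, "bladder"), "D5cc"))
  structure(list(totalDose = totalDose, perFraction = warped,
                 metrics = metrics,
                 constraintFlags = checkConstraints(metrics, constraints),
                 provenance = list(nRepeats = settings$nRepeats,
                                   registrationWarnings = warned,
                                   oarNote = paste(
                                     "rectum/bladder metrics reliable only",
                                     "near the target: contours are",
                                     "corrected only within the ring"))),
            class = "AccumulationResult")
}

#' @export
print.AccumulationResult <- function(x, ...) {
  cat("AccumulationResult:\n")
  for (nm in names(x$metrics))
    cat(sprintf("  %-13s %6.2f Gy  [%s]\n", nm, x$metrics[[nm]],
                if (is.na(x$constraintFlags[[nm]])) "-"
                else if (x$constraintFlags[[nm]]) "pass" else "FAIL"))
  cat(" ", x$provenance$oarNote, "\n")
  invisible(x)
}

#' Dose-volume histogram query
#'
#' `"Dp%"` is the near-minimum dose received by the hottest p% of the
#' structure volume; `"Dvcc"` the minimum dose of the hottest v cm3.
#' Both are evaluated on the sorted voxel doses with linear interpolation
#' between order statistics: with doses sorted hottest-first, the value
#' at fractional rank `r = p/100 * (N-1) + 1` (respectively
#' `r = (v / voxelVolume - 1) * ... + 1` expressed through the same rank
#' convention) is returned.
#'
#' @param dose a [DoseGrid-class]
#' @param structureMask logical mask (nonempty) on the dose grid
#' @param query a string like `"D99%"`, `"D95%"`, `"D1cc"`, `"D5cc"`
#' @return dose in Gy
#' @export
dvhQuery <- function(dose, structureMask, query) {
  if (!any(structureMask)) stop("structure mask is empty")
  vals <- sort(dose@data[structureMask], decreasing = TRUE)
  N <- length(vals)
  qp <- toupper(gsub(" ", "", query))
  if (grepl("^D[0-9.]+%$", qp)) {
    p <- as.numeric(sub("^D([0-9.]+)%$", "\\1", qp))
    if (p <= 0 || p > 100) stop("percentage query must be in (0, 100]")
    r <- p / 100 * (N - 1) + 1
  } else if (grepl("^D[0-9.]+(CC|CM3)$", qp)) {
    v <- as.numeric(sub("^D([0-9.]+)(CC|CM3)$", "\\1", qp))
    volCc <- N * voxelVolumeCc(dose@grid)
    if (v > volCc)
      stop(sprintf("structure volume %.2f cm3 is smaller than query %.2f cm3",
                   volCc, v))
    r <- v / volCc * (N - 1) + 1
  } else stop("unrecognised DVH query '", query, "'")
  lo <- floor(r); hi <- ceiling(r)
  if (lo < 1) return(vals[1])
  vals[lo] + (r - lo) * (vals[min(hi, N)] - vals[lo])
}

#' Clinical dose constraints
#'
#' Target coverage and organ-at-risk limits: CTV D99% at or above
#' `ctvD99Gy`; rectum D1cm3 below `rectumD1ccGy`; bladder D5cm3 below
#' `bladderD5ccGy`.
#'
#' @param ctvD99Gy CTV coverage threshold (Gy)
#' @param rectumD1ccGy rectum hot-volume limit (Gy)
#' @param bladderD5ccGy bladder hot-volume limit (Gy)
#' @return list of class `ConstraintSet`
#' @export
constraintSet <- function(ctvD99Gy = 34.4, rectumD1ccGy = 38.0,
                          bladderD5ccGy = 37.0) {
  stopifnot(ctvD99Gy > 0, rectumD1ccGy > 0, bladderD5ccGy > 0)
  structure(list(ctvD99Gy = ctvD99Gy, rectumD1ccGy = rectumD1ccGy,
                 bladderD5ccGy = bladderD5ccGy), class = "ConstraintSet")
}

#' Evaluate constraint flags for a metric set
#' @param metrics named list with `ctv_d99`, `rectum_d1cc`, `bladder_d5cc`
#' @param constraints a [constraintSet()]
#' @return named logical list (TRUE = constraint met)
#' @export
checkConstraints <- function(metrics, constraints = constraintSet()) {
  list(ctv_d99 = metrics$ctv_d99 >= constraints$ctvD99Gy,
       ctv_d95 = NA,
       rectum_d1cc = metrics$rectum_d1cc < constraints$rectumD1ccGy,
       bladder_d5cc = metrics$bladder_d5cc < constraints$bladderD5ccGy)
}

.medianIqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

#' Cohort summary of accumulated metrics
#'
#' Median and interquartile range of the accumulated CTV D99%/D95% and
#' OAR hot-volume doses, split by protocol subgroup (tight-margin
#' completers vs switchers), plus the fraction of patients meeting the
#' coverage threshold.
#'
#' @param perPatient data.frame with one row per patient: columns
#'   `patient`, `switched`, `ctv_d99`, `ctv_d95`, `rectum_d1cc`,
#'   `bladder_d5cc`
#' @param constraints a [constraintSet()]
#' @return list of class `CohortSummary` with `bySubgroup` (data.frame of
#'   median/IQR per metric and subgroup) and `coverage` (pass fractions)
#' @export
summarizeCohort <- function(perPatient, constraints = constraintSet()) {
  stopifnot(nrow(perPatient) >= 1)
  mets <- c("ctv_d99", "ctv_d95", "rectum_d1cc", "bladder_d5cc")
  groups <- split(perPatient,
                  ifelse(perPatient$switched, "switched", "tight"))
  rows <- list()
  for (gnm in names(groups)) for (mv in mets) {
    if (!mv %in% names(groups[[gnm]])) next
    s <- .medianIqr(groups[[gnm]][[mv]])
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup = gnm, metric = mv, n = nrow(groups[[gnm]]),
      median = s["median"], q25 = s["q25"], q75 = s["q75"])
  }
  bySub <- do.call(rbind, rows); rownames(bySub) <- NULL
  coverage <- vapply(groups, function(d)
    mean(d$ctv_d99 >= constraints$ctvD99Gy), numeric(1))
  structure(list(bySubgroup = bySub,
                 coverage = as.list(coverage),
                 nPatients = nrow(perPatient)),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("Cohort summary (", x$nPatients, " patients)\n", sep = "")
  for (i in seq_len(nrow(x$bySubgroup))) {
    r <- x$bySubgroup[i, ]
    cat(sprintf("  %-8s %-13s n=%-3d median %.1f Gy (IQR: %.1f - %.1f)\n",
                r$subgroup, r$metric, r$n, r$median, r$q25, r$q75))
  }
  for (gnm in names(x$coverage))
    cat(sprintf("  %s: %.0f%% of patients with CTV D99%% above threshold\n",
                gnm, 100 * x$coverage[[gnm]]))
  invisible(x)
}
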