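# Geometric shift bookkeeping and the traffic-light margin-adaptation
# protocol.
#
# Residual intrafraction motion is summarised per subfraction interval:
# shift 1 is the CTV translation between MR2 and MR3, shift 2 between
# MR3 and MR4. Fractions 1-3 are monitored; an orange light at fraction 3
# extends monitoring to fraction 4; a red light in any monitored fraction
# switches all subsequent fractions to the large (5 mm isotropic)
# margins. The switch is absorbing.
#
# The green/orange/red thresholds are configuration values. The defaults
# (green < 3 mm, orange 3-5 mm, red >= 5 mm on the per-subfraction 3D
# magnitude) are deliberately NOT the 2-3 mm planning margins: averaging
# over ten subfractions makes per-subfraction excursions of the margin
# size routine, and using them as triggers would cause numerous
# unwarranted interventions.

#' Construct / validate a shift record table
#'
#' A `ShiftRecord` data.frame has one row per (patient, fraction,
#' subfraction interval) with the CTV translation in mm along LR/AP/SI,
#' its 3D magnitude, and whether it came from registration estimates or
#' simulator ground truth.
#'
#' @param df data.frame with columns `patient`, `fraction`, `interval`
#'   (`"shift1"` or `"shift2"`), `dx_lr`, `dy_ap`, `dz_si`, `source`
#' @return the validated data.frame with a `magnitude` column, class
#'   `ShiftRecord`
#' @export
shiftRecords <- function(df) {
  need <- c("patient", "fraction", "interval", "dx_lr", "dy_ap", "dz_si",
            "source")
  if (!all(need %in% names(df)))
    stop("shift records need columns: ", paste(need, collapse = ", "))
  if (!all(df$interval %in% c("shift1", "shift2")))
    stop("interval must be 'shift1' or 'shift2'")
  df$magnitude <- sqrt(df$dx_lr^2 + df$dy_ap^2 + df$dz_si^2)
  rownames(df) <- NULL
  class(df) <- c("ShiftRecord", "data.frame")
  df
}

#' Cohort systematic and random error statistics
#'
#' Per axis, the systematic error Sigma is the SD over patients of the
#' per-patient mean shift, and the random error sigma is the RMS over
#' patients of the within-patient SD. Patients with fewer than two
#' records contribute to Sigma but are excluded from sigma with a
#' warning. A cohort-level mean and SD of the 3D shift magnitudes is
#' included.
#'
#' @param records a [shiftRecords()] table
#' @return list of class `ErrorStats` with per-axis `mean`, `Sigma`,
#'   `sigma` (mm, named LR/AP/SI) and `magnitudeMean`, `magnitudeSd`
#' @export
cohortErrorStats <- function(records) {
  stopifnot(nrow(records) >= 1)
  axes <- c("dx_lr", "dy_ap", "dz_si")
  sp <- split(records, records$patient)
  perMean <- t(vapply(sp, function(d) colMeans(d[axes]), numeric(3)))
  nRec <- vapply(sp, nrow, integer(1))
  if (any(nRec < 2))
    warning(sum(nRec < 2), " patient(s) with a single record excluded ",
            "from the random-error estimate")
  multi <- sp[nRec >= 2]
  if (length(perMean) && nrow(perMean) >= 2) {
    Sigma <- apply(perMean, 2, sd)
  } else Sigma <- rep(0, 3)
  if (length(multi) >= 1) {
    perSd <- t(vapply(multi, function(d) vapply(d[axes], sd, numeric(1)),
                      numeric(3)))
    sigma <- sqrt(colMeans(perSd^2))
  } else sigma <- rep(0, 3)
  structure(list(mean = setNames(colMeans(perMean), .AXES),
                 Sigma = setNames(Sigma, .AXES),
                 sigma = setNames(sigma, .AXES),
                 magnitudeMean = mean(records$magnitude),
                 magnitudeSd = sd(records$magnitude),
                 nPatients = length(sp), nRecords = nrow(records)),
            class = "ErrorStats")
}

#' @export
print.ErrorStats <- function(x, ...) {
  # reported in LR, SI, AP order, "mean +/- SD" per axis
  ord <- c("LR", "SI", "AP")
  cat("Cohort shift statistics (", x$nPatients, " patients, ",
      x$nRecords, " subfraction records)\n", sep = "")
  cat("  systematic errors (", paste(ord, collapse = ", "), "): ",
      paste(sprintf("%.1f ± %.1f mm", x$mean[ord], x$Sigma[ord]),
            collapse = ", "), "\n", sep = "")
  cat("  random errors sigma (", paste(ord, collapse = ", "), "): ",
      paste(sprintf("%.1f mm", x$sigma[ord]), collapse = ", "), "\n", sep = "")
  cat(sprintf("  3D shift magnitude: %.1f mm (SD: %.1f mm)\n",
              x$magnitudeMean, x$magnitudeSd))
  invisible(x)
}

#' CTV-to-PTV margin from cohort error statistics
#'
#' The community-standard linear margin recipe: per-axis margin =
#' `a * Sigma + b * sigma` with the usual population coefficients
#' a = 2.5 (systematic) and b = 0.7 (random).
#'
#' @param stats an [cohortErrorStats()] result
#' @param a,b non-negative recipe coefficients
#' @return a [marginSpec()]
#' @export
vanHerkMargin <- function(stats, a = 2.5, b = 0.7) {
  if (a < 0 || b < 0) stop("margin recipe coefficients must be non-negative")
  m <- a * stats$Sigma + b * stats$sigma
  marginSpec(m[1], m[2], m[3])
}

#' Traffic-light protocol configuration
#'
#' Colour thresholds on the per-subfraction 3D shift magnitude: green
#' below `greenMm`, red at or above `redMm`, orange between. Fractions in
#' `monitoredFractions` are evaluated; an orange light at the last
#' monitored fraction extends monitoring by one fraction
#' (`orangeEscalation`); a red light in a monitored fraction switches all
#' subsequent fractions to `largeMargins`.
#'
#' @param greenMm,redMm thresholds in mm (`greenMm <= redMm`)
#' @param monitoredFractions integer vector (default 1:3)
#' @param orangeEscalation logical, extend monitoring after an orange at
#'   the last monitored fraction (default TRUE)
#' @param tightMargins,largeMargins [marginSpec()] presets
#' @return list of class `TrafficLightConfig`
#' @export
trafficLightConfig <- function(greenMm = 3, redMm = 5,
                               monitoredFractions = 1:3,
                               orangeEscalation = TRUE,
                               tightMargins = marginSpec("tight"),
                               largeMargins = marginSpec("large")) {
  if (!(greenMm <= redMm)) stop("green threshold must not exceed red")
  structure(list(greenMm = greenMm, redMm = redMm,
                 monitoredFractions = as.integer(monitoredFractions),
                 orangeEscalation = isTRUE(orangeEscalation),
                 tightMargins = tightMargins, largeMargins = largeMargins),
            class = "TrafficLightConfig")
}

#' Initial traffic-light state
#' @param config a [trafficLightConfig()]
#' @param nFractions number of fractions in the treatment
#' @return list of class `TrafficLightState`
#' @export
trafficLightInit <- function(config, nFractions = 5L) {
  structure(list(config = config, nFractions = as.integer(nFractions),
                 colours = setNames(rep(NA_character_, nFractions),
                                    paste0("fx", seq_len(nFractions))),
                 monitored = as.integer(config$monitoredFractions),
                 evaluated = integer(0),
                 switched = FALSE, switchFraction = NA_integer_,
                 log = character(0)),
            class = "TrafficLightState")
}

.classifyColour <- function(magnitudes, config) {
  if (length(magnitudes) == 0 || any(!is.finite(magnitudes)))
    return("orange") # unevaluable: treated conservatively
  m <- max(magnitudes)
  if (m >= config$redMm) "red" else if (m >= config$greenMm) "orange"
  else "green"
}

#' Advance the traffic-light state by one fraction
#'
#' Classifies the fraction from its two subfraction shift magnitudes
#' (either may trigger), updates the monitoring schedule and, on a red
#' light in a monitored fraction, sets the absorbing switch so all
#' subsequent fractions use the large margins.
#'
#' @param state a `TrafficLightState`
#' @param fraction fraction index being evaluated
#' @param records [shiftRecords()] rows for this patient and fraction
#'   (subfractions shift1 and shift2); missing records make the fraction
#'   unevaluable and it is treated as orange
#' @return updated `TrafficLightState`
#' @export
trafficLightStep <- function(state, fraction, records) {
  cfg <- state$config
  rows <- records[records$fraction == fraction, , drop = FALSE]
  if (nrow(rows) < 2)
    state$log <- c(state$log, sprintf(
      "fraction %d: %d/2 subfraction shifts available; treated conservatively",
      fraction, nrow(rows)))
  colour <- .classifyColour(rows$magnitude, cfg)
  state$colours[fraction] <- colour
  monitoredNow <- fraction %in% state$monitored && !state$switched
  if (monitoredNow) {
    state$evaluated <- c(state$evaluated, as.integer(fraction))
    if (colour == "red") {
      state$switched <- TRUE
      state$switchFraction <- as.integer(min(fraction + 1L, state$nFractions + 1L))
      state$log <- c(state$log, sprintf(
        "fraction %d: red light; switching to larger margins from fraction %d",
        fraction, state$switchFraction))
    } else if (colour == "orange" && cfg$orangeEscalation &&
               fraction == max(state$monitored) &&
               fraction + 1L <= state$nFractions) {
      state$monitored <- c(state$monitored, as.integer(fraction + 1L))
      state$log <- c(state$log, sprintf(
        "fraction %d: orange light; fraction %d also monitored",
        fraction, fraction + 1L))
    } else {
      state$log <- c(state$log, sprintf("fraction %d: %s light", fraction,
                                        colour))
    }
  } else {
    state$log <- c(state$log, sprintf("fraction %d: %s (not monitored)",
                                      fraction, colour))
  }
  state
}

#' Margins in force for each fraction of a protocol trace
#' @param state a `TrafficLightState`
#' @return list of [marginSpec()] per fraction
#' @export
activeMargins <- function(state) {
  lapply(seq_len(state$nFractions), function(fx) {
    if (state$switched && !is.na(state$switchFraction) &&
        fx >= state$switchFraction)
      state$config$largeMargins
    else state$config$tightMargins
  })
}

#' Run the traffic-light protocol over a patient's shift records
#'
#' @param records [shiftRecords()] for one patient (both subfraction
#'   intervals of each delivered fraction)
#' @param config a [trafficLightConfig()]
#' @param nFractions number of fractions
#' @return final `TrafficLightState` (with `activeMargins()` giving the
#'   per-fraction margins for the dosimetry modules)
#' @export
applyProtocol <- function(records, config = trafficLightConfig(),
                          nFractions = 5L) {
  state <- trafficLightInit(config, nFractions)
  for (fx in seq_len(nFractions))
    state <- trafficLightStep(state, fx, records)
  state
}

#' @export
print.TrafficLightState <- function(x, ...) {
  cat("Traffic-light protocol trace:\n")
  for (fx in seq_len(x$nFractions)) {
    cat(sprintf("  fraction %d: %-7s margins LR/AP/SI = %s mm%s\n", fx,
                ifelse(is.na(x$colours[fx]), "-", x$colours[fx]),
                paste(format(activeMargins(x)[[fx]], digits = 2),
                      collapse = "/"),
                if (!is.na(x$switchFraction) && fx == x$switchFraction)
                  "  <- switched" else ""))
  }
  invisible(x)
}

#' Cumulative distribution of 3D shifts per fraction
#'
#' Table in the style of a cumulative-distribution plot of the residual
#' 3D intrafraction shift per fraction: for each fraction, the fraction
#' of subfraction shifts at or below each magnitude grid point.
#'
#' @param records a [shiftRecords()] table
#' @param breaksMm magnitude grid in mm
#' @return data.frame with columns `fraction`, `magnitudeMm`,
#'   `cumulativeFraction`
#' @export
shiftCumulativeTable <- function(records, breaksMm = seq(0, 10, by = 0.5)) {
  out <- do.call(rbind, lapply(split(records, records$fraction), function(d) {
    data.frame(fraction = d$fraction[1], magnitudeMm = breaksMm,
               cumulativeFraction = vapply(breaksMm, function(b)
                 mean(d$magnitude <= b), numeric(1)))
  }))
  rownames(out) <- NULL
  out
}
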