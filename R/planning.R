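# Target-volume construction and the idealized dose model.
#
# The dose model is purely geometric: the per-subfraction prescription is
# delivered uniformly inside the PTV and falls off outside as a Gaussian
# of the Euclidean distance to the PTV surface. This gives the plausible
# dose gradients the accumulation analysis needs without a beam/fluence
# model (machine plan optimisation is out of scope).

#' Per-axis planning margins
#'
#' Margins in mm along (LR, AP, SI). Two named presets reflect the
#' clinical protocol: `"tight"` = 2 mm LR, 3 mm AP, 2 mm SI, and
#' `"large"` = 5 mm isotropic.
#'
#' @param lr,ap,si margins in mm, or `lr` may be a preset name
#' @return named numeric(3) of class `MarginSpec`
#' @examples
#' marginSpec("tight")
#' marginSpec(2, 3, 2)
#' @export
marginSpec <- function(lr, ap = NULL, si = NULL) {
  if (is.character(lr)) {
    m <- switch(lr,
      tight = c(2, 3, 2),
      large = c(5, 5, 5),
      stop("unknown margin preset '", lr, "'")
    )
  } else {
    if (is.null(ap)) { m <- rep_len(as.numeric(lr), 3) }
    else m <- c(lr, ap, si)
  }
  if (length(m) != 3 || any(!is.finite(m)) || any(m < 0))
    stop("margins must be 3 non-negative finite values (mm)")
  structure(setNames(as.numeric(m), .AXES), class = "MarginSpec")
}

#' @export
print.MarginSpec <- function(x, ...) {
  cat(sprintf("MarginSpec: LR %.1f / AP %.1f / SI %.1f mm\n",
              x[1], x[2], x[3]))
  invisible(x)
}

#' Build the clinical target volume from the GTV and prostate
#'
#' The CTV is the prostate plus a 4 mm isotropic expansion of the GTV
#' (accounting for microscopic spread), with bladder and rectum voxels
#' excluded.
#'
#' @param gtv,prostate,bladder,rectum logical masks on a shared grid
#' @param grid the [VoxelGrid-class] the masks live on
#' @param gtvExpansionMm isotropic GTV expansion in mm (default 4)
#' @return logical CTV mask
#' @export
ctvFromGtv <- function(gtv, prostate, bladder, rectum, grid,
                       gtvExpansionMm = 4) {
  if (!any(prostate)) stop("prostate mask is empty")
  ctv <- prostate
  if (any(gtv)) {
    d2 <- .edtSquared(gtv, grid@spacing, dmax = gtvExpansionMm + max(grid@spacing))
    ctv <- ctv | (d2 <= gtvExpansionMm^2)
  }
  ctv & !bladder & !rectum
}

#' Anisotropic margin expansion (CTV to PTV)
#'
#' Dilates a mask with an ellipsoidal structuring element whose semi-axes
#' are the per-axis margins: a voxel belongs to the PTV iff its
#' axis-scaled distance to the CTV is at most 1.
#'
#' @param ctv logical mask
#' @param margins a [marginSpec()]
#' @param grid the [VoxelGrid-class]
#' @return logical PTV mask
#' @export
expandMargin <- function(ctv, margins, grid) {
  stopifnot(any(ctv))
  m <- as.numeric(margins)
  if (all(m == 0)) return(ctv)
  m <- pmax(m, 1e-9)
  d2 <- .edtSquared(ctv, grid@spacing / m, dmax = 1.5)
  ptv <- ctv | (d2 <= 1)
  # the PTV must stay on the grid (no mass on the outermost voxel shell)
  sh <- grid@shape
  edge <- array(FALSE, dim = sh)
  edge[c(1, sh[1]), , ] <- TRUE; edge[, c(1, sh[2]), ] <- TRUE
  edge[, , c(1, sh[3])] <- TRUE
  if (any(ptv & edge)) stop("PTV expansion exceeds the grid")
  ptv
}

#' Ring structure around the PTV
#'
#' The shell in which daily contours are corrected and contour guidance
#' applies: an anisotropic expansion of the PTV by 20 mm in the LR and AP
#' directions and 10 mm in the SI (cranio-caudal) direction, minus the
#' PTV itself.
#'
#' @param ptv logical PTV mask
#' @param grid the [VoxelGrid-class]
#' @param extentMm numeric(3) expansion distances in mm (LR, AP, SI)
#' @return logical ring mask (disjoint from the PTV)
#' @export
makeRing <- function(ptv, grid, extentMm = c(20, 20, 10)) {
  stopifnot(any(ptv))
  d2 <- .edtSquared(ptv, grid@spacing / extentMm, dmax = 1.5)
  (d2 <= 1) & !ptv
}

#' Per-subfraction plan specification
#'
#' The fractionation scheme: each of `nFractions` sessions is split into
#' `nSubfractions` deliveries of `prescriptionGy`, so the scheme totals
#' `prescriptionGy * nSubfractions * nFractions` (default
#' 3.625 Gy x 2 x 5 = 36.25 Gy).
#'
#' @param prescriptionGy dose per subfraction in Gy
#' @param nFractions number of treatment fractions
#' @param nSubfractions deliveries per fraction
#' @param penumbraMm Gaussian penumbra scale in mm
#' @return list of class `PlanSpec`
#' @export
planSpec <- function(prescriptionGy = 3.625, nFractions = 5L,
                     nSubfractions = 2L, penumbraMm = 3) {
  stopifnot(prescriptionGy > 0, nFractions >= 1, nSubfractions >= 1)
  if (penumbraMm <= 0) stop("penumbra scale must be positive")
  structure(list(prescriptionGy = prescriptionGy,
                 nFractions = as.integer(nFractions),
                 nSubfractions = as.integer(nSubfractions),
                 totalGy = prescriptionGy * nFractions * nSubfractions,
                 penumbraMm = penumbraMm),
            class = "PlanSpec")
}

#' Idealized per-subfraction dose plan
#'
#' Prescription dose inside the PTV; outside, the dose falls off as
#' `exp(-d^2 / (2 s^2))` of the Euclidean distance d (mm) to the PTV with
#' penumbra scale s.
#'
#' @param ptv logical PTV mask
#' @param grid the [VoxelGrid-class]
#' @param spec a [planSpec()]
#' @return [DoseGrid-class] for one subfraction delivery
#' @export
makePlan <- function(ptv, grid, spec = planSpec()) {
  stopifnot(any(ptv))
  s <- spec$penumbraMm
  dmax <- 5 * s
  d2 <- .edtSquared(ptv, grid@spacing, dmax = dmax)
  dose <- spec$prescriptionGy * exp(-d2 / (2 * s^2))
  dose[ptv] <- spec$prescriptionGy
  dose[d2 >= dmax^2] <- 0
  doseGrid(grid, dose)
}

#' Adapt-to-position: rigid shift of a planned dose distribution
#'
#' Translates the dose by `shiftMm` (the estimated target displacement)
#' and resamples trilinearly. Errors if the translation would move
#' appreciable dose (> 1% of the maximum) off the grid.
#'
#' @param plan a [DoseGrid-class]
#' @param shiftMm numeric(3) translation in mm (LR, AP, SI)
#' @return shifted [DoseGrid-class]
#' @export
adaptToPosition <- function(plan, shiftMm) {
  g <- plan@grid
  stopifnot(length(shiftMm) == 3, all(is.finite(shiftMm)))
  if (all(shiftMm == 0)) return(plan)
  shiftVox <- shiftMm / g@spacing
  sh <- g@shape
  # support check: significant dose must remain on the grid after the shift
  sig <- which(plan@data > 0.01 * max(plan@data), arr.ind = TRUE)
  if (nrow(sig) > 0) {
    moved <- sweep(sig, 2, shiftVox, "+")
    if (any(moved < 1) || any(sweep(moved, 2, sh, ">")))
      stop("adapt-to-position shift moves the dose support off the grid")
  }
  idx <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]), z = seq_len(sh[3]))
  vals <- .interpTrilinear(plan@data, idx$x - shiftVox[1], idx$y - shiftVox[2],
                           idx$z - shiftVox[3])
  doseGrid(g, array(pmax(vals, 0), dim = sh))
}

#' Per-session subfraction plans
#'
#' Daily planning on the session's MR1 anatomy: the CTV is expanded by
#' the active margins to the PTV, one base plan is made, and the two
#' adapt-to-position deliveries are the base plan shifted by the
#' estimated target position at delivery time (ATP1 uses the MR1-to-MR2
#' shift; ATP2 additionally corrects the MR2-to-MR3 shift).
#'
#' @param session a [FractionSession-class]
#' @param margins the active [marginSpec()] for this fraction
#' @param spec a [planSpec()]
#' @param shifts list with `s12` and `s13`: estimated cumulative CTV
#'   shifts (mm) from MR1 to MR2 and from MR1 to MR3
#' @return list with `ptv`, `basePlan`, `atp1`, `atp2`
#' @export
sessionPlans <- function(session, margins, spec = planSpec(),
                         shifts = list(s12 = c(0, 0, 0), s13 = c(0, 0, 0))) {
  g <- session@images$MR1@grid
  ptv <- expandMargin(mask(session@labels, "ctv"), margins, g)
  base <- makePlan(ptv, g, spec)
  list(ptv = ptv,
       basePlan = base,
       atp1 = adaptToPosition(base, shifts$s12),
       atp2 = adaptToPosition(base, shifts$s13))
}

#' Counterfactual re-planning with the original tight margins
#'
#' For fractions delivered with the large margins after a protocol
#' switch, substitutes plans built with the tight margins on the same
#' anatomy and the same estimated shifts, so dose accumulation can be
#' repeated under the counterfactual scenario. Patients who never
#' switched are returned unchanged.
#'
#' @param sessions list of [FractionSession-class]
#' @param protocolState a `TrafficLightState` from [applyProtocol()]
#' @param sessionShifts list (per fraction) of `shifts` as in
#'   [sessionPlans()]
#' @param spec a [planSpec()]
#' @param actualPlans list (per fraction) of [sessionPlans()] results for
#'   the delivered treatment
#' @return list (per fraction) of plan sets; post-switch fractions are
#'   re-planned with the tight margins
#' @export
replanCounterfactual <- function(sessions, protocolState, sessionShifts,
                                 spec = planSpec(), actualPlans) {
  tight <- protocolState$config$tightMargins
  lapply(seq_along(sessions), function(fx) {
    if (protocolState$switched && !is.na(protocolState$switchFraction) &&
        fx >= protocolState$switchFraction) {
      sessionPlans(sessions[[fx]], tight, spec, sessionShifts[[fx]])
    } else actualPlans[[fx]]
  })
}
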