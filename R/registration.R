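# Variational deformable image registration engine.
#
# A demons-style intensity-matching scheme: the data term is the squared
# intensity difference between the (lightly smoothed) fixed image and the
# warped moving image, minimised coarse-to-fine by normalised
# gradient-descent forces with diffusion-type regularization (Gaussian
# smoothing of the displacement field after every update). The
# contour-guided variant adds, inside a ring around the PTV, a force that
# aligns signed distance maps of the daily bladder/prostate/rectum
# contours. A median-of-repeats wrapper re-runs the registration with
# jittered initialisations and takes the component-wise per-voxel median
# field, damping run-to-run variation from distinct local optima.

#' Registration settings
#'
#' @param levels number of pyramid levels (coarsest downsampled by
#'   `2^(levels-1)`)
#' @param iterations iterations per level, coarse to fine (recycled)
#' @param dataSmoothMm Gaussian smoothing (mm) applied to both images
#'   before matching (suppresses noise; a crude band-pass)
#' @param regWeight diffusion regularization weight; the field is
#'   smoothed after each update with sigma = `1.5 mm * regWeight`
#' @param updateSigmaMm fluid-like smoothing (mm) of each force update
#' @param maxStepMm cap on the per-iteration displacement update (mm)
#' @param tolMm convergence: stop a level when the mean update falls
#'   below this (mm)
#' @param edgePreserve strength (0-1) of edge-preserving regularization:
#'   at strong fixed-image gradients the field keeps up to this fraction
#'   of its unsmoothed value (default 0: homogeneous diffusion)
#' @param refineIterations full-resolution refinement iterations run
#'   after the pyramid with annealed regularization
#'   (`refineRegWeight`, `refineDataSmoothMm`); reduces the shrinkage
#'   that diffusion regularization induces at moving/static organ
#'   interfaces. 0 disables.
#' @param refineRegWeight,refineDataSmoothMm refinement-stage values
#' @param nRepeats repeats for [medianOfRepeats()] (default 30)
#' @param jitterSdMm SD (mm) of the zero-mean initialisation jitter used
#'   across repeats
#' @param guidanceWeight relative weight of the contour-guidance force
#' @return list of class `RegistrationSettings`
#' @export
registrationSettings <- function(levels = 2L, iterations = c(60L, 30L),
                                 dataSmoothMm = 1.5, regWeight = 1.25,
                                 updateSigmaMm = 1.5, maxStepMm = 2,
                                 edgePreserve = 0,
                                 refineIterations = 40L,
                                 refineRegWeight = 0.75,
                                 refineDataSmoothMm = 1.0,
                                 tolMm = 0.01, nRepeats = 30L,
                                 jitterSdMm = 0.2, guidanceWeight = 1) {
  stopifnot(levels >= 1, all(iterations >= 1), regWeight >= 0,
            updateSigmaMm >= 0, tolMm > 0, nRepeats >= 1, jitterSdMm >= 0,
            guidanceWeight >= 0, edgePreserve >= 0, edgePreserve <= 1,
            refineIterations >= 0, refineRegWeight >= 0,
            refineDataSmoothMm >= 0)
  structure(list(levels = as.integer(levels),
                 iterations = as.integer(rep_len(iterations, levels)),
                 dataSmoothMm = dataSmoothMm, regWeight = regWeight,
                 updateSigmaMm = updateSigmaMm, maxStepMm = maxStepMm,
                 edgePreserve = edgePreserve,
                 refineIterations = as.integer(refineIterations),
                 refineRegWeight = refineRegWeight,
                 refineDataSmoothMm = refineDataSmoothMm,
                 tolMm = tolMm, nRepeats = as.integer(nRepeats),
                 jitterSdMm = jitterSdMm, guidanceWeight = guidanceWeight),
            class = "RegistrationSettings")
}

# core demons loop at one resolution level.
# f, m: arrays; sp: spacing (mm); u: list of 3 arrays (mm); guid: NULL or
# list(ring=array01, fixedSd=list of arrays, movSd=list, movSdGrad=list of
# list-of-3); returns list(u, residuals, converged)
.demonsLevel <- function(f, m, sp, u, iters, settings, guid = NULL) {
  sh <- dim(f)
  idx <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]), z = seq_len(sh[3]))
  gf <- .gradient3(f, sp)
  K2 <- mean(sp)^2
  gw <- settings$guidanceWeight
  # edge-preserving regularization: where the fixed image has strong
  # gradients the data term is reliable, so the field keeps its
  # data-driven value there instead of being fully smoothed (reduces
  # bleeding across moving/static organ interfaces)
  beta <- 0
  if (settings$edgePreserve > 0) {
    gmag2 <- gf[[1]]^2 + gf[[2]]^2 + gf[[3]]^2
    q <- quantile(gmag2[gmag2 > 0], 0.8, names = FALSE)
    if (is.finite(q) && q > 0)
      beta <- settings$edgePreserve * gmag2 / (gmag2 + q)
  }
  residuals <- numeric(0)
  converged <- FALSE
  for (it in seq_len(iters)) {
    xi <- idx$x + as.vector(u[[1]]) / sp[1]
    yi <- idx$y + as.vector(u[[2]]) / sp[2]
    zi <- idx$z + as.vector(u[[3]]) / sp[3]
    w <- array(.interpTrilinear(m, xi, yi, zi), dim = sh)
    diffI <- w - f
    # symmetric forces: average fixed and warped-moving gradients
    gm <- .gradient3(w, sp)
    ge <- lapply(1:3, function(a) (gf[[a]] + gm[[a]]) / 2)
    g2 <- ge[[1]]^2 + ge[[2]]^2 + ge[[3]]^2
    den <- g2 + diffI^2 / K2
    scl <- ifelse(den > 1e-12, -diffI / den, 0)
    du <- lapply(1:3, function(a) scl * ge[[a]])
    if (!is.null(guid) && gw > 0) {
      for (org in seq_along(guid$fixedSd)) {
        dmWarp <- array(.interpTrilinear(guid$movSd[[org]], xi, yi, zi),
                        dim = sh)
        diffD <- dmWarp - guid$fixedSd[[org]]
        gd <- guid$movSdGrad[[org]]
        gdw <- lapply(1:3, function(a)
          array(.interpTrilinear(gd[[a]], xi, yi, zi), dim = sh))
        gd2 <- gdw[[1]]^2 + gdw[[2]]^2 + gdw[[3]]^2
        dend <- gd2 + diffD^2 / K2
        scld <- ifelse(dend > 1e-12, -gw * guid$ring * diffD / dend, 0)
        for (a in 1:3) du[[a]] <- du[[a]] + scld * gdw[[a]]
      }
    }
    if (settings$updateSigmaMm > 0)
      du <- lapply(du, .smoothGaussian, sigmaVox = settings$updateSigmaMm / sp)
    mag <- sqrt(du[[1]]^2 + du[[2]]^2 + du[[3]]^2)
    cap <- settings$maxStepMm
    over <- mag > cap
    if (any(over)) {
      f_sc <- ifelse(over, cap / pmax(mag, 1e-12), 1)
      du <- lapply(du, function(a) a * f_sc)
      mag <- pmin(mag, cap)
    }
    for (a in 1:3) u[[a]] <- u[[a]] + du[[a]]
    if (settings$regWeight > 0)
      u <- lapply(u, function(a) {
        s <- .smoothGaussian(a, sigmaVox = 1.5 * settings$regWeight / sp)
        s + beta * (a - s)
      })
    residuals <- c(residuals, mean(mag))
    if (mean(mag) < settings$tolMm) { converged <- TRUE; break }
  }
  list(u = u, residuals = residuals, converged = converged)
}

# build pyramid guidance structures at a level
.guidanceAtLevel <- function(guidance, factor, spLevel) {
  down <- function(m) {
    if (factor == 1L) return(m)
    .downsample(m * 1, factor) > 0.5
  }
  ring <- down(guidance$ring) * 1
  organs <- names(guidance$fixed)
  fixedSd <- lapply(organs, function(o)
    .signedDistance(down(guidance$fixed[[o]]), spLevel))
  movSd <- lapply(organs, function(o)
    .signedDistance(down(guidance$moving[[o]]), spLevel))
  movSdGrad <- lapply(movSd, .gradient3, spacing = spLevel)
  list(ring = ring, fixedSd = fixedSd, movSd = movSd, movSdGrad = movSdGrad)
}

.registerCore <- function(fixed, moving, settings, init = NULL,
                          guidance = NULL) {
  g <- fixed@grid
  stopifnot(identical(dim(fixed@data), dim(moving@data)))
  L <- settings$levels
  factors <- 2L^((L - 1L):0L)
  f0 <- fixed@data; m0 <- moving@data
  # intensity normalisation keeps force scaling comparable across inputs
  rng <- diff(range(f0))
  if (rng > 0) { f0 <- f0 / rng; m0 <- m0 / rng }
  u <- NULL
  levelLog <- list()
  for (li in seq_len(L)) {
    fac <- factors[li]
    spL <- g@spacing * fac
    fL <- .downsample(f0, fac)
    mL <- .downsample(m0, fac)
    if (settings$dataSmoothMm > 0) {
      fL <- .smoothGaussian(fL, settings$dataSmoothMm / spL)
      mL <- .smoothGaussian(mL, settings$dataSmoothMm / spL)
    }
    shL <- dim(fL)
    if (is.null(u)) {
      if (is.null(init)) {
        u <- lapply(1:3, function(a) array(0, dim = shL))
      } else {
        u <- lapply(1:3, function(a) .upsampleTo(init@data[, , , a], shL))
      }
    } else {
      u <- lapply(u, .upsampleTo, targetDim = shL)
    }
    guidL <- if (!is.null(guidance)) .guidanceAtLevel(guidance, fac, spL)
    res <- .demonsLevel(fL, mL, spL, u, settings$iterations[li], settings,
                        guid = guidL)
    u <- res$u
    levelLog[[li]] <- list(factor = fac, residuals = res$residuals,
                           converged = res$converged)
  }
  if (settings$refineIterations > 0) {
    rset <- settings
    rset$regWeight <- settings$refineRegWeight
    fR <- f0; mR <- m0
    if (settings$refineDataSmoothMm > 0) {
      fR <- .smoothGaussian(fR, settings$refineDataSmoothMm / g@spacing)
      mR <- .smoothGaussian(mR, settings$refineDataSmoothMm / g@spacing)
    }
    guidR <- if (!is.null(guidance)) .guidanceAtLevel(guidance, 1L, g@spacing)
    res <- .demonsLevel(fR, mR, g@spacing, u, settings$refineIterations,
                        rset, guid = guidR)
    u <- res$u
    levelLog[[L + 1L]] <- list(factor = 1L, refine = TRUE,
                               residuals = res$residuals,
                               converged = res$converged)
    L <- L + 1L
  }
  warned <- !levelLog[[L]]$converged &&
    utils::tail(levelLog[[L]]$residuals, 1) > 5 * settings$tolMm
  data <- array(0, dim = c(g@shape, 3L))
  for (a in 1:3) data[, , , a] <- u[[a]]
  displacementField(g, data,
                    log = list(levels = levelLog, warning = warned,
                               converged = levelLog[[L]]$converged))
}

#' Deformable registration of two images
#'
#' Estimates the displacement field (pull-back convention: fixed
#' coordinates to moving coordinates) that matches the moving image's
#' contrast patterns onto the fixed image. Non-convergence within the
#' iteration budget sets a warning flag in the result log rather than
#' raising an error.
#'
#' @param fixed,moving [ScalarImage-class] objects on one grid
#' @param settings a [registrationSettings()]
#' @param init optional initial [DisplacementField-class]
#' @return a [DisplacementField-class]
#' @export
registerDeformable <- function(fixed, moving,
                               settings = registrationSettings(),
                               init = NULL) {
  .registerCore(fixed, moving, settings, init = init)
}

#' Contour-guided deformable registration
#'
#' As [registerDeformable()], with an additional force that penalises
#' misalignment of signed distance maps of the supplied organ contours,
#' applied only inside the ring mask around the PTV. Used for
#' interfraction registration, where day-to-day bladder and rectum volume
#' changes defeat pure intensity matching.
#'
#' @param fixed,moving [ScalarImage-class] objects on one grid
#' @param guidance list with `fixed` and `moving` (each a named list of
#'   logical organ masks, e.g. bladder/prostate/rectum) and `ring` (the
#'   [makeRing()] mask on the fixed grid)
#' @param settings a [registrationSettings()]
#' @param init optional initial field
#' @return a [DisplacementField-class]
#' @export
registerContourGuided <- function(fixed, moving, guidance,
                                  settings = registrationSettings(),
                                  init = NULL) {
  if (is.null(guidance$ring) || !any(guidance$ring)) {
    warning("empty ring mask; falling back to unguided registration")
    return(.registerCore(fixed, moving, settings, init = init))
  }
  stopifnot(length(guidance$fixed) >= 1,
            identical(names(guidance$fixed), names(guidance$moving)))
  .registerCore(fixed, moving, settings, init = init, guidance = guidance)
}

# row-wise median of a matrix (vectorised via within-row sort)
.rowMedians <- function(M) {
  n <- ncol(M)
  if (n == 1L) return(M[, 1])
  S <- matrix(M[order(row(M), M)], ncol = n, byrow = TRUE)
  if (n %% 2L == 1L) S[, (n + 1L) %/% 2L]
  else (S[, n %/% 2L] + S[, n %/% 2L + 1L]) / 2
}

#' Median-of-repeats registration wrapper
#'
#' Runs a registration `nRepeats` times from seeded, jittered
#' initialisations (zero-mean constant offsets, SD `jitterSdMm` per
#' component) and returns the component-wise per-voxel median field,
#' damping variation from convergence to slightly different local
#' optima.
#'
#' @param registrationCall function taking an initial
#'   [DisplacementField-class] (or NULL) and returning a field
#' @param grid the [VoxelGrid-class] of the registration
#' @param nRepeats number of repeats (clinical default 30)
#' @param seed integer seed for the jitter
#' @param jitterSdMm jitter SD in mm
#' @return a [DisplacementField-class]; its log records the repeat count
#' @export
medianOfRepeats <- function(registrationCall, grid, nRepeats = 30L,
                            seed = 1L, jitterSdMm = 0.2) {
  stopifnot(nRepeats >= 1)
  fields <- lapply(seq_len(nRepeats), function(i) {
    init <- if (jitterSdMm > 0) {
      off <- .withSeed(.substreamSeed(seed, 811, i), rnorm(3, 0, jitterSdMm))
      data <- array(0, dim = c(grid@shape, 3L))
      for (a in 1:3) data[, , , a] <- off[a]
      displacementField(grid, data)
    } else NULL
    registrationCall(init)
  })
  if (nRepeats == 1L) return(fields[[1]])
  nv <- prod(grid@shape)
  data <- array(0, dim = c(grid@shape, 3L))
  for (a in 1:3) {
    M <- vapply(fields, function(f) as.vector(f@data[, , , a]), numeric(nv))
    data[, , , a] <- .rowMedians(M)
  }
  anyWarn <- any(vapply(fields, function(f) isTRUE(f@log$warning), logical(1)))
  displacementField(grid, data,
                    log = list(nRepeats = nRepeats, warning = anyWarn))
}

#' Mean CTV displacement of a field
#'
#' The estimated rigid target shift: the mean displacement vector over
#' the CTV voxels, with its 3D magnitude as an attribute.
#'
#' @param field a [DisplacementField-class]
#' @param ctvMask logical mask on the same grid
#' @return named numeric(3) (mm, LR/AP/SI) with attribute `magnitude`
#' @export
estimateCtvShift <- function(field, ctvMask) {
  if (!any(ctvMask)) stop("CTV mask is empty")
  v <- vapply(1:3, function(a) mean(field@data[, , , a][ctvMask]), numeric(1))
  structure(setNames(v, .AXES), magnitude = sqrt(sum(v^2)))
}

#' Warp an image through a displacement field
#'
#' Pull-back resampling: the output at fixed coordinate x samples the
#' moving image at x + u(x), trilinearly; samples outside the grid take
#' nearest-edge values.
#'
#' @param moving a [ScalarImage-class]
#' @param field a [DisplacementField-class] on the same grid
#' @return warped [ScalarImage-class]
#' @export
warpImage <- function(moving, field) {
  g <- moving@grid
  stopifnot(identical(g@shape, field@grid@shape))
  sh <- g@shape
  idx <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]), z = seq_len(sh[3]))
  vals <- .interpTrilinear(moving@data,
                           idx$x + as.vector(field@data[, , , 1]) / g@spacing[1],
                           idx$y + as.vector(field@data[, , , 2]) / g@spacing[2],
                           idx$z + as.vector(field@data[, , , 3]) / g@spacing[3])
  scalarImage(g, array(vals, dim = sh))
}
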