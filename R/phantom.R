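# Synthetic pelvic phantom and motion generator.
#
# Anatomy is ellipsoid-based with smoothed boundaries and Gaussian noise:
# realism is bounded by what the registration engine needs (distinct,
# smooth contrast patterns between prostate, bladder, rectum and
# background), not by MR physics. Prostate motion is rigid within a
# smooth spatial window; interfraction change adds a bladder-filling
# deformation modeled as a radial Gaussian bump centred in the bladder.

# --- deterministic substream seeding -----------------------------------
# One master seed; per-(patient, fraction, interval) streams are derived
# by mixing the identifiers into a 31-bit seed so that adding patients or
# fractions never perturbs existing streams.
.substreamSeed <- function(master, ...) {
  ids <- c(master, ...)
  M <- 2147483629
  h <- 17
  for (v in ids) h <- (h * 31 + (as.numeric(v) %% M)) %% M
  as.integer(h)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.INTERVALS <- c(MR1_MR2 = 1L, MR2_MR3 = 2L, MR3_MR4 = 3L, interfraction = 4L)

# --- anatomy ------------------------------------------------------------

#' Parameters of the synthetic pelvic anatomy
#'
#' Ellipsoid centres and semi-axes in mm (world coordinates, LR/AP/SI;
#' positive = left/posterior/superior). Defaults place a prostate with a
#' focal GTV between an anterior-superior bladder and a posterior rectum
#' on a 120 mm cube.
#'
#' @param prostateCentre,prostateSemi numeric(3), mm
#' @param gtvCentre,gtvSemi numeric(3), mm
#' @param bladderCentre,bladderSemi numeric(3), mm
#' @param rectumCentre,rectumSemi numeric(3), mm
#' @param intensities named list of mean intensities (a.u.)
#' @param noiseSd additive Gaussian noise SD (a.u.)
#' @param boundarySmoothMm boundary smoothing scale in mm
#' @param overlapTol maximum tolerated fraction of prostate voxels
#'   overlapping bladder or rectum before anatomy is declared invalid
#' @return list of class `AnatomyParams`
#' @export
anatomyParams <- function(prostateCentre = c(60, 62, 50),
                          prostateSemi = c(18, 16, 18),
                          gtvCentre = c(66, 56, 54),
                          gtvSemi = c(6, 6, 6),
                          bladderCentre = c(60, 38, 78),
                          bladderSemi = c(20, 18, 18),
                          rectumCentre = c(60, 88, 50),
                          rectumSemi = c(9, 8, 35),
                          intensities = list(background = 100, prostate = 180,
                                             gtv = 210, bladder = 240,
                                             rectum = 140),
                          noiseSd = 2,
                          boundarySmoothMm = 2,
                          overlapTol = 0.02) {
  structure(as.list(environment()), class = "AnatomyParams")
}

# ellipsoid indicator sampled at voxel centres
.ellipsoidMask <- function(grid, centre, semi) {
  if (any(semi <= 0)) return(array(FALSE, dim = grid@shape))
  sh <- grid@shape
  ax <- lapply(1:3, function(a)
    (grid@origin[a] + (seq_len(sh[a]) - 1) * grid@spacing[a] - centre[a]) / semi[a])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  q <= 1
}

#' Build the synthetic pelvic phantom
#'
#' Generates a [ScalarImage-class] with distinct mean intensities per
#' organ, smooth boundaries, and additive Gaussian noise, plus the
#' corresponding [LabelMap-class] with GTV, prostate, CTV (built as
#' prostate plus 4 mm GTV expansion excluding bladder/rectum), bladder
#' and rectum masks.
#'
#' @param params an [anatomyParams()] list
#' @param grid a [VoxelGrid-class]; organs must fit with a 5 mm border
#' @param seed integer seed for the noise
#' @return list with elements `image` ([ScalarImage-class]) and
#'   `labels` ([LabelMap-class])
#' @export
buildPhantom <- function(params = anatomyParams(),
                         grid = voxelGrid(c(48, 48, 48), spacing = 2.5),
                         seed = 1L) {
  p <- params
  lo <- grid@origin
  hi <- grid@origin + (grid@shape - 1) * grid@spacing
  organs <- list(
    prostate = list(p$prostateCentre, p$prostateSemi),
    gtv = list(p$gtvCentre, p$gtvSemi),
    bladder = list(p$bladderCentre, p$bladderSemi),
    rectum = list(p$rectumCentre, p$rectumSemi)
  )
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (any(o[[2]] > 0) &&
        (any(o[[1]] - o[[2]] < lo + 5) || any(o[[1]] + o[[2]] > hi - 5)))
      stop("organ '", nm, "' does not fit inside the grid with a 5 mm border")
  }
  m <- lapply(organs, function(o) .ellipsoidMask(grid, o[[1]], o[[2]]))
  if (any(m$prostate)) {
    ov <- (sum(m$prostate & m$bladder) + sum(m$prostate & m$rectum)) /
      sum(m$prostate)
    if (ov > p$overlapTol)
      stop(sprintf("invalid anatomy: prostate overlaps OARs (fraction %.3f)", ov))
  }
  img <- array(p$intensities$background, dim = grid@shape)
  img[m$rectum] <- p$intensities$rectum
  img[m$bladder] <- p$intensities$bladder
  img[m$prostate] <- p$intensities$prostate
  img[m$gtv] <- p$intensities$gtv
  img <- .smoothGaussian(img, p$boundarySmoothMm / grid@spacing)
  if (p$noiseSd > 0)
    img <- img + .withSeed(seed, array(rnorm(prod(grid@shape), 0, p$noiseSd),
                                       dim = grid@shape))
  msk <- list(gtv = m$gtv, prostate = m$prostate, bladder = m$bladder,
              rectum = m$rectum)
  if (any(m$prostate))
    msk$ctv <- ctvFromGtv(m$gtv, m$prostate, m$bladder, m$rectum, grid)
  else
    msk$ctv <- array(FALSE, dim = grid@shape)
  list(image = scalarImage(grid, img),
       labels = labelMap(grid, msk[c("gtv", "prostate", "ctv", "bladder",
                                     "rectum")]))
}

# --- motion -------------------------------------------------------------

#' Cohort configuration for the motion and anatomy simulator
#'
#' The per-subfraction prostate shift model: each axis is a zero-mean
#' normal around a per-patient systematic offset, with a small
#' probability (`tailProb`) of a `tailScale`-times wider draw emulating
#' transient bladder-filling/gas events. The `typical` scales are
#' calibrated so the cohort mean 3D shift is about 1.0 mm (SD 0.6 mm);
#' the `large` mover scales give about 1.9 mm (SD 1.5 mm). Motion is
#' anisotropic: AP and SI scales exceed LR.
#'
#' @param nPatients number of patients
#' @param nFractions fractions per patient (default 5)
#' @param nSubfractions deliveries per fraction (default 2)
#' @param largeMoverFraction mixture weight of the large-mover subgroup
#' @param typicalScales,largeScales lists with per-axis `sysSd` and
#'   `baseSd` (mm, LR/AP/SI), `tailProb`, `tailScale`
#' @param interfractionShiftSd per-axis SD (mm) of the rigid
#'   interfraction prostate shift between the daily MR1 scans
#' @param interfractionBladderSd SD (mm) of the bladder-filling
#'   deformation amplitude between fractions
#' @param seed master seed; all downstream randomness derives from it
#' @return list of class `CohortConfig`
#' @export
cohortConfig <- function(nPatients = 10L, nFractions = 5L, nSubfractions = 2L,
                         largeMoverFraction = 0.1,
                         typicalScales = list(sysSd = c(0.3, 0.4, 0.4),
                                              baseSd = c(0.2, 0.5, 0.5),
                                              tailProb = 0.10, tailScale = 3.0),
                         largeScales = list(sysSd = c(0.3, 0.4, 0.4),
                                            baseSd = c(0.4, 1.0, 1.0),
                                            tailProb = 0.15, tailScale = 3.5),
                         interfractionShiftSd = c(0.5, 1.0, 1.0),
                         interfractionBladderSd = 1.5,
                         seed = 1L) {
  stopifnot(nPatients >= 1, nFractions >= 1, nSubfractions >= 1,
            largeMoverFraction >= 0, largeMoverFraction <= 1)
  for (sc in list(typicalScales, largeScales)) {
    stopifnot(all(sc$sysSd >= 0), all(sc$baseSd >= 0),
              sc$tailProb >= 0, sc$tailProb <= 1, sc$tailScale >= 1)
  }
  structure(list(nPatients = as.integer(nPatients),
                 nFractions = as.integer(nFractions),
                 nSubfractions = as.integer(nSubfractions),
                 largeMoverFraction = largeMoverFraction,
                 typicalScales = typicalScales, largeScales = largeScales,
                 interfractionShiftSd = rep_len(interfractionShiftSd, 3),
                 interfractionBladderSd = interfractionBladderSd,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Zero-motion cohort configuration
#'
#' Convenience preset with every motion scale set to zero (used for
#' dose-conservation checks).
#' @param ... overrides passed to [cohortConfig()]
#' @export
zeroMotionConfig <- function(...) {
  z <- list(sysSd = c(0, 0, 0), baseSd = c(0, 0, 0), tailProb = 0,
            tailScale = 1)
  cohortConfig(largeMoverFraction = 0, typicalScales = z, largeScales = z,
               interfractionShiftSd = c(0, 0, 0), interfractionBladderSd = 0,
               ...)
}

# is this patient a large mover? (patient-level stream)
.isLargeMover <- function(config, patientId) {
  if (config$largeMoverFraction <= 0) return(FALSE)
  if (config$largeMoverFraction >= 1) return(TRUE)
  .withSeed(.substreamSeed(config$seed, 901, patientId),
            runif(1) < config$largeMoverFraction)
}

# per-patient systematic offset (mm, LR/AP/SI), constant over treatment
.patientSystematic <- function(config, patientId) {
  sc <- if (.isLargeMover(config, patientId)) config$largeScales
        else config$typicalScales
  .withSeed(.substreamSeed(config$seed, 902, patientId),
            rnorm(3, 0, sc$sysSd))
}

#' Sample one motion interval
#'
#' Draws the rigid prostate translation for one interval of one
#' fraction. Intrafraction intervals (`MR1_MR2`, `MR2_MR3` = shift 1,
#' `MR3_MR4` = shift 2) use the subgroup's per-subfraction distribution;
#' the `interfraction` interval uses the interfraction scales and also
#' carries a bladder-filling deformation amplitude.
#'
#' @param config a [cohortConfig()]
#' @param patientId integer patient id
#' @param fraction fraction index
#' @param interval one of `"MR1_MR2"`, `"MR2_MR3"`, `"MR3_MR4"`,
#'   `"interfraction"`
#' @return list of class `MotionSample` with `translation` (mm),
#'   `magnitude` (mm), `interval`, `deformAmplitudeMm`
#' @export
sampleMotion <- function(config, patientId, fraction, interval) {
  if (!interval %in% names(.INTERVALS))
    stop("unknown interval '", interval, "'")
  seed <- .substreamSeed(config$seed, patientId, fraction,
                         .INTERVALS[[interval]])
  if (interval == "interfraction") {
    draw <- .withSeed(seed, list(t = rnorm(3, 0, config$interfractionShiftSd),
                                 b = rnorm(1, 0, config$interfractionBladderSd)))
    tr <- if (fraction == 1L) c(0, 0, 0) else draw$t
    amp <- if (fraction == 1L) 0 else draw$b
  } else {
    sc <- if (.isLargeMover(config, patientId)) config$largeScales
          else config$typicalScales
    mu <- .patientSystematic(config, patientId)
    draw <- .withSeed(seed, {
      wide <- runif(1) < sc$tailProb
      s <- sc$baseSd * if (wide) sc$tailScale else 1
      rnorm(3, 0, s)
    })
    tr <- mu + draw
    if (all(sc$baseSd == 0) && all(sc$sysSd == 0)) tr <- c(0, 0, 0)
    amp <- 0
  }
  structure(list(translation = setNames(tr, .AXES),
                 magnitude = sqrt(sum(tr^2)),
                 interval = interval,
                 deformAmplitudeMm = amp),
            class = "MotionSample")
}

# --- anatomy deformation -----------------------------------------------

# Smooth window equal to 1 on and around the prostate, decaying to 0
# over ~`taper` mm beyond `inner` mm from the prostate surface.
.prostateWindow <- function(prostate, grid, inner, taper = 5) {
  d <- sqrt(.edtSquared(prostate, grid@spacing, dmax = inner + 4 * taper))
  w <- exp(-pmax(d - inner, 0)^2 / (2 * taper^2))
  w[d >= inner + 3.5 * taper] <- 0
  w
}

# Radial bladder-filling displacement (pull-back): amplitude `amp` mm of
# outward expansion around the bladder centroid.
.bladderBump <- function(bladder, grid, amp) {
  sh <- grid@shape
  if (amp == 0 || !any(bladder))
    return(lapply(1:3, function(a) array(0, dim = sh)))
  cvox <- .maskCentroidVox(bladder)
  cmm <- grid@origin + (cvox - 1) * grid@spacing
  sig <- (sum(bladder) * prod(grid@spacing) * 3 / (4 * pi))^(1 / 3) # eff. radius
  ax <- lapply(1:3, function(a)
    grid@origin[a] + (seq_len(sh[a]) - 1) * grid@spacing[a] - cmm[a])
  X <- array(rep(ax[[1]], times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(ax[[2]], each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(ax[[3]], each = sh[1] * sh[2]), dim = sh)
  r <- sqrt(X^2 + Y^2 + Z^2)
  # expansion: sample from closer to the centre (pull-back is -amp * rhat)
  f <- -amp * exp(-r^2 / (2 * sig^2)) / pmax(r, 1e-6)
  list(X * f, Y * f, Z * f)
}

#' Apply a motion sample to anatomy
#'
#' Moves prostate, GTV and CTV rigidly by the sampled translation (within
#' a smooth spatial window so the image stays continuous) and applies the
#' bladder-filling deformation where present. The image is resampled with
#' trilinear interpolation, labels with nearest-neighbour; prostate-group
#' labels are translated exactly so their centroid displacement equals
#' the generating translation to within half a voxel.
#'
#' @param image a [ScalarImage-class]
#' @param labels a [LabelMap-class] on the same grid
#' @param motion a `MotionSample` from [sampleMotion()]
#' @return list with deformed `image` and `labels`
#' @export
deformAnatomy <- function(image, labels, motion) {
  g <- image@grid
  tr <- as.numeric(motion$translation)
  amp <- motion$deformAmplitudeMm
  sh <- g@shape
  if (all(tr == 0) && amp == 0) return(list(image = image, labels = labels))
  pro <- mask(labels, "prostate")
  ctv <- mask(labels, "ctv")
  # out-of-bounds: the translated CTV must stay on the grid
  if (any(ctv)) {
    bb <- which(ctv, arr.ind = TRUE)
    mn <- apply(bb, 2, min) + tr / g@spacing
    mx <- apply(bb, 2, max) + tr / g@spacing
    if (any(mn < 1) || any(mx > sh))
      stop("translation moves the CTV outside the grid")
  }
  w <- .prostateWindow(pro, g, inner = sqrt(sum(tr^2)) + 4)
  bump <- .bladderBump(mask(labels, "bladder"), g, amp)
  # pull-back field in voxel units per axis
  idx <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]), z = seq_len(sh[3]))
  ux <- (-w * tr[1] + (1 - w) * bump[[1]]) / g@spacing[1]
  uy <- (-w * tr[2] + (1 - w) * bump[[2]]) / g@spacing[2]
  uz <- (-w * tr[3] + (1 - w) * bump[[3]]) / g@spacing[3]
  newImg <- array(.interpTrilinear(image@data, idx$x + as.vector(ux),
                                   idx$y + as.vector(uy),
                                   idx$z + as.vector(uz)), dim = sh)
  tvox <- tr / g@spacing
  newMasks <- list()
  for (nm in names(masks(labels))) {
    m0 <- masks(labels)[[nm]] * 1
    if (nm %in% c("gtv", "prostate", "ctv")) {
      v <- .interpNearest(m0, idx$x - tvox[1], idx$y - tvox[2], idx$z - tvox[3])
    } else {
      v <- .interpNearest(m0, idx$x + as.vector(ux), idx$y + as.vector(uy),
                          idx$z + as.vector(uz))
    }
    newMasks[[nm]] <- array(v > 0.5, dim = sh)
  }
  # physical exclusivity: the moved target displaces OAR volume
  if (!is.null(newMasks$ctv)) {
    newMasks$bladder <- newMasks$bladder & !newMasks$ctv
    newMasks$rectum <- newMasks$rectum & !newMasks$ctv
    newMasks$prostate <- newMasks$prostate | (newMasks$ctv & newMasks$gtv)
  }
  list(image = scalarImage(g, newImg), labels = labelMap(g, newMasks))
}

# --- cohort -------------------------------------------------------------

#' Simulate a treated cohort
#'
#' For each patient, builds a baseline phantom, then for each fraction
#' applies the interfraction anatomy change (relative to the baseline)
#' and generates the four intrafraction images MR1-MR4 by applying the
#' cumulative rigid shifts of the intervals MR1-MR2, MR2-MR3 (shift 1)
#' and MR3-MR4 (shift 2). Full ground truth (motions and propagated
#' labels) is retained.
#'
#' @param config a [cohortConfig()]
#' @param grid a [VoxelGrid-class] for all volumes
#' @param params an [anatomyParams()]
#' @return list of patients; each patient is a list with `patientId`,
#'   `largeMover`, and `sessions` (list of [FractionSession-class])
#' @export
simulateCohort <- function(config,
                           grid = voxelGrid(c(48, 48, 48), spacing = 2.5),
                           params = anatomyParams()) {
  lapply(seq_len(config$nPatients), function(pid) {
    base <- buildPhantom(params, grid,
                         seed = .substreamSeed(config$seed, 903, pid))
    sessions <- lapply(seq_len(config$nFractions), function(fx) {
      inter <- sampleMotion(config, pid, fx, "interfraction")
      day <- deformAnatomy(base$image, base$labels, inter)
      m12 <- sampleMotion(config, pid, fx, "MR1_MR2")
      m23 <- sampleMotion(config, pid, fx, "MR2_MR3")
      m34 <- sampleMotion(config, pid, fx, "MR3_MR4")
      cum <- list(MR2 = m12$translation,
                  MR3 = m12$translation + m23$translation,
                  MR4 = m12$translation + m23$translation + m34$translation)
      imgs <- list(MR1 = day$image)
      labsAt <- list()
      for (nm in names(cum)) {
        mv <- structure(list(translation = cum[[nm]],
                             magnitude = sqrt(sum(cum[[nm]]^2)),
                             interval = nm, deformAmplitudeMm = 0),
                        class = "MotionSample")
        d <- deformAnatomy(day$image, day$labels, mv)
        imgs[[nm]] <- d$image
        labsAt[[nm]] <- d$labels
      }
      new("FractionSession", patient = as.character(pid),
          fraction = as.integer(fx), images = imgs, labels = day$labels,
          labelsAt = labsAt,
          motions = list(interfraction = inter, MR1_MR2 = m12,
                         MR2_MR3 = m23, MR3_MR4 = m34))
    })
    list(patientId = pid, largeMover = .isLargeMover(config, pid),
         sessions = sessions)
  })
}

#' Ground-truth shift records of a cohort
#'
#' Extracts the generating per-subfraction translations (shift 1 =
#' MR2-MR3 interval, shift 2 = MR3-MR4) as a tidy record table.
#'
#' @param cohort output of [simulateCohort()]
#' @return data.frame of class `ShiftRecord` (see [shiftRecords()])
#' @export
groundTruthShiftRecords <- function(cohort) {
  rows <- list()
  for (p in cohort) for (s in p$sessions) {
    for (iv in c("MR2_MR3", "MR3_MR4")) {
      tr <- s@motions[[iv]]$translation
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p$patientId, fraction = s@fraction,
        interval = if (iv == "MR2_MR3") "shift1" else "shift2",
        dx_lr = tr[1], dy_ap = tr[2], dz_si = tr[3],
        source = "ground_truth")
    }
  }
  shiftRecords(do.call(rbind, rows))
}

#' Simulate shift records directly (no imaging)
#'
#' Draws per-subfraction translations from the two-level normal model
#' (per-patient systematic offset with SD `sysSd` per axis; within-patient
#' random component with SD `randSd`) without generating any images. Used
#' for calibration studies of the systematic/random error estimators.
#'
#' @param nPatients number of patients
#' @param nRecords subfraction records per patient
#' @param sysSd,randSd per-axis SDs in mm (scalar or length 3)
#' @param seed integer seed
#' @return `ShiftRecord` data.frame
#' @export
simulateShiftRecords <- function(nPatients, nRecords, sysSd, randSd,
                                 seed = 1L) {
  sysSd <- rep_len(sysSd, 3); randSd <- rep_len(randSd, 3)
  .withSeed(seed, {
    rows <- lapply(seq_len(nPatients), function(pid) {
      mu <- rnorm(3, 0, sysSd)
      d <- matrix(rnorm(3 * nRecords, mean = rep(mu, each = nRecords),
                        sd = rep(randSd, each = nRecords)), ncol = 3)
      data.frame(patient = pid,
                 fraction = rep(seq_len(ceiling(nRecords / 2)),
                                each = 2)[seq_len(nRecords)],
                 interval = rep(c("shift1", "shift2"),
                                length.out = nRecords),
                 dx_lr = d[, 1], dy_ap = d[, 2], dz_si = d[, 3],
                 source = "ground_truth")
    })
    shiftRecords(do.call(rbind, rows))
  })
}
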