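# Shared fixtures, built once per test run. Grids are kept small; the
# noise-free phantom is used wherever registration accuracy is probed.

.fixtureEnv <- new.env()

# default-geometry phantom on a given grid, cached
fixturePhantom <- function(shape = c(48, 48, 48), spacingMm = 2.5,
                           noiseSd = 2, seed = 1) {
  key <- paste(c(shape, spacingMm, noiseSd, seed), collapse = "_")
  if (is.null(.fixtureEnv[[key]])) {
    g <- voxelGrid(shape, spacing = spacingMm)
    p <- anatomyParams(noiseSd = noiseSd)
    .fixtureEnv[[key]] <- buildPhantom(p, g, seed = seed)
  }
  .fixtureEnv[[key]]
}

# a MotionSample without going through the cohort sampler
rigidMotion <- function(translation, amp = 0,
                        interval = "MR2_MR3") {
  structure(list(translation = as.numeric(translation),
                 magnitude = sqrt(sum(translation^2)),
                 interval = interval, deformAmplitudeMm = amp),
            class = "MotionSample")
}

# a single zero-or-known-motion FractionSession built from a phantom
makeSession <- function(ph, t12 = c(0, 0, 0), t23 = c(0, 0, 0),
                        t34 = c(0, 0, 0), fraction = 1L,
                        patient = "1") {
  cum <- list(MR2 = t12, MR3 = t12 + t23, MR4 = t12 + t23 + t34)
  imgs <- list(MR1 = ph$image)
  labsAt <- list()
  for (nm in names(cum)) {
    d <- deformAnatomy(ph$image, ph$labels, rigidMotion(cum[[nm]]))
    imgs[[nm]] <- d$image
    labsAt[[nm]] <- d$labels
  }
  new("FractionSession", patient = patient, fraction = as.integer(fraction),
      images = imgs, labels = ph$labels, labelsAt = labsAt,
      motions = list(
        interfraction = rigidMotion(c(0, 0, 0), interval = "interfraction"),
        MR1_MR2 = rigidMotion(t12, interval = "MR1_MR2"),
        MR2_MR3 = rigidMotion(t23, interval = "MR2_MR3"),
        MR3_MR4 = rigidMotion(t34, interval = "MR3_MR4")))
}

# shift record rows with given per-fraction magnitudes along AP
recordsFromMagnitudes <- function(mags1, mags2, patient = 1) {
  n <- length(mags1)
  shiftRecords(data.frame(
    patient = patient, fraction = rep(seq_len(n), each = 2),
    interval = rep(c("shift1", "shift2"), n),
    dx_lr = 0,
    dy_ap = as.vector(rbind(mags1, mags2)),
    dz_si = 0, source = "ground_truth"))
}

# light registration settings for coarse-grid liveness tests
smokeRegSettings <- function(nRepeats = 1L)
  registrationSettings(levels = 2L, iterations = c(20L, 8L),
                       refineIterations = 6L, nRepeats = nRepeats)
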