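# Deformable registration engine: identity, shift recovery, warping,
# the contour-guided variant and the median-of-repeats wrapper.

test_that("registering an image to itself yields a near-zero field", {
  ph <- fixturePhantom(noiseSd = 0)
  fld <- registerDeformable(ph$image, ph$image)
  mag <- sqrt(fld@data[, , , 1]^2 + fld@data[, , , 2]^2 + fld@data[, , , 3]^2)
  expect_lt(max(mag), 0.1)
})

test_that("a known 3 mm AP prostate shift is recovered over the CTV", {
  ph <- fixturePhantom()
  def <- deformAnatomy(ph$image, ph$labels, rigidMotion(c(0, 3, 0)))
  fld <- registerDeformable(ph$image, def$image)
  est <- estimateCtvShift(fld, mask(ph$labels, "ctv"))
  expect_lt(sqrt(sum((est - c(0, 3, 0))^2)), 0.3)
})

test_that("two successive small shifts compose to the recovered total", {
  ph <- fixturePhantom()
  a <- c(0, 1.5, -1); b <- c(1, -0.5, 1.5)
  def <- deformAnatomy(ph$image, ph$labels, rigidMotion(a + b))
  fld <- registerDeformable(ph$image, def$image)
  est <- estimateCtvShift(fld, mask(ph$labels, "ctv"))
  expect_lt(sqrt(sum((est - (a + b))^2)), 0.5)
})

test_that("field roughness does not increase with regularization weight", {
  ph <- fixturePhantom(c(32, 32, 32), 3.75)
  def <- deformAnatomy(ph$image, ph$labels, rigidMotion(c(0, 2.5, 1)))
  roughness <- vapply(c(0.75, 1.25, 2.5), function(w) {
    s <- registrationSettings(regWeight = w, iterations = c(30L, 15L),
                              refineIterations = 0L)
    fld <- registerDeformable(ph$image, def$image, s)
    g <- lapply(1:3, function(a)
      subfracdose:::.gradient3(fld@data[, , , a], spacing(ph$image)))
    mean(sqrt(Reduce(`+`, lapply(g, function(gg)
      gg[[1]]^2 + gg[[2]]^2 + gg[[3]]^2))))
  }, numeric(1))
  expect_true(all(diff(roughness) <= 1e-9))
})

test_that("warping through a zero field is the identity", {
  ph <- fixturePhantom(c(24, 24, 24), 5)
  z <- subfracdose:::.zeroField(grid(ph$image))
  expect_equal(voxels(warpImage(ph$image, z)), voxels(ph$image))
})

test_that("a uniform field shifts a ramp image by the encoded offset", {
  g <- voxelGrid(c(16, 16, 16), 2)
  ramp <- scalarImage(g, array(rep(seq_len(16), each = 16 * 16),
                               dim = c(16, 16, 16)))  # ramp along SI
  u <- array(0, dim = c(16, 16, 16, 3))
  u[, , , 3] <- 4  # +2 voxels SI in mm
  w <- warpImage(ramp, displacementField(g, u))
  inner <- voxels(w)[, , 3:12]
  expected <- array(rep(seq_len(16) + 2, each = 16 * 16),
                    dim = c(16, 16, 16))[, , 3:12]
  expect_equal(inner, expected, tolerance = 1e-12)
})

test_that("warped intensities stay within the input range", {
  ph <- fixturePhantom(c(24, 24, 24), 5)
  set.seed(5)
  u <- array(rnorm(prod(c(24, 24, 24, 3)), 0, 3), dim = c(24, 24, 24, 3))
  w <- warpImage(ph$image, displacementField(grid(ph$image), u))
  expect_gte(min(voxels(w)), min(voxels(ph$image)) - 1e-9)
  expect_lte(max(voxels(w)), max(voxels(ph$image)) + 1e-9)
})

test_that("CTV shift estimation equals the brute-force average", {
  g <- voxelGrid(c(12, 12, 12), 2)
  z <- subfracdose:::.zeroField(g)
  m <- array(FALSE, dim = c(12, 12, 12)); m[4:9, 4:9, 4:9] <- TRUE
  expect_equal(as.numeric(estimateCtvShift(z, m)), c(0, 0, 0))
  u <- array(0, dim = c(12, 12, 12, 3))
  u[, , , 1] <- 1; u[, , , 2] <- 2; u[, , , 3] <- 2
  est <- estimateCtvShift(displacementField(g, u), m)
  expect_equal(as.numeric(est), c(1, 2, 2))
  expect_equal(attr(est, "magnitude"), 3)
  set.seed(2)
  u <- array(rnorm(12^3 * 3), dim = c(12, 12, 12, 3))
  mask500 <- array(FALSE, dim = c(12, 12, 12))
  mask500[sample(12^3, 500)] <- TRUE
  est <- as.numeric(estimateCtvShift(displacementField(g, u), mask500))
  brute <- vapply(1:3, function(a) {
    acc <- 0; n <- 0
    for (i in which(mask500)) { acc <- acc + u[i + (a - 1) * 12^3]; n <- n + 1 }
    acc / n
  }, numeric(1))
  expect_equal(unname(est), brute, tolerance = 1e-9)
  expect_error(estimateCtvShift(z, array(FALSE, dim = c(12, 12, 12))),
               "empty")
})

test_that("median of identical repeats returns the field exactly", {
  g <- voxelGrid(c(10, 10, 10), 2)
  set.seed(4)
  u <- array(rnorm(10^3 * 3), dim = c(10, 10, 10, 3))
  f <- displacementField(g, u)
  out <- medianOfRepeats(function(init) f, g, nRepeats = 7, seed = 1)
  expect_equal(out@data, u, tolerance = 1e-12)
})

test_that("median of synthetic fields equals the sort-based oracle", {
  g <- voxelGrid(c(8, 8, 8), 2)
  set.seed(6)
  fields <- lapply(1:5, function(i)
    displacementField(g, array(rnorm(8^3 * 3), dim = c(8, 8, 8, 3))))
  i <- 0
  out <- medianOfRepeats(function(init) { i <<- i + 1; fields[[i]] }, g,
                         nRepeats = 5, seed = 1)
  stack <- vapply(fields, function(f) f@data, fields[[1]]@data)
  oracle <- apply(stack, 1:4, median)
  expect_equal(out@data, oracle, tolerance = 1e-12)
})

test_that("repeat count defaults to the clinical 30 and jitter is seeded", {
  expect_equal(registrationSettings()$nRepeats, 30L)
  g <- voxelGrid(c(8, 8, 8), 2)
  seen <- list()
  out1 <- medianOfRepeats(function(init) { seen[[length(seen) + 1L]] <<- init
    init }, g, nRepeats = 3, seed = 9)
  out2 <- medianOfRepeats(function(init) init, g, nRepeats = 3, seed = 9)
  expect_equal(out1@data, out2@data)
  offs <- vapply(seen, function(f) f@data[1, 1, 1, ], numeric(3))
  expect_true(all(abs(offs) < 1.5))   # zero-mean mm-scale jitter
  expect_gt(max(abs(offs)), 0)
})

test_that("contour guidance improves ring alignment under bladder change", {
  ph <- fixturePhantom()
  g <- grid(ph$image)
  day2 <- deformAnatomy(ph$image, ph$labels,
                        rigidMotion(c(0.5, -1.5, 1), amp = 4,
                                    interval = "interfraction"))
  ptv <- expandMargin(mask(ph$labels, "ctv"), marginSpec("tight"), g)
  ring <- makeRing(ptv, g)
  organs <- c("bladder", "prostate", "rectum")
  guid <- list(
    fixed = setNames(lapply(organs, function(o) mask(ph$labels, o)), organs),
    moving = setNames(lapply(organs, function(o) mask(day2$labels, o)),
                      organs),
    ring = ring)
  diceRing <- function(fld) {
    sh <- dim(voxels(ph$image))
    idx <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]),
                       z = seq_len(sh[3]))
    sp <- spacing(ph$image)
    v <- subfracdose:::.interpNearest(mask(day2$labels, "bladder") * 1,
      idx$x + as.vector(fld@data[, , , 1]) / sp[1],
      idx$y + as.vector(fld@data[, , , 2]) / sp[2],
      idx$z + as.vector(fld@data[, , , 3]) / sp[3])
    wb <- array(v > 0.5, dim = sh) & ring
    fb <- mask(ph$labels, "bladder") & ring
    2 * sum(wb & fb) / (sum(wb) + sum(fb))
  }
  s <- registrationSettings()
  unguided <- registerDeformable(ph$image, day2$image, s)
  guided <- registerContourGuided(ph$image, day2$image, guid, s)
  expect_gt(diceRing(guided), diceRing(unguided))
  # identical images and contours: near-zero field
  guidId <- list(fixed = guid$fixed, moving = guid$fixed, ring = ring)
  fid <- registerContourGuided(ph$image, ph$image, guidId, s)
  expect_lt(max(abs(fid@data)), 0.1)
  # zero guidance weight reduces to the unguided engine
  s0 <- s; s0$guidanceWeight <- 0
  f0 <- registerContourGuided(ph$image, day2$image, guid, s0)
  expect_equal(f0@data, unguided@data, tolerance = 1e-12)
  # empty ring falls back with a warning
  guidE <- guid; guidE$ring <- array(FALSE, dim = dim(voxels(ph$image)))
  expect_warning(registerContourGuided(ph$image, day2$image, guidE, s),
                 "empty ring")
})
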