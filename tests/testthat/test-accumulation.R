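# Dose warping, accumulation, and the DVH engine.

test_that("dose warping through a zero field is exact and preserves constants", {
  ph <- fixturePhantom(c(24, 24, 24), 5)
  g <- grid(ph$image)
  ptv <- expandMargin(mask(ph$labels, "ctv"), marginSpec("large"), g)
  plan <- makePlan(ptv, g)
  expect_equal(voxels(warpDose(plan, subfracdose:::.zeroField(g))),
               voxels(plan))
  uniform <- doseGrid(g, array(2.5, dim = c(24, 24, 24)))
  set.seed(3)
  u <- array(rnorm(24^3 * 3, 0, 4), dim = c(24, 24, 24, 3))
  expect_equal(voxels(warpDose(uniform, displacementField(g, u))),
               voxels(uniform), tolerance = 1e-12)
})

test_that("warping a Gaussian dose by a uniform shift matches closed form", {
  g <- voxelGrid(c(32, 32, 32), 2)
  ax <- (seq_len(32) - 1) * 2
  c0 <- c(31, 31, 31); s <- 8
  gauss <- function(centre) {
    X <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, "+"),
               (ax - centre[3])^2, "+")
    10 * exp(-X / (2 * s^2))
  }
  dose <- doseGrid(g, gauss(c0))
  u <- array(0, dim = c(32, 32, 32, 3)); u[, , , 2] <- 2
  w <- warpDose(dose, displacementField(g, u))
  # pull-back by +2 mm AP shows the dose as if centred 2 mm anterior
  expected <- gauss(c0 - c(0, 2, 0))
  inner <- 4:29
  relErr <- abs(voxels(w)[inner, inner, inner] -
                  expected[inner, inner, inner]) / 10
  expect_lt(max(relErr), 0.01)
})

test_that("DVH queries equal sort-based brute force exactly", {
  g <- voxelGrid(c(10, 10, 10), c(2, 2, 2.5))  # voxel 0.01 cm3
  set.seed(12)
  dose <- doseGrid(g, array(runif(1000, 0, 40), dim = c(10, 10, 10)))
  m <- array(FALSE, dim = c(10, 10, 10)); m[sample(1000, 700)] <- TRUE
  vals <- sort(voxels(dose)[m], decreasing = TRUE)
  N <- length(vals)
  brute <- function(r) {
    lo <- floor(r); hi <- ceiling(r)
    if (lo < 1) vals[1] else vals[lo] + (r - lo) * (vals[min(hi, N)] - vals[lo])
  }
  for (p in c(99, 95, 50, 10))
    expect_equal(dvhQuery(dose, m, sprintf("D%d%%", p)),
                 brute(p / 100 * (N - 1) + 1), tolerance = 1e-12)
  voxCc <- prod(c(2, 2, 2.5)) / 1000
  for (v in c(1, 5))
    expect_equal(dvhQuery(dose, m, sprintf("D%dcc", v)),
                 brute(v / (N * voxCc) * (N - 1) + 1), tolerance = 1e-12)
  expect_error(dvhQuery(dose, m, "D99cc"), "smaller than")
  expect_error(dvhQuery(dose, array(FALSE, dim = c(10, 10, 10)), "D99%"),
               "empty")
  expect_error(dvhQuery(dose, m, "Dfoo"), "unrecognised")
})

test_that("a uniform CTV dose gives equal near-minimum metrics and passes", {
  g <- voxelGrid(c(12, 12, 12), 2.5)
  m <- array(FALSE, dim = c(12, 12, 12)); m[4:9, 4:9, 4:9] <- TRUE
  dose <- doseGrid(g, array(36.25, dim = c(12, 12, 12)))
  expect_equal(dvhQuery(dose, m, "D99%"), 36.25)
  expect_equal(dvhQuery(dose, m, "D95%"), 36.25)
  flags <- checkConstraints(list(ctv_d99 = dvhQuery(dose, m, "D99%"),
                                 rectum_d1cc = 10, bladder_d5cc = 10))
  expect_true(flags$ctv_d99)
})

test_that("DVH order statistics are internally consistent", {
  g <- voxelGrid(c(10, 10, 10), 2)
  set.seed(8)
  dose <- doseGrid(g, array(rexp(1000, 1 / 10), dim = c(10, 10, 10)))
  m <- array(TRUE, dim = c(10, 10, 10))
  d99 <- dvhQuery(dose, m, "D99%"); d95 <- dvhQuery(dose, m, "D95%")
  expect_lte(d99, d95)
  expect_lte(d95, max(voxels(dose)))
  vols <- c(0.5, 1, 2, 4)
  dv <- vapply(vols, function(v) dvhQuery(dose, m, sprintf("D%scc", v)),
               numeric(1))
  expect_true(all(diff(dv) <= 1e-12))
})

test_that("intrafraction accumulation conserves dose without motion", {
  ph <- fixturePhantom(c(48, 48, 48), 2.5)
  s <- makeSession(ph)
  pl <- sessionPlans(s, marginSpec("large"))
  fr <- accumulateIntrafraction(s, pl$atp1, pl$atp2,
                                registrationSettings(nRepeats = 3L), seed = 2)
  d99 <- dvhQuery(fr, mask(s@labels, "ctv"), "D99%")
  expect_lt(abs(d99 - 7.25) / 7.25, 0.01)
})

test_that("a large shift during the second delivery causes underdosage", {
  ph <- fixturePhantom(c(48, 48, 48), 2.5)
  sZero <- makeSession(ph)
  # urinary-urgency-like 12 mm inferior drop between MR3 and MR4
  sBig <- makeSession(ph, t34 = c(0, 0, -12))
  set <- registrationSettings(nRepeats = 1L)
  plZ <- sessionPlans(sZero, marginSpec("tight"))
  frZ <- accumulateIntrafraction(sZero, plZ$atp1, plZ$atp2, set, seed = 2)
  plB <- sessionPlans(sBig, marginSpec("tight"))
  frB <- accumulateIntrafraction(sBig, plB$atp1, plB$atp2, set, seed = 2)
  ctv <- mask(ph$labels, "ctv")
  expect_lt(dvhQuery(frB, ctv, "D99%"), dvhQuery(frZ, ctv, "D99%"))
  # delivery-frame oracle: the second subfraction dose lands on the
  # bladder that slid into the target region during delivery
  blRest <- mask(ph$labels, "bladder")
  blMR4 <- mask(sBig@labelsAt$MR4, "bladder")
  expect_gt(mean(voxels(plB$atp2)[blMR4]), 2 * mean(voxels(plB$atp2)[blRest]))
})

test_that("accumulation is linear in the subfraction doses", {
  ph <- fixturePhantom(c(24, 24, 24), 5)
  s <- makeSession(ph, t23 = c(0, 1, 0.5))
  pl <- sessionPlans(s, marginSpec("large"))
  set <- smokeRegSettings()
  fr1 <- accumulateIntrafraction(s, pl$atp1, pl$atp2, set, seed = 5)
  scaled <- function(d, c) doseGrid(d@grid, voxels(d) * c)
  fr2 <- accumulateIntrafraction(s, scaled(pl$atp1, 2), scaled(pl$atp2, 2),
                                 set, seed = 5)
  expect_equal(voxels(fr2), 2 * voxels(fr1), tolerance = 1e-9)
})

test_that("a single fraction accumulates to itself and totals are exact sums", {
  ph <- fixturePhantom(c(24, 24, 24), 5)
  s1 <- makeSession(ph, fraction = 1L)
  s2 <- makeSession(ph, t12 = c(0, 1, 0), fraction = 2L)
  pl <- sessionPlans(s1, marginSpec("large"))
  set <- smokeRegSettings()
  fr <- accumulateIntrafraction(s1, pl$atp1, pl$atp2, set, seed = 1)
  one <- accumulateInterfraction(list(fr), list(s1), set)
  expect_identical(voxels(one$totalDose), voxels(fr))
  # per-voxel total equals the brute-force sum of the warped grids
  flds <- interfractionFields(list(s1, s2), set, seed = 3)
  two <- accumulateInterfraction(list(fr, fr), list(s1, s2), set,
                                 fields = flds)
  manual <- voxels(fr) + voxels(warpDose(fr, flds[[2]]))
  expect_equal(voxels(two$totalDose), manual, tolerance = 1e-12)
  expect_s3_class(two, "AccumulationResult")
  expect_named(two$metrics, c("ctv_d99", "ctv_d95", "rectum_d1cc",
                              "bladder_d5cc"))
})

test_that("cohort summaries match order-statistic oracles", {
  set.seed(10)
  vals <- round(runif(14, 30, 37), 2)
  df <- data.frame(patient = 1:14, switched = rep(c(FALSE, TRUE), c(9, 5)),
                   ctv_d99 = vals, ctv_d95 = vals + 1,
                   rectum_d1cc = vals - 2, bladder_d5cc = vals - 4)
  s <- summarizeCohort(df)
  tightVals <- vals[1:9]
  row <- s$bySubgroup[s$bySubgroup$subgroup == "tight" &
                        s$bySubgroup$metric == "ctv_d99", ]
  q <- quantile(tightVals, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(c(row$q25, row$median, row$q75), q)
  expect_equal(s$coverage$tight, mean(tightVals >= 34.4))
  expect_equal(s$coverage$switched, mean(vals[10:14] >= 34.4))
  # a single patient: median is the value, IQR width zero
  one <- summarizeCohort(df[1, ])
  r1 <- one$bySubgroup[one$bySubgroup$metric == "ctv_d99", ]
  expect_equal(r1$median, vals[1])
  expect_equal(r1$q75 - r1$q25, 0)
})
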