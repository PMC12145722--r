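# Shift statistics, margin recipe and the traffic-light state machine.

test_that("shift records carry Euclidean magnitudes", {
  r <- shiftRecords(data.frame(patient = 1, fraction = 1,
                               interval = c("shift1", "shift2"),
                               dx_lr = c(1, 0), dy_ap = c(2, 0),
                               dz_si = c(2, 0), source = "ground_truth"))
  expect_equal(r$magnitude, c(3, 0))
  expect_error(shiftRecords(data.frame(patient = 1)), "columns")
})

test_that("error statistics are zero for a motionless cohort", {
  r <- simulateShiftRecords(5, 10, sysSd = 0, randSd = 0, seed = 1)
  st <- cohortErrorStats(r)
  expect_equal(unname(st$Sigma), c(0, 0, 0))
  expect_equal(unname(st$sigma), c(0, 0, 0))
})

test_that("systematic and random errors are recovered from a known cohort", {
  r <- simulateShiftRecords(200, 10, sysSd = 0.3, randSd = 0.4, seed = 42)
  st <- cohortErrorStats(r)
  # bootstrap standard errors over patients
  set.seed(99)
  boot <- replicate(200, {
    ids <- sample(unique(r$patient), replace = TRUE)
    rb <- do.call(rbind, lapply(seq_along(ids), function(i) {
      d <- r[r$patient == ids[i], ]; d$patient <- i; d
    }))
    stb <- cohortErrorStats(shiftRecords(rb))
    c(stb$Sigma, stb$sigma)
  })
  se <- apply(boot, 1, sd)
  for (a in 1:3) {
    expect_lt(abs(st$Sigma[a] - 0.3), 3 * se[a])
    expect_lt(abs(st$sigma[a] - 0.4), 3 * se[3 + a])
  }
})

test_that("single-record patients are excluded from sigma with a warning", {
  r <- shiftRecords(data.frame(patient = c(1, 1, 2),
                               fraction = c(1, 1, 1),
                               interval = c("shift1", "shift2", "shift1"),
                               dx_lr = c(1, 3, 9), dy_ap = 0, dz_si = 0,
                               source = "ground_truth"))
  expect_warning(st <- cohortErrorStats(r), "single record")
  expect_equal(unname(st$sigma[1]), sd(c(1, 3)))
})

test_that("the report prints per-axis statistics in LR, SI, AP order", {
  r <- simulateShiftRecords(50, 10, sysSd = c(0.0, 0.1, 0.3),
                            randSd = 0.4, seed = 7)
  out <- paste(capture.output(print(cohortErrorStats(r))), collapse = "\n")
  expect_match(out, "LR, SI, AP")
  expect_match(out, "\\d\\.\\d ± \\d\\.\\d mm")
  expect_match(out, "3D shift magnitude")
})

test_that("the margin recipe is linear with the standard coefficients", {
  mkStats <- function(Sig, sig)
    structure(list(Sigma = setNames(rep(Sig, 3), c("LR", "AP", "SI")),
                   sigma = setNames(rep(sig, 3), c("LR", "AP", "SI"))),
              class = "ErrorStats")
  expect_equal(unname(vanHerkMargin(mkStats(0, 0))), c(0, 0, 0))
  expect_equal(unname(vanHerkMargin(mkStats(1, 1))), rep(3.2, 3))
  m1 <- vanHerkMargin(mkStats(0.3, 0.4))
  expect_true(all(vanHerkMargin(mkStats(0.5, 0.4)) >= m1))
  expect_true(all(vanHerkMargin(mkStats(0.3, 0.6)) >= m1))
  expect_error(vanHerkMargin(mkStats(1, 1), a = -1), "non-negative")
})

test_that("the traffic-light decision table matches hand-enumerated outcomes", {
  cfg <- trafficLightConfig()  # green < 3, red >= 5, monitor 1-3
  run <- function(m1, m2) applyProtocol(recordsFromMagnitudes(m1, m2), cfg)
  # all green: no switch, tight throughout
  s <- run(rep(1, 5), rep(1, 5))
  expect_false(s$switched)
  expect_equal(unname(s$colours), rep("green", 5))
  expect_true(all(vapply(activeMargins(s), function(m)
    all(m == marginSpec("tight")), logical(1))))
  # red at fraction 2 (shift 1): switch from fraction 3, large margins after
  s <- run(c(1, 6, 1, 1, 1), rep(1, 5))
  expect_true(s$switched)
  expect_equal(s$switchFraction, 3L)
  expect_true(all(vapply(activeMargins(s)[3:5], function(m)
    all(m == marginSpec("large")), logical(1))))
  expect_true(all(vapply(activeMargins(s)[1:2], function(m)
    all(m == marginSpec("tight")), logical(1))))
  # either subfraction may trigger: red on shift 2 only
  expect_true(run(rep(1, 5), c(1, 1, 5.5, 1, 1))$switched)
  # orange at fraction 3, green at fraction 4: monitored but no switch
  s <- run(c(1, 1, 4, 1, 1), rep(1, 5))
  expect_false(s$switched)
  expect_true(4L %in% s$evaluated)
  # orange at fraction 3, red at fraction 4: switch from fraction 5
  s <- run(c(1, 1, 4, 6, 1), rep(1, 5))
  expect_true(s$switched)
  expect_equal(s$switchFraction, 5L)
  # red at fraction 4 without prior orange: fraction 4 is unmonitored
  s <- run(c(1, 1, 1, 6, 1), rep(1, 5))
  expect_false(s$switched)
  # orange never triggers by itself
  expect_false(run(rep(4, 5), rep(4, 5))$switched)
  # boundary: exactly the red threshold triggers; just below does not
  expect_true(run(c(5, 1, 1, 1, 1), rep(1, 5))$switched)
  expect_false(run(c(4.999, 1, 1, 1, 1), c(1, 1, 1, 1, 1))$switched)
  # the switch is absorbing: a later green never reverts the margins
  s <- run(c(6, 1, 1, 1, 1), rep(1, 5))
  expect_equal(s$switchFraction, 2L)
  expect_true(all(vapply(activeMargins(s)[2:5], function(m)
    all(m == marginSpec("large")), logical(1))))
})

test_that("missing shift records are treated conservatively as orange", {
  cfg <- trafficLightConfig()
  rec <- recordsFromMagnitudes(c(1, 1, 1, 1, 1), c(1, 1, 1, 1, 1))
  rec <- rec[!(rec$fraction == 3), ]  # fraction 3 unevaluable
  s <- applyProtocol(shiftRecords(rec), cfg)
  expect_equal(unname(s$colours[3]), "orange")
  expect_true(4L %in% s$monitored)  # conservative orange escalates
  expect_match(paste(s$log, collapse = "\n"), "conservatively")
})

test_that("raising thresholds never increases the number of switchers", {
  set.seed(15)
  recs <- lapply(1:40, function(p)
    recordsFromMagnitudes(runif(5, 0, 7), runif(5, 0, 7), patient = p))
  nSwitch <- vapply(c(3, 4, 5, 6, 8), function(red) {
    cfg <- trafficLightConfig(greenMm = min(3, red), redMm = red)
    sum(vapply(recs, function(r) applyProtocol(r, cfg)$switched, logical(1)))
  }, numeric(1))
  expect_true(all(diff(nSwitch) <= 0))
})

test_that("switch-fraction distribution matches the ground-truth oracle", {
  cfg <- cohortConfig(nPatients = 300, largeMoverFraction = 0.1, seed = 77)
  tl <- trafficLightConfig()
  states <- lapply(1:300, function(p) {
    mags <- lapply(1:5, function(fx) c(
      sampleMotion(cfg, p, fx, "MR2_MR3")$magnitude,
      sampleMotion(cfg, p, fx, "MR3_MR4")$magnitude))
    rec <- recordsFromMagnitudes(vapply(mags, `[`, numeric(1), 1),
                                 vapply(mags, `[`, numeric(1), 2),
                                 patient = p)
    applyProtocol(rec, tl)
  })
  switched <- vapply(states, `[[`, logical(1), "switched")
  # oracle: direct evaluation of the red rule on the generating magnitudes
  oracle <- vapply(1:300, function(p) {
    mags <- vapply(1:5, function(fx) c(
      sampleMotion(cfg, p, fx, "MR2_MR3")$magnitude,
      sampleMotion(cfg, p, fx, "MR3_MR4")$magnitude), numeric(2))
    red <- apply(mags >= tl$redMm, 2, any)
    orange <- apply(mags >= tl$greenMm, 2, any)
    any(red[1:3]) || (orange[3] && red[4])
  }, logical(1))
  expect_identical(switched, oracle)
  # switchers concentrate at fractions 2-5 and are a plausible fraction
  sf <- vapply(states[switched], `[[`, integer(1), "switchFraction")
  expect_true(all(sf >= 2 & sf <= 5))
  p <- mean(switched)
  expect_gt(p, 0.01); expect_lt(p, 0.5)
})
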