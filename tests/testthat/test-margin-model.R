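test_that("margin initialization matches its construction contract", {
  p <- marginParams(initLength = 100, nPoints = 50)
  st <- initMargin(p)
  pts <- marginPoints(st)
  expect_equal(nrow(pts), 50)
  expect_equal(marginLength(st), 100)
  expect_equal(sum(pts$isCP), 0)
  expect_true(all(pts$offset == 0))
  ## empty competence zone: no competent points
  p2 <- marginParams(competenceZone = c(0.5, 0.5))
  expect_true(all(!marginPoints(initMargin(p2))$competent))
  ## invalid parameters name the offending field
  expect_error(marginParams(rcoStrength = 2), "rcoStrength")
  expect_error(marginParams(dt = 0.5), "dt")
  ## identical params give identical states
  expect_identical(initMargin(p), initMargin(p))
})

test_that("growth step applies the segment-wise exponential update", {
  ## uniform gradient, no repression, no CPs: every segment times exp(g dt)
  p <- marginParams(gLong = 0.5, gradientFloor = 1, dt = 0.1, diffSpeed = 0)
  st <- initMargin(p)
  st2 <- growMarginStep(st, p)
  seg0 <- diff(marginPoints(st)$arc)
  seg1 <- diff(marginPoints(st2)$arc)
  expect_equal(seg1, seg0 * exp(0.05), tolerance = 1e-12)

  ## full repression freezes segments
  pr <- marginParams(gLong = 0.5, gradientFloor = 1, dt = 0.1, diffSpeed = 0)
  str <- initMargin(pr)
  str@points$repression <- 0
  str2 <- growMarginStep(str, pr)
  expect_equal(diff(marginPoints(str2)$arc), diff(marginPoints(str)$arc),
               tolerance = 1e-12)
})

test_that("basipetal growth matches a per-segment closed-form oracle", {
  p <- marginParams(initLength = 100, nPoints = 11, gLong = 0.4,
                    gradientFloor = 0, growthZone = 100, dt = 0.05,
                    diffSpeed = 0, vOut = 0)
  st <- initMargin(p)
  st2 <- growMarginStep(st, p)
  ## oracle: independent per-segment exponential update on midpoints
  arc <- marginPoints(st)$arc
  mids <- (arc[-1] + arc[-length(arc)]) / 2
  grad <- 1 - mids / 100            # linear 1 at base to 0 at tip
  oracle <- diff(arc) * exp(0.4 * grad * 0.05)
  expect_equal(diff(marginPoints(st2)$arc), oracle, tolerance = 1e-12)
})

test_that("interval breaking follows the threshold rule", {
  ## competent interval shorter than the threshold: nothing happens
  p <- marginParams(initLength = 100, LThresh = 70,
                    competenceZone = c(0.2, 0.8))
  st <- breakIntervals(initMargin(p), p)
  expect_equal(sum(marginPoints(st)$isCP), 0)

  ## interval of 2.5 x threshold: exactly one CP at the midpoint this call
  ## (oracle: exhaustive scan of competent runs)
  p2 <- marginParams(initLength = 100, LThresh = 24,
                     competenceZone = c(0.2, 0.8))
  st2 <- breakIntervals(initMargin(p2), p2)
  pts <- marginPoints(st2)
  expect_equal(sum(pts$isCP), 1)
  expect_equal(pts$arc[pts$isCP], 50)   # midpoint of [20, 80]
  ## a non-competent gap opened around the new point
  d <- abs(pts$arc - 50)
  expect_true(all(!pts$competent[d <= p2@cpGap / 2]))

  ## past the patterning end time it is a no-op
  p3 <- marginParams(initLength = 100, LThresh = 24, tPatternEnd = 1.5)
  expect_equal(sum(marginPoints(breakIntervals(initMargin(p3), p3))$isCP), 0)
})

test_that("convergence points accumulate and stay separated", {
  p <- marginParams()
  st <- initMargin(p)
  nCP <- 0
  for (i in seq_len(150)) {
    st <- growMarginStep(st, p)
    st <- breakIntervals(st, p)
    cps <- marginPoints(st)$arc[marginPoints(st)$isCP]
    expect_gte(length(cps), nCP)     # count never decreases
    nCP <- length(cps)
    if (length(cps) > 1)
      expect_gte(min(diff(sort(cps))), p@cpGap)
  }
  expect_gt(nCP, 1)
})

test_that("margin length never decreases and simulation is deterministic", {
  p <- marginParams()
  states <- simulateMargin(p)
  lens <- vapply(states, marginLength, 0)
  expect_true(all(diff(lens) >= 0))
  states2 <- simulateMargin(p)
  expect_identical(lapply(states, marginPoints), lapply(states2, marginPoints))
})

test_that("without outgrowth the margin stays straight", {
  p <- singleProtrusionParams(vOut = 0)
  st <- simulateMargin(p, outputTimes = p@tEnd)[[1]]
  expect_equal(max(marginPoints(st)$offset), 0)
  sil <- extractSilhouette(st)
  expect_true(all(sil$offset_um == 0))
})

test_that("early patterning cut-off yields a smooth margin", {
  p <- marginParams(tPatternEnd = 2)   # before any interval can break
  st <- simulateMargin(p, outputTimes = p@tEnd)[[1]]
  expect_equal(sum(marginPoints(st)$isCP), 0)
  expect_equal(nrow(detectProtrusions(extractSilhouette(st))), 0)
})

test_that("wild-type reference produces periodic outgrowths with a
           proximodistal size gradient", {
  p <- marginParams()
  st <- simulateMargin(p, outputTimes = p@tEnd)[[1]]
  pr <- detectProtrusions(extractSilhouette(st))
  expect_gte(nrow(pr), 2)
  ## size decreases toward the tip: the youngest (most distal) protrusion
  ## is the smallest and height falls with arc position overall
  o <- order(pr$tip_arc)
  expect_equal(which.min(pr$height[o]), length(o))
  expect_lt(cor(pr$tip_arc, pr$height, method = "spearman"), 0)
})

test_that("protrusion asymmetry develops only under a basipetal gradient", {
  ## differentiation off isolates the effect of the growth gradient
  asymAt <- function(floor) {
    p <- singleProtrusionParams(gradientFloor = floor, diffSpeed = 0)
    sts <- simulateMargin(p, outputTimes = c(3, 7))
    vapply(sts, function(s) {
      pr <- detectProtrusions(extractSilhouette(s))
      pr$asymmetry[which.max(pr$height)]
    }, 0)
  }
  basip <- asymAt(0.08)
  flat <- asymAt(1)
  expect_lt(basip[1], 15)            # near-symmetric at emergence
  expect_gt(basip[2], 50)            # strongly asymmetric late
  expect_lt(flat[2], 5)              # flat gradient stays symmetric
})

test_that("silhouette round-trips through CSV", {
  p <- singleProtrusionParams()
  sil <- extractSilhouette(simulateMargin(p, outputTimes = 5)[[1]])
  f <- tempfile(fileext = ".csv")
  writeSilhouetteCSV(sil, f)
  back <- readSilhouetteCSV(f)
  expect_equal(back$arc_um, sil$arc_um, tolerance = 1e-9)
  expect_equal(back$offset_um, sil$offset_um, tolerance = 1e-9)
  expect_equal(back$x_um, sil$x_um, tolerance = 1e-9)
})

test_that("sweeps validate their axes", {
  p <- marginParams()
  expect_error(sweepParameters(p, list(nope = 1:2)), "unknown")
  expect_error(sweepParameters(p, list(rcoMode = 1:2)), "non-numeric")
})
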