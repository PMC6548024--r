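test_that("polygon primitives match closed forms", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(polyArea(sq), 4)
  expect_equal(polyPerimeter(sq), 8)
  expect_equal(polyCentroid(sq), c(1, 1))
  expect_equal(polySignedArea(sq), 4)          # CCW positive
  expect_equal(polySignedArea(sq[4:1, ]), -4)  # CW negative
  tri <- cbind(c(0, 3, 0), c(0, 0, 4))
  expect_equal(polyArea(tri), 6)
  expect_equal(polyPerimeter(tri), 12)
})

test_that("half-plane clipping keeps the correct region", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  ## keep x <= 1
  cl <- leafmorph:::clipHalfPlane(sq, c(1, 0), 1)
  expect_equal(polyArea(cl), 2)
  expect_true(all(cl[, 1] <= 1 + 1e-9))
  ## plane outside: unchanged; plane excluding all: empty
  expect_equal(nrow(leafmorph:::clipHalfPlane(sq, c(1, 0), 5)), 4)
  expect_equal(nrow(leafmorph:::clipHalfPlane(sq, c(1, 0), -1)), 0)
})

test_that("bounded Voronoi partitions the domain", {
  dom <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  set.seed(1)
  seeds <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  cells <- leafmorph:::boundedVoronoi(seeds, dom)
  expect_equal(sum(vapply(cells, polyArea, 0)), 100, tolerance = 1e-9)
  ## each seed lies in its own cell
  for (i in seq_len(12))
    expect_true(leafmorph:::pointsInPolygon(seeds[i, , drop = FALSE],
                                            cells[[i]]))
})

test_that("line splitting conserves area and places cuts on edges", {
  hexa <- t(vapply(seq(0, 5), function(k)
    c(cos(pi * k / 3), sin(pi * k / 3)), c(0, 0)))
  sp <- leafmorph:::splitPolygonByLine(hexa, c(0, 0), 0.3)
  expect_false(is.null(sp))
  expect_equal(polyArea(sp$a) + polyArea(sp$b), polyArea(hexa),
               tolerance = 1e-12)
})

test_that("affine fit recovers exact deformations and tolerates noise", {
  set.seed(42)
  p0 <- matrix(runif(16, 0, 20), 8, 2)
  Fm <- matrix(c(1.4, 0.2, -0.1, 0.8), 2, 2)
  tv <- c(3, -2)
  p1 <- p0 %*% t(Fm) + matrix(tv, 8, 2, byrow = TRUE)
  fit <- fitAffine(p0, p1)
  expect_equal(fit$F, Fm, tolerance = 1e-10)
  expect_equal(fit$t, tv, tolerance = 1e-9)

  ## Monte-Carlo: junction noise sd 0.5 um on the 8 junctions of a ~20 um
  ## cell, median ratio error below 3%
  oct <- t(vapply(0:7, function(k)
    10 * c(cos(pi * k / 4), sin(pi * k / 4)), c(0, 0)))
  errs <- replicate(200, {
    q0 <- oct + matrix(rnorm(16, 0, 1), 8, 2)
    q1n <- q0 %*% t(Fm) + matrix(rnorm(16, 0, 0.5), 8, 2)
    f <- fitAffine(q0, q1n)
    truth <- leafmorph:::principalStretches(Fm)
    est <- leafmorph:::principalStretches(f$F)
    abs(est$kmax / est$kmin - truth$kmax / truth$kmin) /
      (truth$kmax / truth$kmin)
  })
  expect_lt(median(errs), 0.03)
})

test_that("polar decomposition and principal stretches are exact", {
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(2, 0.3, 0.3, 1.1), 2, 2)
  pd <- leafmorph:::polarDecomp2(R %*% S)
  expect_equal(pd$R, R, tolerance = 1e-12)
  expect_equal(pd$S, S, tolerance = 1e-12)
  ps <- leafmorph:::principalStretches(diag(c(2, 1)))
  expect_equal(ps$kmax, 2)
  expect_equal(ps$kmin, 1)
  expect_equal(ps$orientation, 0)
})

test_that("peak finding respects prominence", {
  y <- c(0, 1, 0.8, 3, 0.1, 0.5, 0.4, 0)
  expect_equal(leafmorph:::findPeaks(y, prominence = 1.5), 4L)
  expect_setequal(leafmorph:::findPeaks(y, prominence = 0.05), c(2L, 4L, 6L))
})
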