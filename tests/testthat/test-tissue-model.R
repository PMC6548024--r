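test_that("primordium initialization is valid and deterministic", {
  cfg <- tissueConfig()
  st <- initPrimordium(cfg)
  expect_true(validObject(st))
  expect_setequal(unique(st@tissue), c("blade", "midrib_petiole", "margin"))
  ## all triangles non-degenerate
  areas <- vapply(seq_len(nrow(st@triangles)), function(t)
    polyArea(st@vertices[st@triangles[t, ], ]), 0)
  expect_true(all(areas > 1e-6))
  ## same seed, same state
  st2 <- initPrimordium(cfg)
  expect_identical(st@vertices, st2@vertices)
  expect_identical(st@margin, st2@margin)
  ## degenerate geometry is refused
  expect_error(initPrimordium(tissueConfig(initWidth = 1)), "degenerate")
})

test_that("differentiation factor follows diffusion-decay physics", {
  cfg <- tissueConfig()
  st <- initPrimordium(cfg)
  ## large D, no decay: field stays at the source value, nothing
  ## differentiates while the level is above threshold
  cfgL <- tissueConfig(D = 1e9, kDecay = 0)
  stL <- st; stL@time <- 3
  stL <- updateDiffFactor(stL, cfgL, 0.1)
  expect_true(all(abs(stL@conc - cfgL@cSource) < 1e-6))
  expect_equal(sum(stL@differentiated), 0)

  ## steady state on a strip matches the cosh closed form to 1%
  m <- meshRectangle(nx = 5, ny = 60, W = 10, L = 200)
  D <- 4000; k <- 0.4; ell <- sqrt(D / k)
  cs <- leafmorph:::implicitDiffusionStep(m$vertices, m$triangles,
                                          rep(1, nrow(m$vertices)),
                                          dt = 1e12, D = D, k = k,
                                          source = m$base, cSource = 1)
  closed <- cosh((200 - m$vertices[, 2]) / ell) / cosh(200 / ell)
  expect_lt(max(abs(cs - closed) / closed), 0.01)
})

test_that("the differentiated set only grows", {
  ## short factor penetration length so the front appears within the run
  cfg <- tissueConfig(patterningEnabled = FALSE, kDecay = 20)
  st <- initPrimordium(cfg)
  prev <- st@differentiated
  for (i in 1:60) {
    st@time <- 1 + i * 0.05
    st <- updateDiffFactor(st, cfg, 0.05)
    spec <- specifiedGrowth(st, cfg)
    st <- growAndRelax(st, spec, cfg, 0.05)
    expect_true(all(st@differentiated[prev]))
    prev <- st@differentiated
  }
  expect_gt(sum(prev), 0)
})

test_that("margin reaction obeys its limiting cases", {
  cfg <- tissueConfig()
  set.seed(11)
  ring <- data.frame(vertex = 1:30, auxin = 1 + rnorm(30, 0, 0.02), cuc = 1,
                     isMax = FALSE, differentiated = FALSE)
  ## cuc = 0 disables the transport feedback: no maxima, auxin approaches
  ## the uniform production/decay balance
  r0 <- ring; r0$cuc <- 0
  cfg0 <- tissueConfig(cucRecover = 0)
  for (i in 1:2000) r0 <- marginReactionStep(r0, cfg0, 0.002)
  expect_equal(sum(r0$isMax), 0)
  expect_lt(diff(range(r0$auxin)), 0.01)
  ## conservation with production and decay off
  cfgC <- tissueConfig(auxinProd = 0, auxinDecay = 0)
  rc <- ring
  tot0 <- sum(rc$auxin)
  for (i in 1:500) {
    rc <- marginReactionStep(rc, cfgC, 0.002)
    expect_lt(abs(sum(rc$auxin) - tot0), 1e-8)
  }
})

test_that("explicit reaction integration matches a deSolve oracle", {
  skip_if_not_installed("deSolve")
  cfg <- tissueConfig()
  set.seed(3)
  n <- 20
  a0 <- 1 + rnorm(n, 0, 0.02)
  rhs <- function(t, y, parms) {
    a <- y[1:n]; cu <- y[n + 1:n]
    left <- c(n, seq_len(n - 1)); right <- c(seq_len(n - 1) + 1, 1)
    wL <- a[left]^cfg@hExp; wR <- a[right]^cfg@hExp
    tot <- wL + wR
    pL <- ifelse(tot > 0, wL / tot, 0); pR <- ifelse(tot > 0, wR / tot, 0)
    fL <- cfg@transportCoef * cu * pL * a
    fR <- cfg@transportCoef * cu * pR * a
    inflow <- numeric(n)
    inflow[left] <- inflow[left] + fL
    inflow[right] <- inflow[right] + fR
    diffus <- cfg@auxinDiffusion * (a[left] + a[right] - 2 * a)
    da <- cfg@auxinProd - cfg@auxinDecay * a - (fL + fR) + inflow + diffus
    hillA <- a^2 / (a^2 + cfg@auxinThr^2)
    dcu <- cfg@cucRecover * (1 - cu) - cfg@cucRepress * hillA * cu
    list(c(da, dcu))
  }
  sol <- deSolve::ode(c(a0, rep(1, n)), times = c(0, 0.5), func = rhs,
                      parms = NULL)
  r <- data.frame(vertex = 1:n, auxin = a0, cuc = 1, isMax = FALSE,
                  differentiated = FALSE)
  for (i in 1:2500) r <- marginReactionStep(r, cfg, 0.0002)
  expect_equal(r$auxin, unname(sol[2, 1 + 1:n]), tolerance = 5e-3)
  expect_equal(r$cuc, unname(sol[2, 1 + n + 1:n]), tolerance = 5e-3)
})

test_that("maxima spacing depends systematically on the transport
           coefficient", {
  counts <- vapply(c(2, 6, 18), function(Tc) {
    cfg <- tissueConfig(transportCoef = Tc, cucRepress = 0)
    set.seed(7)
    r <- data.frame(vertex = 1:60, auxin = 1 + rnorm(60, 0, 0.02), cuc = 1,
                    isMax = FALSE, differentiated = FALSE)
    for (i in 1:4000) r <- marginReactionStep(r, cfg, 0.002)
    sum(r$isMax)
  }, 0)
  expect_true(all(diff(counts) >= 0) || all(diff(counts) <= 0))
  expect_true(counts[1] != counts[3])
})

test_that("specified growth respects tissue, window, patterning and
           differentiation", {
  cfg <- tissueConfig()
  st <- initPrimordium(cfg)
  ## initiation window: one homogeneous anisotropic tensor
  sp0 <- specifiedGrowth(st, cfg)
  expect_equal(unique(sp0$ratePar), cfg@initRatePar)
  expect_equal(unique(sp0$ratePerp), cfg@initRatePerp)
  expect_equal(unique(sp0$theta), pi / 2)

  ## after the window with patterning off: rates depend only on tissue
  ## label and differentiation state
  st@time <- 3
  cfgOff <- tissueConfig(patterningEnabled = FALSE)
  sp1 <- specifiedGrowth(st, cfgOff)
  for (lab in c("blade", "margin"))
    expect_equal(unique(sp1$ratePar[st@tissue == lab]), cfgOff@bladeRate)
  expect_equal(unique(sp1$ratePar[st@tissue == "midrib_petiole"]),
               cfgOff@midribRatePar)

  ## boosted maximum versus CUC2 sinus element: rate ratio equals the
  ## configured boost/inhibition quotient.  Two maxima with an auxin
  ## minimum (the sinus) between them along the chain.
  nm <- nrow(st@margin)
  st@margin$isMax <- FALSE
  st@margin$isMax[c(5, 15)] <- TRUE
  st@margin$auxin <- 1
  st@margin$auxin[c(5, 15)] <- 3
  st@margin$auxin[10] <- 0.2        # the sinus minimum
  st@margin$cuc <- 1
  mv <- st@margin$vertex[5]
  sv <- st@margin$vertex[10]
  inTri <- function(vtx) which(vapply(seq_len(nrow(st@triangles)), function(t)
    vtx %in% st@triangles[t, ], TRUE) & st@tissue == "margin")
  mxT <- inTri(mv)[1]
  snT <- inTri(sv)[1]
  sp2 <- specifiedGrowth(st, cfg)
  expect_equal(sp2$ratePar[mxT] / sp2$ratePar[snT],
               cfg@auxinBoost / cfg@cucInhibition, tolerance = 1e-9)

  ## differentiated triangles get the post-differentiation factor
  st@differentiated[st@tissue == "blade"] <- TRUE
  sp3 <- specifiedGrowth(st, cfgOff)
  expect_equal(unique(sp3$ratePar[st@tissue == "blade"]),
               cfgOff@bladeRate * cfgOff@diffGrowthFactor)
})

test_that("compatible isotropic growth relaxes to exact uniform scaling", {
  cfg <- tissueConfig()
  st <- initPrimordium(cfg)
  a0 <- sum(vapply(seq_len(nrow(st@triangles)), function(t)
    polyArea(st@vertices[st@triangles[t, ], ]), 0))
  spec <- data.frame(ratePar = rep(0.5, nrow(st@triangles)), ratePerp = 0.5,
                     theta = 0)
  st2 <- growAndRelax(st, spec, cfg, 0.2)
  a1 <- sum(vapply(seq_len(nrow(st2@triangles)), function(t)
    polyArea(st2@vertices[st2@triangles[t, ], ]), 0))
  expect_equal(a1 / a0, exp(0.5 * 0.2)^2, tolerance = 1e-3)
})

test_that("relaxation decreases energy and flags incompatible growth", {
  cfg <- tissueConfig()
  st <- initPrimordium(cfg)
  ## anisotropic central strip against an isotropic surround
  strip <- abs((st@vertices[st@triangles[, 1], 1] +
                  st@vertices[st@triangles[, 2], 1] +
                  st@vertices[st@triangles[, 3], 1]) / 3) < 4
  spec <- data.frame(ratePar = ifelse(strip, 1.5, 0.2),
                     ratePerp = 0.2, theta = pi / 2)
  ## energy before relaxation (grown rest, old positions) vs after
  rest <- st@rest
  for (t in seq_len(nrow(st@triangles))) {
    th <- spec$theta[t]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    G <- R %*% diag(c(exp(spec$ratePar[t] * 0.2),
                      exp(spec$ratePerp[t] * 0.2))) %*% t(R)
    rest[, , t] <- G %*% rest[, , t]
  }
  e0 <- leafmorph:::elasticEnergy(st@vertices, st@triangles, rest, 1, 1)
  rx <- elasticRelax(st@vertices, st@triangles, rest)
  e1 <- leafmorph:::elasticEnergy(rx$vertices, st@triangles, rest, 1, 1)
  expect_lt(e1, e0)
  ## resultant growth of strip-adjacent triangles deviates from their
  ## specification: the tissue cannot satisfy both regions at once
  st2 <- st
  st2@rest <- rest
  st2@vertices <- rx$vertices
  gr <- leafmorph:::resultantGrowth(st, st2)
  specArea <- 100 * (exp((spec$ratePar + spec$ratePerp) * 0.2) - 1)
  dev <- abs(gr$area_ext_pct - specArea[gr$tri])
  expect_gt(max(dev), 2)       # mechanical accommodation is visible
  expect_gt(e1, 1e-9)          # residual strain remains
})

test_that("tissue area never shrinks under non-negative specified rates", {
  cfg <- tissueConfig(patterningEnabled = FALSE, tEnd = 1.6)
  sim <- simulateTissue(cfg, saveEvery = 0.2)
  areas <- vapply(sim$states, function(s)
    sum(vapply(seq_len(nrow(s@triangles)), function(t)
      polyArea(s@vertices[s@triangles[t, ], ]), 0)), 0)
  expect_true(all(diff(areas) > 0))
})
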