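test_that("area extension matches closed forms on constructed cases", {
  tp0 <- gridTessellation()
  ## identity: 0% everywhere
  tp1 <- transformTimepoint(tp0)
  ext <- areaExtension(tp0, tp1, identityLineage(tp0, tp1))
  expect_equal(ext$extension_pct, rep(0, 4))
  ## uniform 1.3x per-axis scaling: 69% everywhere
  tp2 <- transformTimepoint(tp0, A = diag(c(1.3, 1.3)))
  ext2 <- areaExtension(tp0, tp2, identityLineage(tp0, tp2))
  expect_equal(ext2$extension_pct, rep(69, 4), tolerance = 1e-9)
  ## child without geometric parent raises a lineage error listing the id
  bad <- lineageMap(tp0@time, tp2@time,
                    c(stats::setNames(cellIds(tp0), cellIds(tp0)),
                      ghost = "nope"))
  expect_error(areaExtension(tp0, tp2, bad), "ghost")
})

test_that("growth anisotropy recovers imposed deformations", {
  tp0 <- gridTessellation()
  ## pure x2 stretch along x
  tp1 <- transformTimepoint(tp0, A = diag(c(2, 1)))
  ani <- growthAnisotropy(tp0, tp1, identityLineage(tp0, tp1))
  expect_equal(ani$ratio, rep(2, 4), tolerance = 1e-12)
  expect_equal(ani$pct, rep(50, 4), tolerance = 1e-12)
  expect_equal(ani$orientation, rep(0, 4), tolerance = 1e-9)
  ## pure uniform scaling: ratio 1, orientation undefined (NA)
  tp2 <- transformTimepoint(tp0, A = diag(c(1.5, 1.5)))
  ani2 <- growthAnisotropy(tp0, tp2, identityLineage(tp0, tp2))
  expect_equal(ani2$ratio, rep(1, 4), tolerance = 1e-9)
  expect_true(all(is.na(ani2$orientation)))
  ## general affine recovered through the polar decomposition
  A <- matrix(c(1.7, 0.4, 0.1, 0.9), 2, 2)
  tp3 <- transformTimepoint(tp0, A = A, shift = c(5, -3))
  ani3 <- growthAnisotropy(tp0, tp3, identityLineage(tp0, tp3))
  ps <- leafmorph:::principalStretches(A)
  expect_equal(ani3$ratio, rep(ps$kmax / ps$kmin, 4), tolerance = 1e-10)
  expect_equal(ani3$orientation, rep(ps$orientation, 4), tolerance = 1e-8)
})

test_that("quantifications are invariant under rigid motions", {
  tp0 <- gridTessellation()
  A <- matrix(c(1.4, 0.2, 0, 1.1), 2, 2)
  tp1 <- transformTimepoint(tp0, A = A)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tp0r <- transformTimepoint(tp0, A = R, shift = c(12, 7), time = tp0@time)
  tp1r <- transformTimepoint(tp1, A = R, shift = c(-4, 3), time = tp1@time)
  lin <- identityLineage(tp0, tp1)
  expect_equal(areaExtension(tp0r, tp1r, lin)$extension_pct,
               areaExtension(tp0, tp1, lin)$extension_pct, tolerance = 1e-9)
  expect_equal(growthAnisotropy(tp0r, tp1r, lin)$ratio,
               growthAnisotropy(tp0, tp1, lin)$ratio, tolerance = 1e-9)
  p <- cellPolygons(tp0)[[1]]
  pr <- p %*% t(R) * 3.7
  pr <- sweep(pr, 2, c(100, -50), "+")
  expect_equal(lobeyness(pr), lobeyness(p), tolerance = 1e-9)
})

test_that("lobeyness matches direct perimeter arithmetic", {
  ## any convex polygon: exactly 1
  hexa <- t(vapply(0:5, function(k) c(cos(pi * k / 3), sin(pi * k / 3)),
                   c(0, 0)))
  expect_identical(lobeyness(hexa), 1)
  ## plus-sign with arms of length and width a: hand-computed oracle
  a <- 2
  plus <- cbind(
    c(a, 2 * a, 2 * a, 3 * a, 3 * a, 2 * a, 2 * a, a, a, 0, 0, a),
    c(0, 0, a, a, 2 * a, 2 * a, 3 * a, 3 * a, 2 * a, 2 * a, a, a))
  perim <- 12 * a
  hull <- 4 * a + 4 * a * sqrt(2)   # chull of the 12 corners
  expect_equal(lobeyness(plus), perim / hull, tolerance = 1e-12)
  ## self-intersecting input is rejected
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(lobeyness(bow), "self-intersecting")
})

test_that("lineage composition equals brute-force path following", {
  ## worked example: A -> {B, C}, B -> {D}, C -> {E, F}
  m1 <- lineageMap(0, 1, c(B = "A", C = "A"))
  m2 <- lineageMap(1, 2, c(D = "B", E = "C", F = "C"))
  comp <- composeLineages(list(m1, m2))
  expect_equal(parentMap(comp), c(D = "A", E = "A", F = "A"))
  expect_equal(lineageInterval(comp), c(0, 2))
  ## single map composes to itself
  expect_identical(parentMap(composeLineages(list(m1))), parentMap(m1))
  ## broken chains are refused
  m3 <- lineageMap(5, 6, c(X = "D"))
  expect_error(composeLineages(list(m1, m3)), "broken")

  ## random division forests over 5 intervals vs path following
  set.seed(99)
  maps <- list()
  pop <- sprintf("c%03d", 1:20)
  for (i in 1:5) {
    nxt <- character(0)
    par <- character(0)
    counter <- 1
    for (cid in pop) {
      kids <- if (runif(1) < 0.3) 2 else 1
      for (k in seq_len(kids)) {
        child <- sprintf("g%d_%03d", i, counter)
        counter <- counter + 1
        nxt <- c(nxt, child)
        par[child] <- cid
      }
    }
    maps[[i]] <- lineageMap(i - 1, i, par)
    pop <- nxt
  }
  comp <- composeLineages(maps)
  follow <- function(cid) {
    for (i in 5:1) cid <- parentMap(maps[[i]])[[cid]]
    cid
  }
  for (leaf in names(parentMap(comp)))
    expect_identical(parentMap(comp)[[leaf]], follow(leaf))
})

test_that("alignment graphs profile growth along the P-D axis", {
  ## homogeneous growth: flat graph
  cfg <- synthConfig(nCellsInit = 120, nTimepoints = 3, junctionNoiseSD = 0,
                     seed = 8, growthField = list(type = "uniform", rate = 0.3))
  tl <- makeTimelapse(cfg)
  ag <- alignmentGraph(tl$series, tl$lineages, "area_extension")
  expect_equal(nrow(ag), 10)
  expect_true(all(abs(ag$n - mean(ag$n)) <= 1))        # equal-count bins
  expect_lt(max(ag$value) - min(ag$value), 1)          # flat within 1%
  ## contribution bins sum to 100
  agc <- alignmentGraph(tl$series, tl$lineages, "contribution")
  expect_equal(sum(agc$value), 100, tolerance = 0.01)
  ## proximal growth zone: extension decreases from base to tip
  cfgB <- synthConfig(nCellsInit = 120, nTimepoints = 3, junctionNoiseSD = 0,
                      seed = 8,
                      growthField = list(type = "basipetal", rate = 0.4,
                                         zone = 0.6, floor = 0.1))
  tlB <- makeTimelapse(cfgB)
  agB <- alignmentGraph(tlB$series, tlB$lineages, "area_extension")
  expect_lt(cor(agB$bin, agB$value, method = "spearman"), -0.9)
  ## cell-number distance mode produces the same monotone trend
  agN <- alignmentGraph(tlB$series, tlB$lineages, "area_extension",
                        distanceMode = "cell_number")
  expect_lt(cor(agN$bin, agN$value, method = "spearman"), -0.8)
})

test_that("region classification recovers a programmed midrib strip", {
  cfg <- synthConfig(nCellsInit = 250, nTimepoints = 5, junctionNoiseSD = 0,
                     seed = 4, divisionArea = 1e9, lloydIters = 8,
                     growthField = list(type = "tissue", bladeRate = 0.15,
                                        midribRatePar = 0.50,
                                        midribRatePerp = 0, midribFrac = 0.45))
  tl <- makeTimelapse(cfg)
  truth <- tl$truth[tl$truth$t_from == 3, ]
  regs <- classifyRegions(tl$series, tl$lineages)
  r0 <- regs[regs$time == 3, ]
  tru <- stats::setNames(truth$region, truth$cell)[r0$cell]
  ## evaluate away from the strip interface, where junction sharing blurs
  ## the programmed field over one cell by construction
  adj <- adjacency(tl$series[[1]])
  mixed <- tru[adj[, 1]] != tru[adj[, 2]]
  interface <- unique(c(adj[mixed, 1], adj[mixed, 2]))
  core <- !(r0$cell %in% interface)
  got <- ifelse(r0$region == "sinus", "blade", r0$region)
  expect_gte(mean(got[core] == tru[core]), 0.95)
  ## lineage monotonicity: pushforward of the reference labels covers a
  ## superset of each label set (division only adds members)
  lin <- composeLineages(tl$lineages)
  r1 <- regs[regs$time == max(regs$time), ]
  for (lab in c("midrib_petiole", "blade")) {
    refSet <- r0$cell[r0$region == lab]
    fwd <- names(parentMap(lin))[parentMap(lin) %in% refSet]
    expect_true(all(r1$region[match(fwd, r1$cell)] == lab))
  }
})

test_that("no protrusions means no sinus cells", {
  cfg <- synthConfig(nCellsInit = 80, nTimepoints = 3, junctionNoiseSD = 0,
                     seed = 5, growthField = list(type = "uniform", rate = 0.3))
  tl <- makeTimelapse(cfg)
  regs <- classifyRegions(tl$series, tl$lineages)
  expect_equal(sum(regs$region == "sinus"), 0)
})

test_that("protrusion triangle metrics match coordinate arithmetic", {
  ## isoceles bump: base 10, height 20
  outline <- cbind(c(0, 5, 10), c(0, 20, 0))
  tri <- protrusionTriangle(outline, landmarks = c(1, 2, 3))
  expect_equal(unname(tri), c(10, 20, 0))
  ## tip shifted 3 um along the base: asymmetry from the hypotenuses
  out2 <- cbind(c(0, 8, 10), c(0, 20, 0))
  tri2 <- protrusionTriangle(out2, landmarks = c(1, 2, 3))
  expect_equal(unname(tri2["base_width"]), 10)
  expect_equal(unname(tri2["length"]), 20)
  expect_equal(unname(tri2["asymmetry"]),
               abs(sqrt(8^2 + 20^2) - sqrt(2^2 + 20^2)), tolerance = 1e-12)
})

test_that("margin-model runs reproduce the serration versus leaflet base
           dynamics", {
  ## serration-like run (no repression): base widens faster than length
  p <- singleProtrusionParams()
  sts <- simulateMargin(p, outputTimes = c(4, 7))
  m <- lapply(sts, function(s) {
    pr <- detectProtrusions(extractSilhouette(s))
    pr[which.max(pr$height), ]
  })
  baseGrowth <- m[[2]]$base_width / m[[1]]$base_width
  lenGrowth <- m[[2]]$length / m[[1]]$length
  expect_gt(baseGrowth, lenGrowth)
  ## strong basal repression: base nearly constant while length grows
  pr <- singleProtrusionParams(rcoStrength = 0.9, rcoMode = "extend_into_base")
  stsR <- simulateMargin(pr, outputTimes = c(4, 7))
  mR <- lapply(stsR, function(s) {
    d <- detectProtrusions(extractSilhouette(s))
    d[which.max(d$height), ]
  })
  expect_lt(mR[[2]]$base_width / mR[[1]]$base_width, baseGrowth)
  expect_gt(mR[[2]]$length / mR[[1]]$length, 1.3)
})

test_that("growth records assemble into one table", {
  tp0 <- gridTessellation()
  tp1 <- transformTimepoint(tp0, A = diag(c(1.2, 1.5)))
  rec <- quantifyGrowth(tp0, tp1, identityLineage(tp0, tp1))
  expect_setequal(rec$cell, cellIds(tp0))
  expect_equal(rec$extension_pct, rep(80, 4), tolerance = 1e-9)
  expect_equal(rec$ratio, rep(1.25, 4), tolerance = 1e-9)
  expect_true(all(rec$lobeyness == 1))
})
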