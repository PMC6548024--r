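test_that("tessellation generation tiles the domain deterministically", {
  cfg <- synthConfig(nCellsInit = 100, seed = 3)
  tp <- generateTessellation(cfg)
  expect_equal(nCells(tp), 100)
  dom <- leafDomain(cfg)
  expect_equal(tessellationArea(tp), polyArea(dom), tolerance = 1e-9)
  ## all polygons simple with positive area
  areas <- vapply(cellPolygons(tp), polyArea, 0)
  expect_true(all(areas > 0))
  ## same seed: identical output
  tp2 <- generateTessellation(cfg)
  expect_identical(tp@vertices, tp2@vertices)
  expect_identical(tp@cells, tp2@cells)
})

test_that("degenerate generator configurations are handled", {
  ## single cell equals the domain
  cfg1 <- synthConfig(nCellsInit = 1, seed = 1)
  tp1 <- generateTessellation(cfg1)
  expect_equal(nCells(tp1), 1)
  expect_equal(tessellationArea(tp1), polyArea(leafDomain(cfg1)),
               tolerance = 1e-9)
  ## domain too small for the requested count
  cfgBad <- synthConfig(nCellsInit = 10000, domainLength = 30,
                        bladeWidth = 16, seed = 1)
  expect_error(generateTessellation(cfgBad), "too small")
})

test_that("advancing without divisions is a bijection", {
  cfg <- synthConfig(nCellsInit = 60, nTimepoints = 2, junctionNoiseSD = 0,
                     seed = 5, divisionArea = 1e9,
                     growthField = list(type = "uniform", rate = 0.3))
  tl <- makeTimelapse(cfg)
  lin <- parentMap(tl$lineages[[1]])
  expect_equal(sort(names(lin)), sort(unname(lin)))
  expect_equal(anyDuplicated(unname(lin)), 0L)
})

test_that("divisions conserve area and keep junctions consistent", {
  ## tiny threshold: every cell divides each interval
  cfg <- synthConfig(nCellsInit = 40, nTimepoints = 3, junctionNoiseSD = 0,
                     seed = 6, divisionArea = 1,
                     growthField = list(type = "uniform", rate = 0.2))
  tl <- makeTimelapse(cfg)
  for (k in 1:2) {
    t0 <- tl$series[[k]]; t1 <- tl$series[[k + 1]]
    lin <- tl$lineages[[k]]
    expect_true(all(table(parentMap(lin)) == 2))  # every cell divided
    ## daughters' areas sum to the parent's grown area
    ext <- areaExtension(t0, t1, lin)
    expect_equal(ext$area_t1, ext$area_t0 * 1.2, tolerance = 1e-9)
    expect_true(validObject(t1))
  }
})

test_that("basipetal truth decreases monotonically along the axis", {
  cfg <- synthConfig(nCellsInit = 150, nTimepoints = 2, junctionNoiseSD = 0,
                     seed = 7,
                     growthField = list(type = "basipetal", rate = 0.4,
                                        zone = 0.6, floor = 0.1))
  tl <- makeTimelapse(cfg)
  tr <- tl$truth
  cents <- t(vapply(cellPolygons(tl$series[[1]], tr$cell), polyCentroid,
                    c(0, 0)))
  dec <- cut(cents[, 2], quantile(cents[, 2], 0:10 / 10),
             include.lowest = TRUE)
  mExt <- tapply(tr$extension_pct, dec, mean)
  ## strictly decreasing through the proximal zone, constant at the floor
  ## beyond it
  expect_true(all(diff(mExt) <= 1e-9))
  expect_gt(mExt[1] - mExt[10], 10)
})

test_that("quantification round-trips the programmed uniform field", {
  cfg <- synthConfig(nCellsInit = 80, nTimepoints = 5, junctionNoiseSD = 0,
                     seed = 2, divisionArea = 600,
                     growthField = list(type = "uniform", rate = 0.3))
  tl <- makeTimelapse(cfg)
  for (k in seq_len(4)) {
    ext <- areaExtension(tl$series[[k]], tl$series[[k + 1]], tl$lineages[[k]])
    expect_true(all(abs(ext$extension_pct - 30) < 0.5))
  }
})

test_that("junction noise leaves isotropic cells nearly isotropic", {
  ## ~25 um cells (epidermal scale at mid development), noise on both
  ## observations
  cfg <- synthConfig(nCellsInit = 80, domainLength = 400, bladeWidth = 200,
                     nTimepoints = 2, junctionNoiseSD = 0.5,
                     seed = 9, divisionArea = 1e9,
                     growthField = list(type = "uniform", rate = 0.3))
  tl <- makeTimelapse(cfg)
  ani <- growthAnisotropy(tl$series[[1]], tl$series[[2]], tl$lineages[[1]])
  expect_lt(median(ani$pct, na.rm = TRUE), 5)
})

test_that("emitted files reproduce the in-memory truth exactly", {
  cfg <- synthConfig(nCellsInit = 50, nTimepoints = 3, junctionNoiseSD = 0,
                     seed = 10, divisionArea = 700,
                     growthField = list(type = "uniform", rate = 0.35))
  tl <- makeTimelapse(cfg)
  d <- tempfile(); dir.create(d)
  for (i in seq_along(tl$series))
    writeTessellation(tl$series[[i]], file.path(d, sprintf("t%d.txt", i)))
  writeLineage(tl$lineages[[1]], file.path(d, "lin1.csv"))
  r1 <- readTessellation(file.path(d, "t1.txt"))
  r2 <- readTessellation(file.path(d, "t2.txt"))
  l1 <- readLineage(file.path(d, "lin1.csv"))
  extMem <- areaExtension(tl$series[[1]], tl$series[[2]], tl$lineages[[1]])
  extFile <- areaExtension(r1, r2, l1)
  expect_equal(extFile$extension_pct, extMem$extension_pct, tolerance = 1e-9)
  expect_equal(extFile$proliferation, extMem$proliferation)
})
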