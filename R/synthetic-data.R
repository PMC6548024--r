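## Synthetic segmented time-lapse generator with known ground truth.
##
## Emulates the data regime of confocal leaf time-lapse segmentations:
## leaf-shaped domains of polygonal cells, daily observation intervals,
## spatially graded areal growth, proximodistal anisotropy in the
## midrib/petiole, size-triggered divisions with shortest-wall placement,
## and junction jitter emulating segmentation noise.  Every emitted
## quantity (per-cell growth tensors, lineages, regions) is recorded as
## ground truth before noise is added, so the quantification pipeline can
## be validated without any external data.

#' Synthetic time-lapse configuration
#'
#' Defaults emulate the study conditions: a few hundred cells on a
#' leaf-shaped domain a few hundred um long, daily intervals, basipetally
#' graded areal growth of a few tens of percent per day, and sub-micron
#' junction jitter.
#'
#' @param nCellsInit initial cell count.
#' @param domainLength leaf outline length (um).
#' @param bladeWidth maximal blade width (um).
#' @param petioleFraction fraction of the length occupied by the petiole.
#' @param petioleWidth petiole width as a fraction of \code{bladeWidth}.
#' @param growthField list descriptor.  \code{type = "uniform"}: areal rate
#'   \code{rate} (fraction/day) everywhere.  \code{type = "basipetal"}:
#'   \code{rate} at the base declining linearly to \code{floor * rate} at
#'   \code{zone} (fraction of the domain length), floor beyond — the
#'   basipetally receding proliferative zone.  \code{type = "tissue"}:
#'   isotropic \code{bladeRate} in the blade, anisotropic
#'   (\code{midribRatePar}, \code{midribRatePerp}) along/across the
#'   proximodistal axis in a central strip of half-width
#'   \code{midribFrac * bladeWidth / 2}; tissue rates are per-axis linear
#'   extension rates (fraction/day), whereas uniform/basipetal rates are
#'   areal.  \code{type = "custom"}: element
#'   \code{fun(x, y, dt)} returning per-axis linear factors.
#' @param divisionArea division area threshold (um^2).
#' @param divisionJitterSD orientation jitter of the division wall (rad).
#' @param nTimepoints number of observations (daily).
#' @param dtDays observation interval (day).
#' @param junctionNoiseSD junction coordinate noise (um), applied after
#'   ground truth is recorded.
#' @param lloydIters Lloyd iterations for the initial centroidal Voronoi
#'   tessellation.
#' @param seed integer seed.
#' @return a validated \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(nCellsInit = 150, domainLength = 300,
                        bladeWidth = 160, petioleFraction = 0.25,
                        petioleWidth = 0.35,
                        growthField = list(type = "basipetal", rate = 0.35,
                                           zone = 0.5, floor = 0.15),
                        divisionArea = 800, divisionJitterSD = 0.15,
                        nTimepoints = 5, dtDays = 1,
                        junctionNoiseSD = 0.25, lloydIters = 12, seed = 1L) {
  obj <- new("SynthConfig", nCellsInit = nCellsInit,
             domainLength = domainLength, bladeWidth = bladeWidth,
             petioleFraction = petioleFraction, petioleWidth = petioleWidth,
             growthField = growthField, divisionArea = divisionArea,
             divisionJitterSD = divisionJitterSD, nTimepoints = nTimepoints,
             dtDays = dtDays, junctionNoiseSD = junctionNoiseSD,
             lloydIters = lloydIters, seed = seed)
  msg <- validObject(obj, test = TRUE)
  if (is.character(msg)) stop("invalid synthetic configuration: ",
                              paste(msg, collapse = "; "))
  obj
}

#' Leaf-shaped domain outline
#'
#' Petiole (rectangular strip) plus a half-elliptic blade, base at y = 0,
#' midline on x = 0, counter-clockwise.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param nArc boundary points per side.
#' @return n x 2 outline matrix (um).
#' @export
leafDomain <- function(config, nArc = 40) {
  L <- config@domainLength
  pl <- config@petioleFraction * L
  bw <- config@bladeWidth / 2
  pw <- config@petioleWidth * bw
  bladeY <- seq(pl, L, length.out = nArc)
  half <- function(y) {
    t <- (y - pl) / (L - pl)
    pw + (bw - pw) * sin(pi * pmin(t, 1))^0.8 * as.numeric(t < 1) +
      0 * as.numeric(t >= 1)
  }
  xr <- half(bladeY)
  xr[length(xr)] <- 0
  right <- cbind(xr, bladeY)
  left <- cbind(-rev(xr[-length(xr)]), rev(bladeY[-length(bladeY)]))
  out <- rbind(c(pw, 0), right, left, c(-pw, 0))
  ensureCCW(out)
}

## snap a list of polygons to a shared vertex table; returns
## list(vertices = data.frame(id, x, y), cells = named list of id cycles)
snapToVertexTable <- function(polys, tol = 1e-6) {
  allpts <- do.call(rbind, polys)
  key <- paste(round(allpts[, 1] / tol), round(allpts[, 2] / tol))
  uk <- !duplicated(key)
  ids <- seq_len(sum(uk))
  lookup <- stats::setNames(ids, key[uk])
  verts <- data.frame(id = ids, x = allpts[uk, 1], y = allpts[uk, 2])
  off <- 0
  cells <- lapply(polys, function(p) {
    k <- paste(round(p[, 1] / tol), round(p[, 2] / tol))
    vv <- unname(lookup[k])
    vv[!duplicated(vv)]          # drop snap-collapsed duplicates
  })
  list(vertices = verts, cells = cells)
}

#' Generate the initial tessellation
#'
#' Centroidal Voronoi tessellation of the leaf-shaped domain: seeds sampled
#' uniformly, relaxed by Lloyd iterations, clipped to the domain, with a
#' shared junction table.  Deterministic given the seed.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param time observation time assigned to the tessellation (DAI).
#' @return a \linkS4class{SegmentedTimepoint}.
#' @export
generateTessellation <- function(config, time = 3) {
  domain <- leafDomain(config)
  n <- as.integer(config@nCellsInit)
  if (polyArea(domain) / n < 1)
    stop("domain too small for ", n, " cells")
  set.seed(as.integer(config@seed))
  if (n == 1) {
    st <- snapToVertexTable(list(domain))
    names(st$cells) <- "c1"
    return(segmentedTimepoint(time, st$vertices, st$cells))
  }
  seeds <- samplePointsInPolygon(n, domain)
  for (it in seq_len(config@lloydIters)) {
    cells <- boundedVoronoi(seeds, domain)
    seeds <- t(vapply(cells, polyCentroid, c(0, 0)))
  }
  cells <- boundedVoronoi(seeds, domain)
  cells <- lapply(cells, ensureCCW)
  st <- snapToVertexTable(cells)
  names(st$cells) <- sprintf("c%04d", seq_len(n))
  segmentedTimepoint(time, st$vertices, st$cells)
}

## per-axis linear growth factors of the programmed field at (x, y)
fieldFactors <- function(field, x, y, dt, config) {
  switch(field$type,
    uniform = {
      f <- sqrt(1 + field$rate * dt)
      cbind(fx = rep(f, length(x)), fy = rep(f, length(x)))
    },
    basipetal = {
      L <- config@domainLength
      zone <- field$zone * L
      g <- ifelse(y < zone, 1 - (1 - field$floor) * y / zone, field$floor)
      f <- sqrt(1 + field$rate * g * dt)
      cbind(fx = f, fy = f)
    },
    tissue = {
      hw <- field$midribFrac * config@bladeWidth / 2
      mid <- abs(x) <= hw
      ## tissue rates are per-axis linear extension rates
      fxm <- 1 + field$midribRatePerp * dt
      fym <- 1 + field$midribRatePar * dt
      fb <- 1 + field$bladeRate * dt
      cbind(fx = ifelse(mid, fxm, fb), fy = ifelse(mid, fym, fb))
    },
    custom = field$fun(x, y, dt),
    stop("unknown growth field type: ", field$type))
}

## move junctions through the programmed field over one interval.
## Uniform and basipetal fields use a globally integrable map (the
## basipetal y-coordinate integrates the local stretch so vertical strain
## matches the local factor); the tissue field uses the per-cell local
## affine averaged over each junction's incident cells, so region cores
## deform exactly by their programmed tensor.
moveJunctions <- function(tp, field, dt, config) {
  verts <- tp@vertices
  if (field$type %in% c("uniform", "custom")) {
    vf <- fieldFactors(field, verts$x, verts$y, dt, config)
    verts$x <- verts$x * vf[, 1]
    verts$y <- verts$y * vf[, 2]
  } else if (field$type == "basipetal") {
    vf <- fieldFactors(field, verts$x, verts$y, dt, config)
    verts$x <- verts$x * vf[, 1]
    ## integrate the stretch along y so dY/dy = f(y) pointwise
    ys <- seq(0, max(verts$y) * 1.001, length.out = 512)
    fy <- fieldFactors(field, rep(0, 512), ys, dt, config)[, 2]
    Y <- c(0, cumsum((fy[-1] + fy[-512]) / 2 * diff(ys)))
    verts$y <- stats::approx(ys, Y, xout = verts$y, rule = 2)$y
  } else {
    cents <- t(vapply(cellPolygons(tp), polyCentroid, c(0, 0)))
    ff <- fieldFactors(field, cents[, 1], cents[, 2], dt, config)
    predX <- numeric(nrow(verts)); predY <- numeric(nrow(verts))
    cnt <- numeric(nrow(verts))
    idx <- match(unlist(tp@cells, use.names = FALSE), verts$id)
    ci <- rep(seq_along(tp@cells), lengths(tp@cells))
    for (k in seq_along(idx)) {
      i <- idx[k]; cc <- ci[k]
      predX[i] <- predX[i] + verts$x[i] * ff[cc, 1]
      predY[i] <- predY[i] + verts$y[i] * ff[cc, 2]
      cnt[i] <- cnt[i] + 1
    }
    keep <- cnt > 0
    verts$x[keep] <- predX[keep] / cnt[keep]
    verts$y[keep] <- predY[keep] / cnt[keep]
  }
  verts
}

## true region label from position (geometry-based, field-independent)
trueRegion <- function(config, x, y) {
  hw <- (if (!is.null(config@growthField$midribFrac))
    config@growthField$midribFrac else 0.2) * config@bladeWidth / 2
  ifelse(abs(x) <= hw, "midrib_petiole", "blade")
}

## divide cell `cid` of the tessellation by the shortest wall through the
## centroid (with orientation jitter), updating the shared vertex table and
## the neighbour cycles.  Returns the updated list(vertices, cells) plus the
## two child ids.
divideCellById <- function(verts, cells, cid, jitterSD, newIds) {
  vv <- cells[[cid]]
  i <- match(vv, verts$id)
  P <- cbind(verts$x[i], verts$y[i])
  cen <- polyCentroid(P)
  ## shortest wall through the centroid over candidate angles
  angs <- seq(0, pi, length.out = 25)[-25]
  wall <- vapply(angs, function(a) {
    sp <- splitPolygonByLine(P, cen, a)
    if (is.null(sp)) return(Inf)
    sum((sp$cuts[1, 1:2] - sp$cuts[2, 1:2])^2)
  }, 0)
  if (all(!is.finite(wall))) return(NULL)
  a <- angs[which.min(wall)] + stats::rnorm(1, 0, jitterSD)
  sp <- splitPolygonByLine(P, cen, a)
  if (is.null(sp)) sp <- splitPolygonByLine(P, cen, angs[which.min(wall)])
  if (is.null(sp)) return(NULL)
  ## register the two cut points as new vertices
  nid <- max(verts$id) + 1:2
  verts <- rbind(verts, data.frame(id = nid, x = sp$cuts[, 1], y = sp$cuts[, 2]))
  ## rebuild the two child cycles in terms of vertex ids, walking the ring
  n <- length(vv)
  dirv <- c(cos(a), sin(a)); nrm <- c(-dirv[2], dirv[1])
  s <- as.vector((P - matrix(cen, n, 2, byrow = TRUE)) %*% nrm)
  ca <- integer(0); cb <- integer(0)
  for (k in seq_len(n)) {
    if (s[k] <= 0) ca <- c(ca, vv[k]) else cb <- c(cb, vv[k])
    kk <- which(sp$cuts[, 3] == k)
    if (length(kk) == 1) { ca <- c(ca, nid[kk]); cb <- c(cb, nid[kk]) }
  }
  ## insert the cut vertices into neighbours sharing the cut edges
  for (k in 1:2) {
    e <- sp$cuts[k, 3]
    a1 <- vv[e]; a2 <- vv[if (e == n) 1 else e + 1]
    for (oc in names(cells)) {
      if (oc == cid) next
      w <- cells[[oc]]
      m <- length(w)
      for (q in seq_len(m)) {
        r <- if (q == m) 1 else q + 1
        if ((w[q] == a1 && w[r] == a2) || (w[q] == a2 && w[r] == a1)) {
          cells[[oc]] <- append(w, nid[k], after = q)
          break
        }
      }
    }
  }
  cells[[cid]] <- NULL
  cells[[newIds[1]]] <- ca
  cells[[newIds[2]]] <- cb
  list(vertices = verts, cells = cells)
}

#' Advance a synthetic tessellation by one interval
#'
#' Applies the programmed growth field to the junctions, divides cells
#' exceeding the area threshold by the shortest (jittered) wall through
#' their centroid, and records the ground truth of the interval.  Junction
#' noise is \emph{not} added here (see \code{\link{makeTimelapse}}); truth
#' is recorded pre-noise by construction.
#'
#' @param tp a \linkS4class{SegmentedTimepoint} (noise-free).
#' @param config a \linkS4class{SynthConfig}.
#' @param idCounter integer; cell ids for new daughters start here.
#' @return list with elements \code{tp} (next noise-free timepoint),
#'   \code{lineage} (a \linkS4class{LineageMap}), \code{truth} (per-cell
#'   data.frame of programmed extension/anisotropy/orientation/region) and
#'   \code{idCounter}.
#' @export
advanceTessellation <- function(tp, config, idCounter = 1L) {
  dt <- config@dtDays
  field <- config@growthField
  verts <- tp@vertices
  cents <- t(vapply(cellPolygons(tp), polyCentroid, c(0, 0)))

  ## programmed truth at cell centroids, pre-move
  ff <- fieldFactors(field, cents[, 1], cents[, 2], dt, config)
  kmax <- pmax(ff[, 1], ff[, 2]); kmin <- pmin(ff[, 1], ff[, 2])
  truth <- data.frame(
    cell = cellIds(tp), t_from = tp@time, t_to = tp@time + dt,
    extension_pct = 100 * (ff[, 1] * ff[, 2] - 1),
    ratio = kmax / kmin,
    pct = 100 * (1 - kmin / kmax),
    orientation = ifelse(kmax / kmin < 1 + 1e-12, NA_real_,
                         ifelse(ff[, 2] >= ff[, 1], 90, 0)),
    region = trueRegion(config, cents[, 1], cents[, 2]),
    row.names = NULL, stringsAsFactors = FALSE)

  ## move junctions through the field map
  verts <- moveJunctions(tp, field, dt, config)

  cells <- tp@cells
  next_tp <- segmentedTimepoint(tp@time + dt, verts, cells, sample = tp@sample)

  ## divisions (one per over-threshold cell per interval)
  parentOf <- stats::setNames(names(cells), names(cells))
  areas <- vapply(cellPolygons(next_tp), polyArea, 0)
  toDivide <- names(cells)[areas > config@divisionArea]
  st <- list(vertices = verts, cells = cells)
  for (cid in toDivide) {
    ids <- sprintf("c%04d", idCounter + 0:1)
    res <- divideCellById(st$vertices, st$cells, cid,
                          config@divisionJitterSD, ids)
    if (is.null(res)) next
    st <- res
    idCounter <- idCounter + 2L
    parentOf <- parentOf[names(parentOf) != cid]
    parentOf[ids] <- cid
  }
  out_tp <- segmentedTimepoint(tp@time + dt, st$vertices, st$cells,
                               sample = tp@sample)
  truth$proliferation <- as.integer(table(factor(parentOf,
                                                 levels = truth$cell)))
  list(tp = out_tp,
       lineage = lineageMap(tp@time, tp@time + dt, parentOf),
       truth = truth, idCounter = idCounter)
}

#' Generate a full synthetic time-lapse
#'
#' Iterates \code{\link{advanceTessellation}} over the configured number of
#' daily observations, then applies junction noise to the emitted series
#' (ground truth and the internal state stay noise-free).
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return list with \code{series} (emitted, noisy if
#'   \code{junctionNoiseSD > 0}), \code{cleanSeries} (noise-free),
#'   \code{lineages} (list of \linkS4class{LineageMap}), \code{truth}
#'   (row-bound per-interval per-cell truth data.frame).
#' @export
makeTimelapse <- function(config) {
  tp <- generateTessellation(config)
  clean <- list(tp)
  lineages <- list()
  truths <- list()
  counter <- as.integer(config@nCellsInit) + 1L
  for (k in seq_len(config@nTimepoints - 1)) {
    step <- advanceTessellation(tp, config, idCounter = counter)
    tp <- step$tp
    counter <- step$idCounter
    clean[[k + 1]] <- tp
    lineages[[k]] <- step$lineage
    truths[[k]] <- step$truth
  }
  series <- clean
  if (config@junctionNoiseSD > 0) {
    series <- lapply(clean, function(s) {
      v <- s@vertices
      v$x <- v$x + stats::rnorm(nrow(v), 0, config@junctionNoiseSD)
      v$y <- v$y + stats::rnorm(nrow(v), 0, config@junctionNoiseSD)
      segmentedTimepoint(s@time, v, s@cells, s@attrs, s@sample)
    })
  }
  list(series = series, cleanSeries = clean, lineages = lineages,
       truth = do.call(rbind, truths))
}
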