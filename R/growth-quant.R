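## Cell-resolution growth quantification for segmented time-lapse tissues:
## area extension, growth-anisotropy tensors from matched junctions,
## lobeyness, lineage algebra, proximodistal alignment graphs, region
## classification (fate maps) and protrusion triangle metrics.

#' Per-lineage area extension
#'
#' For each cell at the earlier time, the percent area increase of its
#' clonal lineage over the interval:
#' \code{100 * (sum of daughter areas - parent area) / parent area}.
#'
#' @param t0,t1 \linkS4class{SegmentedTimepoint} objects at the interval
#'   endpoints.
#' @param lin a \linkS4class{LineageMap} spanning \code{(t0, t1)}.
#' @return data.frame with columns \code{cell} (t0 cell id),
#'   \code{area_t0}, \code{area_t1}, \code{extension_pct},
#'   \code{proliferation} (daughter count).
#' @export
areaExtension <- function(t0, t1, lin) {
  if (abs(lin@tFrom - t0@time) > 1e-9 || abs(lin@tTo - t1@time) > 1e-9)
    stop(sprintf("lineage spans (%g, %g) but timepoints are (%g, %g)",
                 lin@tFrom, lin@tTo, t0@time, t1@time))
  par <- parentMap(lin)
  bad <- setdiff(names(par), cellIds(t1))
  if (length(bad))
    stop("lineage children missing from t1: ", paste(bad, collapse = ", "))
  orphan <- setdiff(unique(par), cellIds(t0))
  if (length(orphan))
    stop("children without geometric parent at t0: ",
         paste(orphan, collapse = ", "))
  a0 <- vapply(cellPolygons(t0), polyArea, 0)
  a1 <- vapply(cellPolygons(t1), polyArea, 0)
  byPar <- split(a1[names(par)], par)
  cells <- cellIds(t0)
  sumA <- vapply(cells, function(cid) {
    v <- byPar[[cid]]
    if (is.null(v)) NA_real_ else sum(v)
  }, 0)
  nDau <- vapply(cells, function(cid) {
    v <- byPar[[cid]]
    if (is.null(v)) 0L else length(v)
  }, 0L)
  data.frame(cell = cells, area_t0 = as.numeric(a0[cells]),
             area_t1 = as.numeric(sumA),
             extension_pct = 100 * (sumA - a0[cells]) / a0[cells],
             proliferation = nDau, row.names = NULL,
             stringsAsFactors = FALSE)
}

## coordinates of a set of vertex ids in a timepoint
vertexCoords <- function(tp, ids) {
  i <- match(ids, tp@vertices$id)
  cbind(tp@vertices$x[i], tp@vertices$y[i])
}

#' Per-cell growth anisotropy from matched junctions
#'
#' For each cell at the earlier time, fits the best linear deformation F
#' (least squares over matched junction displacements between the cell's
#' junctions at t0 and the same junctions, identified by id, at t1), and
#' reports the principal stretches of F: the anisotropy ratio kmax/kmin,
#' the percentage \code{100 * (1 - kmin/kmax)} and the orientation of the
#' maximal principal direction in degrees in [0, 180).  Cells with fewer
#' than 3 non-collinear matched junctions are flagged, not dropped.
#'
#' @inheritParams areaExtension
#' @return data.frame with columns \code{cell}, \code{kmax}, \code{kmin},
#'   \code{ratio}, \code{pct}, \code{orientation}, \code{n_junctions},
#'   \code{ok}.  Isotropic deformations report \code{orientation = NA}.
#' @export
growthAnisotropy <- function(t0, t1, lin) {
  par <- parentMap(lin)
  v1ids <- t1@vertices$id
  cells <- cellIds(t0)
  rows <- lapply(cells, function(cid) {
    vv <- t0@cells[[cid]]
    m <- vv[vv %in% v1ids]
    res <- data.frame(cell = cid, kmax = NA_real_, kmin = NA_real_,
                      ratio = NA_real_, pct = NA_real_,
                      orientation = NA_real_,
                      n_junctions = length(m), ok = FALSE,
                      stringsAsFactors = FALSE)
    if (length(m) < 3) return(res)
    p0 <- vertexCoords(t0, m)
    p1 <- vertexCoords(t1, m)
    ## collinearity guard
    c0 <- sweep(p0, 2, colMeans(p0))
    if (svd(c0)$d[2] < 1e-9 * max(svd(c0)$d[1], 1e-12)) return(res)
    fit <- fitAffine(p0, p1)
    ps <- principalStretches(fit$F)
    ratio <- ps$kmax / ps$kmin
    res$kmax <- ps$kmax; res$kmin <- ps$kmin
    res$ratio <- ratio
    res$pct <- 100 * (1 - ps$kmin / ps$kmax)
    res$orientation <- if (ratio < 1 + 1e-9) NA_real_ else ps$orientation
    res$ok <- TRUE
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## simple O(n^2) self-intersection test for a polygon
polySelfIntersects <- function(xy) {
  n <- nrow(xy)
  jn <- c(2:n, 1)
  segInt <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # closing edge shares vertex 1
      if (segInt(xy[i, ], xy[jn[i], ], xy[j, ], xy[jn[j], ])) return(TRUE)
    }
  }
  FALSE
}

#' Lobeyness of a cell polygon
#'
#' Pavement-cell waviness: the ratio of the cell's perimeter to the
#' perimeter of its convex hull (the smallest convex shape containing the
#' cell).  Equals 1 exactly for convex cells.
#'
#' @param poly n x 2 matrix of polygon vertices in order (um).
#' @return dimensionless value >= 1.
#' @export
lobeyness <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  if (polySelfIntersects(poly)) stop("self-intersecting polygon")
  polyPerimeter(poly) / convexHullPerimeter(poly)
}

#' Compose lineage maps across consecutive intervals
#'
#' Functional composition of child-to-parent maps: links daily parent
#' relations into lineage relations over longer periods.
#'
#' @param maps list of \linkS4class{LineageMap} objects whose intervals
#'   chain (each map's \code{tTo} equals the next map's \code{tFrom}).
#' @return a \linkS4class{LineageMap} spanning the full period.
#' @export
composeLineages <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (length(maps) == 1) return(maps[[1]])
  for (i in seq_len(length(maps) - 1)) {
    if (abs(maps[[i]]@tTo - maps[[i + 1]]@tFrom) > 1e-9)
      stop(sprintf("broken lineage chain: map %d ends at %g, map %d starts at %g",
                   i, maps[[i]]@tTo, i + 1, maps[[i + 1]]@tFrom))
  }
  acc <- maps[[1]]@parentOf
  for (i in seq(2, length(maps))) {
    nxt <- maps[[i]]@parentOf
    composed <- acc[nxt]
    names(composed) <- names(nxt)
    if (anyNA(composed))
      stop("lineage children with no ancestor at the first time: ",
           paste(names(nxt)[is.na(composed)], collapse = ", "))
    acc <- composed
  }
  lineageMap(maps[[1]]@tFrom, maps[[length(maps)]]@tTo, acc)
}

## ---------------------------------------------------------------------------
## tessellation boundary and midline helpers
## ---------------------------------------------------------------------------

## Ordered outer boundary of a tessellation: vertex-id cycle of the edges
## that belong to exactly one cell.
tessellationBoundary <- function(tp) {
  edges <- list()
  for (cid in names(tp@cells)) {
    vv <- tp@cells[[cid]]
    j <- c(seq_along(vv)[-1], 1L)
    edges[[cid]] <- cbind(vv, vv[j])
  }
  em <- do.call(rbind, edges)
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  cnt <- table(key)
  outer <- em[cnt[key] == 1, , drop = FALSE]
  if (!nrow(outer)) stop("tessellation has no boundary")
  ## chain the directed boundary edges
  nxt <- outer[, 2]; names(nxt) <- as.character(outer[, 1])
  start <- outer[1, 1]
  cyc <- integer(nrow(outer))
  cur <- start
  for (i in seq_len(nrow(outer))) {
    cyc[i] <- cur
    cur <- nxt[[as.character(cur)]]
    if (is.null(cur)) stop("boundary is not a closed cycle")
  }
  cyc
}

## cells owning at least one boundary edge
boundaryCells <- function(tp) {
  b <- tessellationBoundary(tp)
  bk <- paste(pmin(b, c(b[-1], b[1])), pmax(b, c(b[-1], b[1])))
  owns <- vapply(names(tp@cells), function(cid) {
    vv <- tp@cells[[cid]]
    j <- c(seq_along(vv)[-1], 1L)
    any(paste(pmin(vv, vv[j]), pmax(vv, vv[j])) %in% bk)
  }, TRUE)
  names(tp@cells)[owns]
}

## Piecewise-linear midline of a tessellation: band midpoints along the
## principal axis of the junction cloud, ordered proximal (base, min
## projection) to distal.  An approximation of the outline medial axis
## adequate for proximodistal coordinates.
tessellationMidline <- function(tp, nBands = 20) {
  P <- cbind(tp@vertices$x, tp@vertices$y)
  mu <- colMeans(P)
  ax <- svd(sweep(P, 2, mu))$v[, 1]
  if (ax[2] < 0) ax <- -ax   # orient distally (+y convention)
  s <- as.vector(sweep(P, 2, mu) %*% ax)
  br <- seq(min(s), max(s), length.out = nBands + 1)
  mids <- t(vapply(seq_len(nBands), function(k) {
    inb <- s >= br[k] & s <= br[k + 1]
    if (!any(inb)) return(c(NA_real_, NA_real_))
    colMeans(P[inb, , drop = FALSE])
  }, c(0, 0)))
  mids <- mids[stats::complete.cases(mids), , drop = FALSE]
  mids
}

## proximodistal arc coordinate of points, via projection on the midline
pdCoordinate <- function(pts, midline) {
  seg <- diff(midline)
  s0 <- c(0, cumsum(sqrt(rowSums(seg^2))))
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    best <- Inf; arc <- 0
    for (k in seq_len(nrow(midline) - 1)) {
      a <- midline[k, ]; d <- seg[k, ]
      L2 <- sum(d^2)
      t <- if (L2 > 0) max(0, min(1, sum((p - a) * d) / L2)) else 0
      q <- a + t * d
      dd <- sum((p - q)^2)
      if (dd < best) { best <- dd; arc <- s0[k] + t * sqrt(L2) }
    }
    arc
  }, 0)
}

#' Midline arc length of a tessellation or outline
#'
#' Arc length of the proximodistal midline (band midpoints along the
#' principal axis), the organ-length measure used for calibration.
#'
#' @param x a \linkS4class{SegmentedTimepoint}, a \linkS4class{TissueState},
#'   or an n x 2 outline matrix.
#' @param nBands number of bands used to trace the midline.
#' @return midline length (um).
#' @export
midlineLength <- function(x, nBands = 20) {
  P <- if (is(x, "SegmentedTimepoint")) cbind(x@vertices$x, x@vertices$y)
  else if (is(x, "TissueState")) x@vertices
  else as.matrix(x)
  mu <- colMeans(P)
  ax <- svd(sweep(P, 2, mu))$v[, 1]
  s <- as.vector(sweep(P, 2, mu) %*% ax)
  br <- seq(min(s), max(s), length.out = nBands + 1)
  mids <- t(vapply(seq_len(nBands), function(k) {
    inb <- s >= br[k] & s <= br[k + 1]
    if (!any(inb)) return(c(NA_real_, NA_real_))
    colMeans(P[inb, , drop = FALSE])
  }, c(0, 0)))
  mids <- mids[stats::complete.cases(mids), , drop = FALSE]
  polylineLength(mids)
}

## ---------------------------------------------------------------------------
## alignment graphs
## ---------------------------------------------------------------------------

#' Growth alignment graph
#'
#' Bins the cells of the reference (earliest) time point along the
#' proximodistal axis into equal-count bins and profiles a growth measure
#' per bin: the developmental-biology analogue of a sequence alignment,
#' used to compare genotypes stage-for-stage.
#'
#' @param series list of \linkS4class{SegmentedTimepoint} objects in time
#'   order; the first is the reference, the last the final time.
#' @param lineages list of \linkS4class{LineageMap} objects chaining
#'   reference to final.
#' @param measure \code{"area_extension"} (% over the whole interval),
#'   \code{"proliferation"} (descendant count) or \code{"contribution"}
#'   (percent of final tissue area descended from the bin; bin values sum
#'   to 100).
#' @param nBins number of equal-count bins (default 10: each bin holds 10%
#'   of reference-time cells).
#' @param distanceMode \code{"arc_um"} (arc distance from the base along
#'   the midline) or \code{"cell_number"} (adjacency-graph hop count from
#'   the basal cell row).
#' @return data.frame with one row per bin: \code{bin}, \code{n},
#'   \code{pd_lo}, \code{pd_hi}, \code{value}, \code{sem}; the measure and
#'   mode are attached as attributes.
#' @export
alignmentGraph <- function(series, lineages, measure = c("area_extension",
                           "proliferation", "contribution"),
                           nBins = 10,
                           distanceMode = c("arc_um", "cell_number")) {
  measure <- match.arg(measure)
  distanceMode <- match.arg(distanceMode)
  ref <- series[[1]]; fin <- series[[length(series)]]
  lin <- composeLineages(lineages)
  cells <- cellIds(ref)
  cent <- t(vapply(cellPolygons(ref), polyCentroid, c(0, 0)))

  pd <- if (distanceMode == "arc_um") {
    ml <- tessellationMidline(ref)
    pdCoordinate(cent, ml)
  } else {
    ## hop distance from the basal cell layer through the adjacency graph
    adj <- adjacency(ref)
    nbr <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
    ml <- tessellationMidline(ref)
    arc <- pdCoordinate(cent, ml)
    base <- cells[arc <= stats::quantile(arc, 0.05)]
    dist <- stats::setNames(rep(Inf, length(cells)), cells)
    dist[base] <- 0
    frontier <- base
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    as.numeric(dist[cells])
  }
  bad <- !is.finite(pd)
  if (any(bad)) {
    warning("excluding ", sum(bad), " cell(s) lacking a P-D coordinate: ",
            paste(cells[bad], collapse = ", "))
    cells <- cells[!bad]; pd <- pd[!bad]
  }

  ext <- areaExtension(ref, fin, lin)
  vals <- switch(measure,
    area_extension = stats::setNames(ext$extension_pct, ext$cell),
    proliferation = stats::setNames(as.numeric(ext$proliferation), ext$cell),
    contribution = {
      aFin <- vapply(cellPolygons(fin), polyArea, 0)
      byPar <- vapply(cells, function(cid) {
        ch <- names(parentMap(lin))[parentMap(lin) == cid]
        sum(aFin[ch])
      }, 0)
      100 * byPar / sum(vapply(cellPolygons(fin), polyArea, 0))
    })
  vals <- vals[cells]

  ord <- order(pd)
  rk <- integer(length(cells)); rk[ord] <- seq_along(cells)
  bin <- ceiling(rk * nBins / length(cells))
  rows <- lapply(seq_len(nBins), function(b) {
    inb <- bin == b
    v <- vals[inb]
    data.frame(bin = b, n = sum(inb),
               pd_lo = min(pd[inb]), pd_hi = max(pd[inb]),
               value = if (measure == "contribution") sum(v) else mean(v),
               sem = if (measure == "contribution" || sum(inb) < 2) NA_real_
                     else stats::sd(v) / sqrt(sum(inb)))
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- measure
  attr(out, "distance_mode") <- distanceMode
  out
}

## ---------------------------------------------------------------------------
## region classification (fate maps)
## ---------------------------------------------------------------------------

## aspect ratio of a polygon from the principal-component spread of its
## densified boundary
polyAspect <- function(xy) {
  b <- resamplePolyline(rbind(xy, xy[1, , drop = FALSE]),
                        polyPerimeter(xy) / 40)
  sv <- svd(sweep(b, 2, colMeans(b)))$d
  sv[1] / max(sv[2], 1e-12)
}

#' Classify blade, midrib/petiole and sinus regions
#'
#' Labels final-time cells as midrib/petiole versus blade by thresholds on
#' cell elongation and lineage proliferation, pulls the labels back to the
#' reference time through the lineage, marks the slow-growing sinus cells
#' between detected protrusions at the reference time, and pushes the sinus
#' labels forward to the final time.
#'
#' @inheritParams alignmentGraph
#' @param thresholds list with elements \code{aspect} (elongation threshold,
#'   default 2.5), \code{prolifQuantile} (proliferation at or below this
#'   quantile is midrib-like, default 0.5), \code{growthDecile} (sinus cells
#'   lie in this lowest extension quantile, default 0.1) and
#'   \code{prominence} (protrusion detection prominence on the outline, um).
#' @return data.frame with columns \code{time}, \code{cell}, \code{region}
#'   (\code{"blade"}, \code{"midrib_petiole"}, \code{"sinus"} or
#'   \code{"unassigned"}) covering the reference and final times.
#' @export
classifyRegions <- function(series, lineages,
                            thresholds = list()) {
  thr <- utils::modifyList(list(aspect = 2.5, prolifQuantile = 0.5,
                                growthDecile = 0.1, prominence = 4),
                           thresholds)
  ref <- series[[1]]; fin <- series[[length(series)]]
  lin <- composeLineages(lineages)
  par <- parentMap(lin)
  ext <- areaExtension(ref, fin, lin)
  prolif <- stats::setNames(ext$proliferation, ext$cell)

  ## 1) label clone sectors at the final time: each reference cell's clone
  ##    (the merged outline of its descendants) is midrib/petiole-like when
  ##    elongated with below-median proliferation; division planes reset
  ##    per-cell aspect, so elongation is read off the clone outline
  finPolys <- cellPolygons(fin)
  aFin <- vapply(finPolys, polyArea, 0)
  pm <- stats::quantile(prolif, thr$prolifQuantile, na.rm = TRUE)
  refLab <- vapply(cellIds(ref), function(cid) {
    ch <- names(par)[par == cid]
    if (!length(ch)) return("unassigned")
    cl <- cloneOutline(fin, ch)
    if (is.null(cl)) return("unassigned")
    if (polyAspect(cl) > thr$aspect && prolif[cid] <= pm)
      "midrib_petiole" else "blade"
  }, "")

  ## 2) final cells inherit their clone's label (the pullback to the
  ##    reference time is the identity on clones)
  finLab <- refLab[par[cellIds(fin)]]
  names(finLab) <- cellIds(fin)
  finLab[is.na(par[cellIds(fin)])] <- "unassigned"

  ## 3) sinus cells: margin-adjacent reference cells in the slowest-growth
  ##    decile, lying between protrusion tips on the final outline
  bnd <- boundaryCells(ref)
  extv <- stats::setNames(ext$extension_pct, ext$cell)
  slow <- bnd[extv[bnd] <= stats::quantile(extv, thr$growthDecile, na.rm = TRUE)]
  tips <- character(0)
  o <- tessellationBoundary(fin)
  ov <- vertexCoords(fin, o)
  prot <- outlineProtrusionIdx(ov, prominence = thr$prominence)
  if (length(prot$tips)) {
    ## final boundary cells at the tips, mapped back to reference
    tipPts <- ov[prot$tips, , drop = FALSE]
    finB <- boundaryCells(fin)
    centF <- t(vapply(cellPolygons(fin, finB), polyCentroid, c(0, 0)))
    tipCells <- finB[apply(tipPts, 1, function(q)
      which.min(colSums((t(centF) - q)^2)))]
    tips <- unique(par[tipCells])
  }
  sinus <- character(0)
  if (length(tips) >= 2 && length(slow)) {
    ## order boundary cells along the reference margin path
    bref <- tessellationBoundary(ref)
    bv <- vertexCoords(ref, bref)
    centB <- t(vapply(cellPolygons(ref, bnd), polyCentroid, c(0, 0)))
    pos <- apply(centB, 1, function(q)
      which.min(colSums((t(bv) - q)^2)))
    names(pos) <- bnd
    tpos <- sort(pos[tips[tips %in% bnd]])
    if (length(tpos) >= 2) {
      sinus <- slow[vapply(slow, function(cid) {
        q <- pos[cid]
        any(q > tpos[-length(tpos)] & q < tpos[-1])
      }, TRUE)]
    }
  }
  refLab[sinus] <- "sinus"
  ## 4) push sinus labels forward
  finLab[names(par)[par %in% sinus]] <- "sinus"

  rbind(data.frame(time = ref@time, cell = cellIds(ref), region = refLab,
                   row.names = NULL, stringsAsFactors = FALSE),
        data.frame(time = fin@time, cell = cellIds(fin), region = finLab,
                   row.names = NULL, stringsAsFactors = FALSE))
}

## merged outline of a set of cells (a clone sector): edges used exactly
## once within the set, chained into the largest cycle
cloneOutline <- function(tp, ids) {
  em <- do.call(rbind, lapply(ids, function(cid) {
    vv <- tp@cells[[cid]]
    j <- c(seq_along(vv)[-1], 1L)
    cbind(vv, vv[j])
  }))
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  cnt <- table(key)
  outer <- em[cnt[key] == 1, , drop = FALSE]
  if (nrow(outer) < 3) return(NULL)
  nxt <- stats::setNames(outer[, 2], as.character(outer[, 1]))
  used <- stats::setNames(rep(FALSE, nrow(outer)), as.character(outer[, 1]))
  best <- NULL
  for (s in outer[, 1]) {
    if (used[[as.character(s)]]) next
    cyc <- integer(0); cur <- s
    repeat {
      cyc <- c(cyc, cur)
      used[as.character(cur)] <- TRUE
      cur <- nxt[[as.character(cur)]]
      if (is.null(cur) || is.na(cur)) break
      if (cur == s) break
      if (length(cyc) > nrow(outer)) break
    }
    if (is.null(best) || length(cyc) > length(best)) best <- cyc
  }
  if (length(best) < 3) return(NULL)
  vertexCoords(tp, best)
}

## curvature-based protrusion landmarks on a closed outline polygon;
## returns indices of tips (curvature maxima above prominence) and sinuses
outlineProtrusionIdx <- function(ov, prominence = 4) {
  n <- nrow(ov)
  ## signed turning angle per unit length, smoothed
  prv <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n - 1) + 1, 1)
  e1 <- ov - ov[prv, , drop = FALSE]
  e2 <- ov[nxt, , drop = FALSE] - ov
  ang <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1],
               rowSums(e1 * e2))
  len <- (sqrt(rowSums(e1^2)) + sqrt(rowSums(e2^2))) / 2
  kap <- ang / pmax(len, 1e-9)
  ks <- stats::filter(c(kap, kap, kap), rep(1 / 5, 5), circular = FALSE)
  ks <- as.numeric(ks[(n + 1):(2 * n)])
  ## protrusion tips: strong convex curvature peaks away from the base
  pk <- findPeaks(c(ks, ks[1]), prominence = prominence * stats::sd(ks))
  pk <- pk[pk <= n]
  list(tips = pk, curvature = ks)
}

## ---------------------------------------------------------------------------
## protrusion triangle
## ---------------------------------------------------------------------------

#' Protrusion triangle metrics
#'
#' Approximates a marginal protrusion by the triangle (proximal sinus, tip,
#' distal sinus): base width is the distance between the sinuses, length
#' the distance from the tip to the base segment (the triangle height), and
#' asymmetry the absolute difference between the left and right edge
#' lengths.
#'
#' @param outline n x 2 matrix: the outline polyline (um).
#' @param landmarks integer length-3 vector of row indices
#'   (proximal sinus, tip, distal sinus); if \code{NULL} the most prominent
#'   protrusion is auto-detected from the curvature profile.
#' @return named numeric vector \code{c(base_width, length, asymmetry)}.
#' @export
protrusionTriangle <- function(outline, landmarks = NULL) {
  outline <- as.matrix(outline)
  if (is.null(landmarks)) {
    det <- outlineProtrusionIdx(outline)
    if (!length(det$tips)) {
      stop("no protrusion detected; curvature profile: ",
           paste(sprintf("%.3g", det$curvature), collapse = " "))
    }
    tip <- det$tips[which.max(det$curvature[det$tips])]
    tr <- findPeaks(-det$curvature, prominence = 0)
    lo <- tr[tr < tip]; hi <- tr[tr > tip]
    if (!length(lo) || !length(hi))
      stop("protrusion landmarks incomplete; curvature profile: ",
           paste(sprintf("%.3g", det$curvature), collapse = " "))
    landmarks <- c(max(lo), tip, min(hi))
  }
  s1 <- outline[landmarks[1], ]
  tp <- outline[landmarks[2], ]
  s2 <- outline[landmarks[3], ]
  base <- s2 - s1
  bw <- sqrt(sum(base^2))
  h <- if (bw > 0) abs(base[1] * (tp[2] - s1[2]) - base[2] * (tp[1] - s1[1])) / bw
       else sqrt(sum((tp - s1)^2))
  asym <- abs(sqrt(sum((tp - s1)^2)) - sqrt(sum((tp - s2)^2)))
  c(base_width = bw, length = h, asymmetry = asym)
}

#' Per-cell growth record table
#'
#' Convenience wrapper combining area extension, proliferation, anisotropy,
#' lobeyness and region labels into one table of per-cell growth records
#' over an interval.
#'
#' @inheritParams areaExtension
#' @param regions optional region label data.frame from
#'   \code{\link{classifyRegions}}.
#' @return data.frame with one row per t0 cell: \code{cell},
#'   \code{extension_pct}, \code{proliferation}, \code{ratio}, \code{pct},
#'   \code{orientation}, \code{lobeyness}, \code{region}.
#' @export
quantifyGrowth <- function(t0, t1, lin, regions = NULL) {
  ext <- areaExtension(t0, t1, lin)
  ani <- growthAnisotropy(t0, t1, lin)
  lob <- vapply(cellPolygons(t0), lobeyness, 0)
  out <- merge(ext[, c("cell", "extension_pct", "proliferation")],
               ani[, c("cell", "ratio", "pct", "orientation")], by = "cell")
  out$lobeyness <- as.numeric(lob[out$cell])
  out$region <- "unassigned"
  if (!is.null(regions)) {
    r0 <- regions[abs(regions$time - t0@time) < 1e-9, ]
    idx <- match(out$cell, r0$cell)
    out$region[!is.na(idx)] <- r0$region[idx[!is.na(idx)]]
  }
  out
}
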