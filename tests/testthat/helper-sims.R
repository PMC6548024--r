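## Memoized tissue simulations shared between test files (each takes a
## couple of minutes), plus the outline/serration statistics used by the
## tissue-level acceptance checks.

.simCache <- new.env(parent = emptyenv())

wildTypeTissueSim <- function() {
  if (is.null(.simCache$wt))
    .simCache$wt <- suppressWarnings(simulateTissue(tissueConfig()))
  .simCache$wt
}

ablatedTissueSim <- function() {
  if (is.null(.simCache$ablated))
    .simCache$ablated <-
      suppressWarnings(simulateTissue(tissueConfig(patterningEnabled = FALSE)))
  .simCache$ablated
}

## marginal protrusion peaks of a closed leaf outline: lateral deviation
## from a smooth (loess) baseline per branch, peaks away from the apex and
## base poles; returns the peak prominences (um)
outlinePeakProminences <- function(ov) {
  n <- nrow(ov); ia <- which.max(ov[, 2]); L <- max(ov[, 2])
  out <- numeric(0)
  for (br in list(ov[1:ia, , drop = FALSE], ov[n:ia, , drop = FALSE])) {
    arc <- c(0, cumsum(sqrt(rowSums(diff(br)^2))))
    lat <- abs(br[, 1])
    base <- tryCatch(stats::predict(stats::loess(lat ~ arc, span = 0.45)),
                     error = function(e) lat)
    dev <- lat - base
    pk <- leafmorph:::findPeaks(dev, prominence = 1)
    pk <- pk[br[pk, 2] > 0.12 * L & br[pk, 2] < 0.88 * L]
    out <- c(out, dev[pk])
  }
  sort(out, decreasing = TRUE)
}

## asymmetry dynamics of the youngest tracked serration: landmarks (tip =
## auxin maximum, sinuses = flanking auxin minima) are fixed as margin
## vertex ids at the first snapshot with full patterning and followed as
## material points; flank lengths are arc lengths along the margin chain
serrationAsymmetry <- function(sim) {
  times <- as.numeric(names(sim$states))
  ref <- NULL
  for (nm in names(sim$states)) {
    if (sum(sim$states[[nm]]@margin$isMax) >= 3) { ref <- nm; break }
  }
  if (is.null(ref)) return(NULL)
  st <- sim$states[[ref]]
  m <- st@margin; mx <- which(m$isMax); nm_ <- nrow(m)
  L <- max(st@vertices[, 2])
  ys <- st@vertices[m$vertex[mx], 2]
  cand <- mx[ys > 0.3 * L & ys < 0.85 * L]
  if (!length(cand)) return(NULL)
  pick <- cand[which.max(st@vertices[m$vertex[cand], 2])]  # youngest
  nextmx <- mx[mx > pick]; prevmx <- mx[mx < pick]
  hi <- if (length(nextmx)) min(nextmx) else min(pick + round(nm_ / 6), nm_)
  lo <- if (length(prevmx)) max(prevmx) else max(pick - round(nm_ / 6), 1)
  iLo <- lo:pick; iHi <- pick:hi
  s1 <- iLo[which.min(m$auxin[iLo])]
  s2 <- iHi[which.min(m$auxin[iHi])]
  ids <- m$vertex[c(s1, pick, s2)]
  ## measure from one snapshot after the maxima appear: at the reference
  ## the auxin pattern has only just converged and the protrusion has no
  ## morphological extent yet
  useTimes <- names(sim$states)[times > as.numeric(ref)]
  rows <- lapply(useTimes, function(nm2) {
    st2 <- sim$states[[nm2]]
    ch <- st2@margin$vertex
    p <- match(ids, ch)
    if (anyNA(p)) return(NULL)
    arcOf <- function(a, b) {
      idx <- ch[min(a, b):max(a, b)]
      sum(sqrt(rowSums(diff(st2@vertices[idx, , drop = FALSE])^2)))
    }
    fp <- arcOf(p[1], p[2]); fd <- arcOf(p[2], p[3])
    data.frame(time = as.numeric(nm2), flank_prox = fp, flank_dist = fd,
               asym = abs(fp - fd), rel = abs(fp - fd) / ((fp + fd) / 2))
  })
  do.call(rbind, rows)
}

## alignment of resultant growth orientations with the radial direction in
## an annulus around the blade-petiole junction, over the last interval
radialAlignment <- function(sim, rInner = 20, rOuter = 120) {
  gr <- sim$growth[[length(sim$growth)]]
  gr <- gr[!is.na(gr$orientation_deg) & gr$ratio > 1.05, ]
  stF <- sim$states[[as.character(gr$t_from[1])]]
  cen <- (stF@vertices[stF@triangles[, 1], ] +
            stF@vertices[stF@triangles[, 2], ] +
            stF@vertices[stF@triangles[, 3], ]) / 3
  jy <- max(cen[stF@tissue == "midrib_petiole", 2])
  d <- sqrt(gr$x^2 + (gr$y - jy)^2)
  ann <- gr[d > rInner & d < rOuter, ]
  if (!nrow(ann)) return(NULL)
  radial <- atan2(ann$y - jy, ann$x) * 180 / pi
  dev <- abs(((ann$orientation_deg - radial) + 90) %% 180 - 90)
  list(n = nrow(ann), medianDev = stats::median(dev),
       spread = diff(range(radial %% 180)))
}
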