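## Accessors, constructors and show() methods for the core classes.

#' Construct a SegmentedTimepoint
#'
#' @param time observation time (DAI).
#' @param vertices data.frame with columns \code{id}, \code{x}, \code{y}.
#' @param cells named list of integer vertex-id vectors in polygon order.
#' @param attrs optional per-cell attribute data.frame with a \code{cell_id}
#'   column.
#' @param sample sample identifier.
#' @return a \linkS4class{SegmentedTimepoint}.
#' @export
segmentedTimepoint <- function(time, vertices, cells,
                               attrs = data.frame(cell_id = character(0)),
                               sample = "synthetic") {
  new("SegmentedTimepoint", time = as.numeric(time),
      vertices = as.data.frame(vertices), cells = cells,
      attrs = as.data.frame(attrs), sample = sample)
}

#' Construct a LineageMap
#'
#' @param tFrom,tTo interval endpoints (DAI).
#' @param parentOf named character vector mapping child cell ids at
#'   \code{tTo} to parent cell ids at \code{tFrom}.
#' @return a \linkS4class{LineageMap}.
#' @export
lineageMap <- function(tFrom, tTo, parentOf) {
  new("LineageMap", tFrom = as.numeric(tFrom), tTo = as.numeric(tTo),
      parentOf = parentOf)
}

#' @rdname timeDai
setMethod("timeDai", "SegmentedTimepoint", function(x) x@time)
#' @rdname timeDai
setMethod("timeDai", "MarginState", function(x) x@time)
#' @rdname timeDai
setMethod("timeDai", "TissueState", function(x) x@time)

#' @rdname cellIds
setMethod("cellIds", "SegmentedTimepoint", function(x) names(x@cells))

#' @rdname nCells
setMethod("nCells", "SegmentedTimepoint", function(x) length(x@cells))

#' @rdname cellPolygons
setMethod("cellPolygons", "SegmentedTimepoint", function(x, ids = NULL) {
  vid <- x@vertices$id
  xs <- x@vertices$x; ys <- x@vertices$y
  idx <- seq_along(vid); names(idx) <- as.character(vid)
  use <- if (is.null(ids)) x@cells else {
    miss <- setdiff(ids, names(x@cells))
    if (length(miss)) stop("unknown cell id(s): ", paste(miss, collapse = ", "))
    x@cells[ids]
  }
  lapply(use, function(vv) {
    k <- idx[as.character(vv)]
    cbind(x = xs[k], y = ys[k])
  })
})

#' @rdname adjacency
setMethod("adjacency", "SegmentedTimepoint", function(x) {
  ## walls are undirected vertex-id pairs; cells sharing a wall are adjacent
  edges <- lapply(names(x@cells), function(cid) {
    vv <- x@cells[[cid]]
    j <- c(seq_along(vv)[-1], 1L)
    a <- pmin(vv, vv[j]); b <- pmax(vv, vv[j])
    data.frame(key = paste(a, b), cell = cid, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)
  sp <- split(edges$cell, edges$key)
  prs <- Filter(function(z) length(z) == 2, sp)
  if (!length(prs)) return(matrix(character(0), 0, 2))
  m <- unique(t(vapply(prs, sort, character(2))))
  dimnames(m) <- NULL
  m
})

#' @rdname parentMap
setMethod("parentMap", "LineageMap", function(x) x@parentOf)

#' @rdname lineageInterval
setMethod("lineageInterval", "LineageMap", function(x) c(x@tFrom, x@tTo))

#' @rdname marginPoints
setMethod("marginPoints", "MarginState", function(x) x@points)

#' @rdname marginLength
setMethod("marginLength", "MarginState", function(x)
  x@points$arc[nrow(x@points)])

setMethod("show", "MarginState", function(object) {
  p <- object@points
  cat(sprintf(paste0("MarginState at %.2f DAI: %d points, length %.1f um, ",
                     "%d convergence point(s), diff front at %.2f\n"),
              object@time, nrow(p), p$arc[nrow(p)], sum(p$isCP),
              object@diffFront))
})

setMethod("show", "MarginParams", function(object) {
  cat(sprintf(paste0("MarginParams: gLong=%.3g/day, growthZone=%.3g um, ",
                     "LThresh=%.3g um, vOut=%.3g um/day, rco=%.2g (%s), ",
                     "t=[%.2g,%.2g] dt=%.3g\n"),
              object@gLong, object@growthZone, object@LThresh, object@vOut,
              object@rcoStrength, object@rcoMode, object@tStart, object@tEnd,
              object@dt))
})

setMethod("show", "TissueState", function(object) {
  cat(sprintf(paste0("TissueState at %.2f DAI: %d vertices, %d triangles ",
                     "(%d differentiated), %d margin cells\n"),
              object@time, nrow(object@vertices), nrow(object@triangles),
              sum(object@differentiated), nrow(object@margin)))
})

setMethod("show", "TissueConfig", function(object) {
  cat(sprintf(paste0("TissueConfig: init %.0fx%.0f um, initiation %.2f-%.2f ",
                     "DAI, tEnd=%.2f, patterning=%s\n"),
              object@initLength, object@initWidth, object@initiationStart,
              object@initiationEnd, object@tEnd, object@patterningEnabled))
})

setMethod("show", "SegmentedTimepoint", function(object) {
  cat(sprintf("SegmentedTimepoint '%s' at %.2f DAI: %d cells, %d junctions\n",
              object@sample, object@time, length(object@cells),
              nrow(object@vertices)))
})

setMethod("show", "LineageMap", function(object) {
  cat(sprintf("LineageMap %.2f -> %.2f DAI: %d children, %d parents\n",
              object@tFrom, object@tTo, length(object@parentOf),
              length(unique(object@parentOf))))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d cells on %.0fx%.0f um domain, field=%s, ",
                     "%d timepoints (dt=%.2g day), noise sd=%.2g um, seed=%d\n"),
              object@nCellsInit, object@domainLength, object@bladeWidth,
              object@growthField$type, object@nTimepoints, object@dtDays,
              object@junctionNoiseSD, as.integer(object@seed)))
})

#' Total tissue area of a tessellation
#'
#' @param x a \linkS4class{SegmentedTimepoint}.
#' @return summed cell area (um^2).
#' @export
tessellationArea <- function(x) {
  sum(vapply(cellPolygons(x), polyArea, 0))
}
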