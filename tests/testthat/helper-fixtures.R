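## Small programmatic fixtures shared across test files.

## a 2 x 2 grid of unit-square cells with shared junctions
gridTessellation <- function(time = 3, nx = 2, ny = 2, size = 10) {
  xs <- seq(0, nx * size, by = size)
  ys <- seq(0, ny * size, by = size)
  verts <- expand.grid(x = xs, y = ys)
  verts <- data.frame(id = seq_len(nrow(verts)), x = verts$x, y = verts$y)
  vid <- function(i, j) as.integer((j - 1) * (nx + 1) + i)
  cells <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    cells[[sprintf("c%d%d", i, j)]] <-
      c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1))
  }
  segmentedTimepoint(time, verts, cells, sample = "grid")
}

## apply an affine map to every junction of a tessellation
transformTimepoint <- function(tp, A = diag(2), shift = c(0, 0),
                               time = tp@time + 1) {
  v <- tp@vertices
  p <- cbind(v$x, v$y) %*% t(A)
  v$x <- p[, 1] + shift[1]
  v$y <- p[, 2] + shift[2]
  segmentedTimepoint(time, v, tp@cells, tp@attrs, tp@sample)
}

## identity lineage between two timepoints
identityLineage <- function(t0, t1) {
  ids <- cellIds(t0)
  lineageMap(t0@time, t1@time, stats::setNames(ids, ids))
}

## the margin configuration producing exactly one protrusion (narrow
## competence zone, early pattern end); used where protrusion identity
## must not depend on convergence-point count
singleProtrusionParams <- function(...) {
  marginParams(competenceZone = c(0.2, 0.8), tPatternEnd = 2.8, ...)
}
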