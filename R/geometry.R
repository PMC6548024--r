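## Planar geometry primitives used throughout the package.
## Polygons are n x 2 numeric matrices of vertices in order (open ring:
## the closing edge last->first is implied).  All coordinates are in um.

#' Signed area of a simple polygon
#'
#' Shoelace formula; positive for counter-clockwise orientation.
#'
#' @param xy numeric matrix (n x 2) of polygon vertices in order.
#' @return signed area (um^2).
#' @export
polySignedArea <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a simple polygon
#' @inheritParams polySignedArea
#' @return absolute area (um^2).
#' @export
polyArea <- function(xy) abs(polySignedArea(xy))

#' Perimeter of a polygon
#' @inheritParams polySignedArea
#' @return perimeter length (um).
#' @export
polyPerimeter <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 2) return(0)
  j <- c(2:n, 1)
  sum(sqrt(rowSums((xy[j, , drop = FALSE] - xy)^2)))
}

#' Centroid of a simple polygon
#' @inheritParams polySignedArea
#' @return length-2 numeric (um).
#' @export
polyCentroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

## Orient a polygon counter-clockwise.
ensureCCW <- function(xy) {
  if (polySignedArea(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

## Sutherland-Hodgman clip of a convex-or-simple polygon by the half-plane
## {x : <nrm, x> <= d}.  Returns a matrix (possibly 0-row).
clipHalfPlane <- function(xy, nrm, d) {
  n <- nrow(xy)
  if (n == 0) return(xy)
  s <- as.vector(xy %*% nrm) - d     # <= 0 means inside
  inside <- s <= 1e-12
  if (all(inside)) return(xy)
  if (!any(inside)) return(xy[0, , drop = FALSE])
  out <- matrix(0, n + 4, 2); k <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (inside[i]) { k <- k + 1; out[k, ] <- xy[i, ] }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1
      out[k, ] <- xy[i, ] + t * (xy[j, ] - xy[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

## Bounded Voronoi tessellation of `domain` (simple CCW polygon) for the
## given seed points.  O(n^2) half-plane clipping with an early exit once the
## running cell is provably final.  Returns a list of polygons (one per seed).
boundedVoronoi <- function(seeds, domain) {
  n <- nrow(seeds)
  domain <- ensureCCW(domain)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    p <- seeds[i, ]
    d2 <- rowSums((seeds - matrix(p, n, 2, byrow = TRUE))^2)
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- domain
    for (j in ord) {
      ## early exit: every remaining site is farther than twice the cell radius
      r2max <- max(rowSums((cell - matrix(p, nrow(cell), 2, byrow = TRUE))^2))
      if (d2[j] > 4 * r2max) break
      q <- seeds[j, ]
      nrm <- q - p
      d <- sum(nrm * (p + q) / 2)
      cell <- clipHalfPlane(cell, nrm, d)
      if (nrow(cell) == 0) break
    }
    cells[[i]] <- cell
  }
  cells
}

## Even-odd point-in-polygon test, vectorised over points.
pointsInPolygon <- function(pts, poly) {
  n <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Rejection-sample n points uniformly inside a polygon (deterministic given
## the RNG state).
samplePointsInPolygon <- function(n, poly) {
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, rx[1], rx[2]), stats::runif(m, ry[1], ry[2]))
    out <- rbind(out, cand[pointsInPolygon(cand, poly), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

## Split a simple polygon by the infinite line through `pt` with direction
## angle `theta`.  Returns NULL when the line misses the polygon interior,
## otherwise list(a=, b=, cuts=) where cuts is a 2x3 matrix: for each of the
## two cut points, (x, y, edge index of the original polygon it lies on).
splitPolygonByLine <- function(xy, pt, theta) {
  dirv <- c(cos(theta), sin(theta))
  nrm <- c(-dirv[2], dirv[1])
  s <- as.vector((xy - matrix(pt, nrow(xy), 2, byrow = TRUE)) %*% nrm)
  n <- nrow(xy)
  jn <- c(2:n, 1)
  crossing <- which((s <= 0 & s[jn] > 0) | (s > 0 & s[jn] <= 0))
  if (length(crossing) != 2) return(NULL)
  cuts <- matrix(0, 2, 3)
  for (k in 1:2) {
    i <- crossing[k]; j <- jn[i]
    t <- s[i] / (s[i] - s[j])
    cuts[k, 1:2] <- xy[i, ] + t * (xy[j, ] - xy[i, ])
    cuts[k, 3] <- i
  }
  ## walk the ring, inserting the cut points, and collect the two sides
  side_a <- list(); side_b <- list()
  for (i in seq_len(n)) {
    tgt <- if (s[i] <= 0) "a" else "b"
    if (tgt == "a") side_a[[length(side_a) + 1]] <- xy[i, ]
    else side_b[[length(side_b) + 1]] <- xy[i, ]
    kk <- which(cuts[, 3] == i)
    if (length(kk) == 1) {
      side_a[[length(side_a) + 1]] <- cuts[kk, 1:2]
      side_b[[length(side_b) + 1]] <- cuts[kk, 1:2]
    }
  }
  a <- do.call(rbind, side_a); b <- do.call(rbind, side_b)
  if (is.null(a) || is.null(b) || nrow(a) < 3 || nrow(b) < 3) return(NULL)
  list(a = a, b = b, cuts = cuts)
}

#' Best-fit affine deformation between matched point sets
#'
#' Least-squares fit of \code{p1 ~ F p0 + t} for matched planar points,
#' the deformation-gradient estimate used for cell growth tensors.
#'
#' @param p0,p1 numeric matrices (n x 2) of matched positions at the earlier
#'   and later time.
#' @return list with \code{F} (2 x 2), \code{t} (length 2) and \code{rmse}.
#' @export
fitAffine <- function(p0, p1) {
  stopifnot(nrow(p0) == nrow(p1), nrow(p0) >= 3)
  X <- cbind(p0, 1)
  B <- qr.solve(X, p1)           # 3 x 2: rows (F col wise, t)
  Fm <- t(B[1:2, , drop = FALSE])
  tv <- B[3, ]
  pred <- p0 %*% t(Fm) + matrix(tv, nrow(p0), 2, byrow = TRUE)
  list(F = Fm, t = tv, rmse = sqrt(mean((pred - p1)^2)))
}

## 2x2 polar decomposition F = R S with R a rotation, S symmetric pos.def.
polarDecomp2 <- function(Fm) {
  ## closed form for 2x2: R = (F + det-adjusted cofactor)/norm
  a <- Fm[1, 1] + Fm[2, 2]
  b <- Fm[2, 1] - Fm[1, 2]
  r <- sqrt(a * a + b * b)
  if (r < 1e-14) return(list(R = diag(2), S = Fm))
  cth <- a / r; sth <- b / r
  R <- matrix(c(cth, sth, -sth, cth), 2, 2)
  list(R = R, S = t(R) %*% Fm)
}

## Principal stretches and max-stretch direction of a 2x2 deformation
## gradient, via SVD.  Orientation reported in degrees in [0, 180) in the
## target frame.
principalStretches <- function(Fm) {
  sv <- svd(Fm)
  kmax <- sv$d[1]; kmin <- sv$d[2]
  u1 <- sv$u[, 1]
  ang <- atan2(u1[2], u1[1]) * 180 / pi
  ang <- ang %% 180
  list(kmax = kmax, kmin = kmin, orientation = ang)
}

## Local peak (and trough) finder with prominence, on a numeric vector.
## Returns indices of peaks whose prominence exceeds `prominence`.
findPeaks <- function(y, prominence = 0) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    ## prominence: height above the higher of the two flanking key saddles
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    hi_l <- which(left >= y[i])
    lmin <- if (length(hi_l)) min(left[seq(max(hi_l), length(left))]) else min(left)
    hi_r <- which(right >= y[i])
    rmin <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
    keep[k] <- (y[i] - max(lmin, rmin)) >= prominence
  }
  cand[keep]
}

## Resample a polyline (n x 2) at approximately uniform spacing `ds`,
## keeping endpoints.  Returns a matrix.
resamplePolyline <- function(xy, ds) {
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(xy[c(1, nrow(xy)), , drop = FALSE])
  m <- max(2L, ceiling(L / ds) + 1L)
  si <- seq(0, L, length.out = m)
  cbind(stats::approx(s, xy[, 1], xout = si)$y,
        stats::approx(s, xy[, 2], xout = si)$y)
}

## Arc length of a polyline.
polylineLength <- function(xy) sum(sqrt(rowSums(diff(xy)^2)))

## Perimeter of the convex hull of a point set.
convexHullPerimeter <- function(xy) {
  h <- grDevices::chull(xy[, 1], xy[, 2])
  polyPerimeter(xy[h, , drop = FALSE])
}
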