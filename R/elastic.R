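## Finite-element primitives on the triangulated tissue: P1
## diffusion-decay of the differentiation factor and corotational
## linear-elastic relaxation of grown rest shapes.
##
## Energy per triangle: A_rest * [ mu ||sym(R'F) - I||^2 + lambda/2
## tr(sym(R'F) - I)^2 ], with F the deformation gradient from the rest
## edge matrix to the current one and R its polar rotation.  With R held
## fixed the energy is quadratic in vertex positions, so relaxation
## alternates polar-rotation updates with one sparse SPD solve.

#' Structured rectangular strip mesh
#'
#' Regular triangulated grid on [0, W] x [0, L]; used for closed-form
#' verification of the diffusion-decay solver and as a simple test domain.
#'
#' @param nx,ny number of vertex columns and rows.
#' @param W,L strip width and length (um).
#' @return list with \code{vertices} (n x 2), \code{triangles} (m x 3, CCW)
#'   and \code{base} (indices of the y = 0 vertex row).
#' @export
meshRectangle <- function(nx = 5, ny = 40, W = 10, L = 200) {
  xs <- seq(0, W, length.out = nx)
  ys <- seq(0, L, length.out = ny)
  verts <- as.matrix(expand.grid(x = xs, y = ys))
  id <- function(i, j) (j - 1) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  list(vertices = verts, triangles = do.call(rbind, tris),
       base = seq_len(nx))
}

## per-triangle edge matrices of the current configuration
edgeMatrices <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  list(e1 = p2 - p1, e2 = p3 - p1)
}

## rest areas from the 2x2xm rest array
restAreas <- function(rest) {
  vapply(seq_len(dim(rest)[3]), function(t) {
    D <- rest[, , t]
    abs(D[1, 1] * D[2, 2] - D[1, 2] * D[2, 1]) / 2
  }, 0)
}

## deformation gradients F = Ds Dm^-1 per triangle (list of 2x2)
deformationGradients <- function(vertices, triangles, rest) {
  em <- edgeMatrices(vertices, triangles)
  lapply(seq_len(nrow(triangles)), function(t) {
    Ds <- cbind(em$e1[t, ], em$e2[t, ])
    Dm <- rest[, , t]
    Ds %*% solve(Dm)
  })
}

## P1 stiffness and lumped mass matrices of the current mesh
assembleDiffusionOperators <- function(vertices, triangles) {
  m <- nrow(triangles); n <- nrow(vertices)
  ii <- integer(0); jj <- integer(0); ss <- numeric(0)
  mi <- integer(0); ms <- numeric(0)
  for (t in seq_len(m)) {
    vid <- triangles[t, ]
    P <- vertices[vid, ]
    ## gradients of the barycentric basis
    b <- c(P[2, 2] - P[3, 2], P[3, 2] - P[1, 2], P[1, 2] - P[2, 2])
    cc <- c(P[3, 1] - P[2, 1], P[1, 1] - P[3, 1], P[2, 1] - P[1, 1])
    A2 <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
      (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])
    A <- abs(A2) / 2
    Ke <- (outer(b, b) + outer(cc, cc)) / (4 * A)
    ii <- c(ii, rep(vid, each = 3)); jj <- c(jj, rep(vid, times = 3))
    ss <- c(ss, as.vector(t(Ke)))
    mi <- c(mi, vid); ms <- c(ms, rep(A / 3, 3))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = ss, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = mi, j = mi, x = ms, dims = c(n, n))
  list(K = K, M = M)
}

## one implicit diffusion-decay step with Dirichlet values on `source`
## vertices: (M/dt + D K + k M) c' = (M/dt) c,  c'[source] = cSource
implicitDiffusionStep <- function(vertices, triangles, conc, dt, D, k,
                                  source, cSource) {
  ops <- assembleDiffusionOperators(vertices, triangles)
  n <- nrow(vertices)
  A <- ops$M / dt + D * ops$K + k * ops$M
  b <- as.vector(ops$M %*% conc) / dt
  ## Dirichlet elimination
  free <- setdiff(seq_len(n), source)
  b <- b - as.vector(A[, source, drop = FALSE] %*% rep(cSource, length(source)))
  sol <- tryCatch(
    Matrix::solve(A[free, free, drop = FALSE], b[free]),
    error = function(e) stop("singular diffusion system (", e$message,
                             "); mesh: ", n, " vertices, ",
                             nrow(triangles), " triangles"))
  out <- numeric(n)
  out[free] <- as.vector(sol)
  out[source] <- cSource
  pmax(out, 0)
}

## total corotational elastic energy of a configuration
elasticEnergy <- function(vertices, triangles, rest, mu, lambda) {
  Fs <- deformationGradients(vertices, triangles, rest)
  A <- restAreas(rest)
  e <- 0
  for (t in seq_along(Fs)) {
    S <- polarDecomp2(Fs[[t]])$S
    eps <- (S + t(S)) / 2 - diag(2)
    e <- e + A[t] * (mu * sum(eps^2) + lambda / 2 * sum(diag(eps))^2)
  }
  e
}

#' Elastic relaxation of a grown mesh
#'
#' Minimizes the corotational linear-elastic energy of the deviation
#' between the current configuration and the per-triangle rest shapes,
#' with free boundaries (rigid modes pinned internally).  Alternates
#' per-triangle polar-rotation updates with sparse SPD solves until vertex
#' positions stop moving.
#'
#' @param vertices n x 2 current positions (um).
#' @param triangles m x 3 vertex indices.
#' @param rest 2 x 2 x m rest edge matrices.
#' @param poisson Poisson ratio.
#' @param tol convergence tolerance on the relative vertex displacement per
#'   iteration.
#' @param maxIter maximum corotational iterations.
#' @param onInverted \code{"error"} (default) aborts when the relaxed
#'   configuration contains inverted elements; \code{"return"} reports them
#'   in the \code{inverted} component instead, for callers that untangle.
#' @return list with \code{vertices} (relaxed positions), \code{energy},
#'   \code{iterations}, \code{residual} (last relative displacement) and
#'   \code{inverted} (indices of inverted elements, normally empty).
#' @export
elasticRelax <- function(vertices, triangles, rest, poisson = 0.3,
                         tol = 1e-8, maxIter = 12,
                         onInverted = c("error", "return")) {
  onInverted <- match.arg(onInverted)
  E <- 1
  mu <- E / (2 * (1 + poisson))
  lambda <- E * poisson / ((1 + poisson) * (1 - 2 * poisson))
  n <- nrow(vertices); m <- nrow(triangles)
  A <- restAreas(rest)
  Binv <- lapply(seq_len(m), function(t) solve(rest[, , t]))
  ## rigid-mode pinning: fix the basal-most vertex, and the x coordinate of
  ## the most distant vertex (kills translation + rotation, no stress for
  ## compatible growth)
  i0 <- which.min(vertices[, 2])
  i1 <- which.max(rowSums(sweep(vertices, 2, vertices[i0, ])^2))
  scale0 <- sqrt(max(rowSums(sweep(vertices, 2, colMeans(vertices))^2)))
  pos <- vertices
  ## vectorized per-triangle constants
  Bv <- t(vapply(Binv, as.vector, numeric(4)))  # (B11, B21, B12, B22)
  W <- array(0, c(m, 3, 2))                     # w[k, b] per triangle
  W[, 1, 1] <- -(Bv[, 1] + Bv[, 2]); W[, 2, 1] <- Bv[, 1]; W[, 3, 1] <- Bv[, 2]
  W[, 1, 2] <- -(Bv[, 3] + Bv[, 4]); W[, 2, 2] <- Bv[, 3]; W[, 3, 2] <- Bv[, 4]
  gdof <- cbind(2 * triangles[, 1] - 1, 2 * triangles[, 1],
                2 * triangles[, 2] - 1, 2 * triangles[, 2],
                2 * triangles[, 3] - 1, 2 * triangles[, 3])
  iiAll <- as.vector(t(gdof[, rep(1:6, each = 6)]))
  jjAll <- as.vector(t(gdof[, rep(1:6, times = 6)]))
  cthPrev <- rep(1, m); sthPrev <- rep(0, m)
  res <- Inf; it <- 0
  while (it < maxIter && res > tol) {
    it <- it + 1
    em <- edgeMatrices(pos, triangles)
    F11 <- em$e1[, 1] * Bv[, 1] + em$e2[, 1] * Bv[, 2]
    F21 <- em$e1[, 2] * Bv[, 1] + em$e2[, 2] * Bv[, 2]
    F12 <- em$e1[, 1] * Bv[, 3] + em$e2[, 1] * Bv[, 4]
    F22 <- em$e1[, 2] * Bv[, 3] + em$e2[, 2] * Bv[, 4]
    detF <- F11 * F22 - F12 * F21
    ## closed-form 2x2 polar rotation; transiently degenerate or inverted
    ## elements keep their previous rotation (the quadratic energy then
    ## pulls them back through the next solve)
    pa <- F11 + F22; pb <- F21 - F12
    pr <- sqrt(pa^2 + pb^2)
    bad <- detF <= 0 | pr < 1e-14
    cth <- ifelse(bad, cthPrev, pa / pr)
    sth <- ifelse(bad, sthPrev, pb / pr)
    cthPrev <- cth; sthPrev <- sth
    ## b-vectors over the 6 element dofs (x1, y1, x2, y2, x3, y3):
    ## bS(i,b)[2k-2+a] = R[a,i] w[k,b]; R = [[cth, -sth], [sth, cth]]
    mkB <- function(Ri1, Ri2, b) {
      cbind(Ri1 * W[, 1, b], Ri2 * W[, 1, b],
            Ri1 * W[, 2, b], Ri2 * W[, 2, b],
            Ri1 * W[, 3, b], Ri2 * W[, 3, b])
    }
    b11 <- mkB(cth, sth, 1)              # R[,1] = (cth, sth)
    b22 <- mkB(-sth, cth, 2)             # R[,2] = (-sth, cth)
    b12 <- (mkB(cth, sth, 2) + mkB(-sth, cth, 1)) / 2
    bs <- b11 + b22
    ss <- matrix(0, m, 36)
    for (i in 1:6) for (j in 1:6) {
      ss[, (i - 1) * 6 + j] <- A * (2 * mu * (b11[, i] * b11[, j] +
                                                b22[, i] * b22[, j] +
                                                2 * b12[, i] * b12[, j]) +
                                      lambda * bs[, i] * bs[, j])
    }
    fe <- A * (2 * mu * (b11 + b22) + 2 * lambda * bs)
    fvec <- as.vector(Matrix::sparseMatrix(
      i = as.vector(gdof), j = rep(1L, 6L * m), x = as.vector(fe),
      dims = c(2 * n, 1)))
    ## ss column order is (i,j) with i-major over rows of the 6x6 block;
    ## iiAll/jjAll were built j-fastest, matching t(block) — symmetric
    H <- Matrix::sparseMatrix(i = iiAll, j = jjAll, x = as.vector(t(ss)),
                              dims = c(2 * n, 2 * n))
    fixed <- c(2 * i0 - 1, 2 * i0, 2 * i1 - 1)
    fixedVal <- c(pos[i0, 1], pos[i0, 2], pos[i1, 1])
    free <- setdiff(seq_len(2 * n), fixed)
    rhs <- fvec - as.vector(H[, fixed, drop = FALSE] %*% fixedVal)
    sol <- Matrix::solve(H[free, free, drop = FALSE], rhs[free])
    u <- numeric(2 * n)
    u[free] <- as.vector(sol)
    u[fixed] <- fixedVal
    newPos <- cbind(u[seq(1, 2 * n, 2)], u[seq(2, 2 * n, 2)])
    res <- max(abs(newPos - pos)) / scale0
    pos <- newPos
  }
  ## the relaxed configuration itself must be inversion-free
  emF <- edgeMatrices(pos, triangles)
  detEnd <- (emF$e1[, 1] * Bv[, 1] + emF$e2[, 1] * Bv[, 2]) *
    (emF$e1[, 2] * Bv[, 3] + emF$e2[, 2] * Bv[, 4]) -
    (emF$e1[, 1] * Bv[, 3] + emF$e2[, 1] * Bv[, 4]) *
    (emF$e1[, 2] * Bv[, 1] + emF$e2[, 2] * Bv[, 2])
  inverted <- which(detEnd <= 0)
  if (length(inverted) && onInverted == "error")
    stop("inverted element ", inverted[1], " after relaxation")
  if (!is.finite(res) || res > sqrt(tol))
    warning(sprintf("relaxation stopped at residual %.3g after %d iterations",
                    res, it))
  list(vertices = pos, energy = elasticEnergy(pos, triangles, rest, mu, lambda),
       iterations = it, residual = res, inverted = inverted)
}
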