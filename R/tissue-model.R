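## 2D growing-tissue model of the leaf primordium.
##
## Architecture: specified growth (per-triangle growth tensors set by
## tissue type, differentiation state and, when patterning is enabled, the
## auxin-PIN1-CUC2 margin reaction) deforms per-triangle rest shapes;
## elastic relaxation of the connected tissue then yields resultant growth
## and organ shape.  A factor produced at the leaf base diffuses and
## decays; differentiation starts where it falls below a threshold, so the
## differentiation front progresses basipetally as the organ outgrows the
## factor's penetration length.

#' Tissue model configuration
#'
#' Constructor with the wild-type calibration used throughout the package:
#' defaults are chosen so the simulated primordium midline measures about
#' 150 um at 3 DAI and about 800 um at 7 DAI (see the methods vignette).
#'
#' @param initLength,initWidth initial primordium size at 1 DAI (um).
#' @param meshRings rings of the structured initial mesh.
#' @param initiationStart,initiationEnd initiation window (DAI); specified
#'   growth is homogeneous and anisotropic inside it.
#' @param initRatePar,initRatePerp initiation-window rates (1/day)
#'   along/across the organ axis.
#' @param bladeRate isotropic blade rate (1/day).
#' @param midribRatePar,midribRatePerp midrib/petiole rates (1/day).
#' @param diffGrowthFactor post-differentiation rate multiplier.
#' @param auxinBoost margin growth boost at auxin maxima.
#' @param cucInhibition growth multiplier next to high-CUC2 margin cells.
#' @param cucRadius how many triangles deep the CUC2 inhibition reaches.
#' @param auxinDiffAccel fractional local reduction of the effective
#'   differentiation-factor level at auxin maxima.
#' @param D,kDecay,cSource,cStar differentiation-factor parameters
#'   (um^2/day, 1/day, source level, threshold).
#' @param transportCoef,hExp,auxinDiffusion,auxinProd,auxinDecay,cucRepress,cucRecover,auxinThr,promThr
#'   margin reaction parameters (polar transport coefficient, up-the-gradient
#'   exponent, passive cell-to-cell auxin exchange, production, decay, CUC2
#'   repression/recovery, auxin threshold for CUC2 repression, prominence
#'   threshold for maxima).
#' @param poisson Poisson ratio of the relaxation.
#' @param dtGrowth growth step (day).
#' @param reactionSubsteps reaction substeps per growth step.
#' @param tEnd end time (DAI).
#' @param patterningEnabled enable the margin reaction (FALSE reproduces
#'   the no-patterning convergent form).
#' @param seed integer seed for the initial reaction perturbation.
#' @param midribFrac,midribTopFrac midrib strip geometry (fractions of the
#'   half-width and length).
#' @param remeshFactor boundary edges longer than this multiple of the
#'   initial mean boundary edge are split.
#' @return a validated \linkS4class{TissueConfig}.
#' @export
tissueConfig <- function(initLength = 40, initWidth = 24, meshRings = 5,
                         initiationStart = 1, initiationEnd = 1.85,
                         initRatePar = 0.85, initRatePerp = 0.30,
                         bladeRate = 0.55,
                         midribRatePar = 0.78, midribRatePerp = 0.05,
                         diffGrowthFactor = 0.12,
                         auxinBoost = 1.8, cucInhibition = 0.35,
                         cucRadius = 1, auxinDiffAccel = 0.35,
                         D = 2e5, kDecay = 3.2, cSource = 1, cStar = 0.30,
                         transportCoef = 6, hExp = 2, auxinDiffusion = 1,
                         auxinProd = 0.25, auxinDecay = 0.25,
                         cucRepress = 2.5, cucRecover = 0.3,
                         auxinThr = 2.0, promThr = 1.3,
                         poisson = 0.3,
                         dtGrowth = 0.02, reactionSubsteps = 10, tEnd = 7,
                         patterningEnabled = TRUE, seed = 1L,
                         midribFrac = 0.3, midribTopFrac = 0.55,
                         remeshFactor = 2) {
  obj <- new("TissueConfig", initLength = initLength, initWidth = initWidth,
             meshRings = meshRings, initiationStart = initiationStart,
             initiationEnd = initiationEnd, initRatePar = initRatePar,
             initRatePerp = initRatePerp, bladeRate = bladeRate,
             midribRatePar = midribRatePar, midribRatePerp = midribRatePerp,
             diffGrowthFactor = diffGrowthFactor, auxinBoost = auxinBoost,
             cucInhibition = cucInhibition, cucRadius = cucRadius,
             auxinDiffAccel = auxinDiffAccel, D = D, kDecay = kDecay,
             cSource = cSource, cStar = cStar, transportCoef = transportCoef,
             hExp = hExp, auxinDiffusion = auxinDiffusion,
             auxinProd = auxinProd, auxinDecay = auxinDecay,
             cucRepress = cucRepress, cucRecover = cucRecover,
             auxinThr = auxinThr, promThr = promThr, poisson = poisson,
             dtGrowth = dtGrowth, reactionSubsteps = reactionSubsteps,
             tEnd = tEnd, patterningEnabled = patterningEnabled, seed = seed,
             midribFrac = midribFrac, midribTopFrac = midribTopFrac,
             remeshFactor = remeshFactor)
  msg <- validObject(obj, test = TRUE)
  if (is.character(msg)) stop("invalid tissue configuration: ",
                              paste(msg, collapse = "; "))
  obj
}

## structured hexagonal disk triangulation: ring k carries 6k vertices, so
## element quality is uniform (no high-valence centre, no needle fans)
diskMesh <- function(rings, M = NULL) {
  verts <- matrix(0, 1, 2)
  ringStart <- integer(rings + 1)   # index of first vertex of ring k
  ringStart[1] <- 1                 # ring 0 = centre vertex
  for (k in seq_len(rings)) {
    nk <- 6 * k
    th <- 2 * pi * seq(0, nk - 1) / nk
    ringStart[k + 1] <- nrow(verts) + 1
    verts <- rbind(verts, (k / rings) * cbind(cos(th), sin(th)))
  }
  at <- function(k, j) {            # vertex j (0-based, wrapped) of ring k
    if (k == 0) return(1L)
    as.integer(ringStart[k + 1] + (j %% (6 * k)))
  }
  tris <- list()
  for (j in 0:5)                    # centre hexagon
    tris[[length(tris) + 1]] <- c(1L, at(1, j), at(1, j + 1))
  if (rings > 1) for (k in 2:rings) for (s in 0:5) {
    ## sector s: outer ring k nodes s*k .. s*k+k, inner ring k-1 nodes
    ## s*(k-1) .. s*(k-1)+(k-1), zig-zag triangulated
    for (i in 0:(k - 1))
      tris[[length(tris) + 1]] <- c(at(k, s * k + i), at(k, s * k + i + 1),
                                    at(k - 1, s * (k - 1) + i))
    if (k >= 2) for (i in 0:(k - 2))
      tris[[length(tris) + 1]] <- c(at(k - 1, s * (k - 1) + i),
                                    at(k, s * k + i + 1),
                                    at(k - 1, s * (k - 1) + i + 1))
  }
  tri <- do.call(rbind, tris)
  for (t in seq_len(nrow(tri))) {
    P <- verts[tri[t, ], ]
    if (polySignedArea(P) < 0) tri[t, ] <- tri[t, c(1, 3, 2)]
  }
  list(vertices = verts, triangles = tri)
}

## ordered boundary vertex cycle of a triangle mesh, starting at the basal
## (minimum y) vertex, counter-clockwise
meshBoundary <- function(vertices, triangles) {
  em <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  cnt <- table(key)
  bnd <- em[cnt[key] == 1, , drop = FALSE]   # directed, CCW for CCW triangles
  nxt <- bnd[, 2]; names(nxt) <- as.character(bnd[, 1])
  start <- bnd[which.min(vertices[bnd[, 1], 2]), 1]
  cyc <- integer(nrow(bnd)); cur <- start
  for (i in seq_len(nrow(bnd))) {
    cyc[i] <- cur
    cur <- nxt[[as.character(cur)]]
  }
  cyc
}

#' Initialize the primordium
#'
#' Builds a small rounded-oblong triangulated primordium (base at y = 0),
#' assigns tissue labels (central proximal strip = midrib/petiole, boundary
#' strip = margin, rest = blade), sets the differentiation factor to its
#' source value and initializes the margin-cell chain with a small seeded
#' auxin perturbation.
#'
#' @param config a \linkS4class{TissueConfig}.
#' @return a \linkS4class{TissueState} at \code{initiationStart}.
#' @export
initPrimordium <- function(config) {
  msg <- validObject(config, test = TRUE)
  if (is.character(msg)) stop("invalid tissue configuration: ",
                              paste(msg, collapse = "; "))
  if (config@initWidth < config@initLength / 20)
    stop("degenerate primordium geometry: blade width too small")
  dm <- diskMesh(as.integer(config@meshRings))
  v <- dm$vertices
  ## map unit disk to a rounded oblong, base at y = 0
  v <- cbind(v[, 1] * config@initWidth / 2,
             (v[, 2] + 1) * config@initLength / 2)
  tri <- dm$triangles
  m <- nrow(tri)
  cent <- (v[tri[, 1], ] + v[tri[, 2], ] + v[tri[, 3], ]) / 3
  bnd <- meshBoundary(v, tri)
  nb <- rowSums(matrix(tri %in% bnd, m, 3))
  tissue <- rep("blade", m)
  tissue[abs(cent[, 1]) <= config@midribFrac * config@initWidth / 2 &
           cent[, 2] <= config@midribTopFrac * config@initLength] <-
    "midrib_petiole"
  tissue[nb >= 2] <- "margin"
  if (!all(c("blade", "midrib_petiole", "margin") %in% tissue))
    stop("degenerate geometry: a tissue class is empty")
  rest <- array(0, c(2, 2, m))
  for (t in seq_len(m)) {
    rest[, , t] <- cbind(v[tri[t, 2], ] - v[tri[t, 1], ],
                         v[tri[t, 3], ] - v[tri[t, 1], ])
  }
  base <- bnd[v[bnd, 2] <= 0.08 * config@initLength]
  set.seed(as.integer(config@seed))
  ## mirror-symmetric seed perturbation: leaf primordia pattern their
  ## margins in near-symmetric left/right pairs, and a symmetric seed
  ## keeps the simulated organ straight
  nb <- length(bnd)
  noise <- stats::rnorm(nb, 0, 0.02)
  for (k in seq_len(nb)) {
    partner <- which.min((v[bnd, 1] + v[bnd[k], 1])^2 +
                           (v[bnd, 2] - v[bnd[k], 2])^2)
    if (partner > k) noise[partner] <- noise[k]
  }
  marg <- data.frame(vertex = bnd, auxin = 1 + noise,
                     cuc = 1, isMax = FALSE, differentiated = FALSE)
  new("TissueState", vertices = v, triangles = tri, rest = rest,
      tissue = tissue, differentiated = rep(FALSE, m),
      conc = rep(config@cSource, nrow(v)), margin = marg,
      baseVertices = as.integer(base), time = config@initiationStart)
}

#' @rdname meshOutline
setMethod("meshOutline", "TissueState", function(x) {
  x@vertices[meshBoundary(x@vertices, x@triangles), , drop = FALSE]
})

#' Update the differentiation factor and differentiation state
#'
#' One implicit diffusion-decay step of the basally produced factor
#' (Dirichlet source on the base boundary), then irreversible
#' differentiation of triangles whose effective factor level falls below
#' the threshold outside the initiation window.  At margin auxin maxima the
#' effective level is locally reduced (auxin accelerates differentiation).
#'
#' @param state a \linkS4class{TissueState}.
#' @param config a \linkS4class{TissueConfig}.
#' @param dt step (day).
#' @return the updated \linkS4class{TissueState}.
#' @export
updateDiffFactor <- function(state, config, dt) {
  conc <- implicitDiffusionStep(state@vertices, state@triangles, state@conc,
                                dt, config@D, config@kDecay,
                                state@baseVertices, config@cSource)
  state@conc <- conc
  t1 <- state@time
  if (t1 > config@initiationEnd) {
    accel <- rep(1, nrow(state@vertices))
    mx <- state@margin$vertex[state@margin$isMax]
    if (length(mx)) accel[mx] <- 1 - config@auxinDiffAccel
    ceff <- conc * accel
    tric <- (ceff[state@triangles[, 1]] + ceff[state@triangles[, 2]] +
               ceff[state@triangles[, 3]]) / 3
    state@differentiated <- state@differentiated | (tric < config@cStar)
    ## margin cells follow the differentiation of their incident triangles
    mv <- state@margin$vertex
    diffv <- rep(FALSE, nrow(state@vertices))
    dtri <- state@triangles[state@differentiated, , drop = FALSE]
    diffv[unique(as.vector(dtri))] <- TRUE
    state@margin$differentiated <- state@margin$differentiated | diffv[mv]
  }
  state
}

#' One step of the auxin-PIN1-CUC2 margin reaction
#'
#' Up-the-gradient PIN1 allocation (exponent \code{hExp}) with transport
#' feedback scaled by CUC2, uniform auxin production and linear decay,
#' CUC2 repression where auxin is high and recovery elsewhere, and
#' flagging of auxin maxima above the prominence threshold.  Differentiated
#' cells drop out of the reaction.
#'
#' @param margin margin-cell data.frame (columns \code{auxin}, \code{cuc},
#'   \code{isMax}, \code{differentiated}).
#' @param config a \linkS4class{TissueConfig}.
#' @param dt step (day).
#' @param topology \code{"ring"} (periodic; the default, and the geometry
#'   of the primordium boundary) or \code{"path"}.
#' @return the updated margin data.frame.
#' @export
marginReactionStep <- function(margin, config, dt, topology = c("ring", "path")) {
  topology <- match.arg(topology)
  n <- nrow(margin)
  a <- margin$auxin; cu <- margin$cuc
  act <- !margin$differentiated
  left <- c(n, seq_len(n - 1)); right <- c(seq_len(n - 1) + 1, 1)
  if (topology == "path") { left[1] <- NA; right[n] <- NA }
  wL <- ifelse(!is.na(left) & act[pmax(left, 1)], a[pmax(left, 1)]^config@hExp, 0)
  wR <- ifelse(!is.na(right) & act[pmin(right, n)], a[pmin(right, n)]^config@hExp, 0)
  wL[!act] <- 0; wR[!act] <- 0
  tot <- wL + wR
  pL <- ifelse(tot > 0, wL / tot, 0)
  pR <- ifelse(tot > 0, wR / tot, 0)
  fL <- config@transportCoef * cu * pL * a    # flux to left neighbour
  fR <- config@transportCoef * cu * pR * a
  fL[!act] <- 0; fR[!act] <- 0
  inflow <- numeric(n)
  okL <- !is.na(left); okR <- !is.na(right)
  inflow[left[okL]] <- inflow[left[okL]] + fL[okL]
  inflow[right[okR]] <- inflow[right[okR]] + fR[okR]
  ## passive auxin exchange between active neighbours (conservative)
  diffus <- numeric(n)
  if (config@auxinDiffusion > 0) {
    for (i in which(act)) {
      for (j in c(left[i], right[i])) {
        if (!is.na(j) && act[j])
          diffus[i] <- diffus[i] + config@auxinDiffusion * (a[j] - a[i])
      }
    }
  }
  da <- config@auxinProd - config@auxinDecay * a - (fL + fR) + inflow + diffus
  da[!act] <- 0
  hillA <- a^2 / (a^2 + config@auxinThr^2)
  dcu <- config@cucRecover * (1 - cu) - config@cucRepress * hillA * cu
  dcu[!act] <- 0
  margin$auxin <- pmax(a + dt * da, 0)
  margin$cuc <- pmin(pmax(cu + dt * dcu, 0), 1)
  aa <- margin$auxin
  isMax <- act & aa > config@promThr &
    aa >= ifelse(is.na(left), -Inf, aa[pmax(left, 1)]) &
    aa >= ifelse(is.na(right), -Inf, aa[pmin(right, n)])
  margin$isMax <- isMax
  margin
}

#' Specified growth tensors
#'
#' Per-triangle specified growth (rate along / rate across / orientation of
#' the local polarity axis).  During the initiation window growth is
#' homogeneous and anisotropic along the organ axis; afterwards the blade
#' grows isotropically, the midrib/petiole anisotropically along the local
#' proximodistal axis (the differentiation-factor gradient), margin
#' triangles at auxin maxima receive boosted outward-oriented growth and
#' CUC2-adjacent elements the inhibition factor; differentiated triangles
#' are scaled by the post-differentiation factor.
#'
#' @inheritParams updateDiffFactor
#' @return data.frame with per-triangle columns \code{ratePar},
#'   \code{ratePerp}, \code{theta} (radians).
#' @export
specifiedGrowth <- function(state, config) {
  m <- nrow(state@triangles)
  tri <- state@triangles
  v <- state@vertices
  if (state@time <= config@initiationEnd) {
    out <- data.frame(ratePar = rep(config@initRatePar, m),
                      ratePerp = rep(config@initRatePerp, m),
                      theta = rep(pi / 2, m))
  } else {
    ratePar <- rep(config@bladeRate, m)
    ratePerp <- rep(config@bladeRate, m)
    theta <- rep(pi / 2, m)
    ## proximodistal axis = direction of decreasing differentiation factor
    mid <- state@tissue == "midrib_petiole"
    if (any(mid)) {
      for (t in which(mid)) {
        P <- v[tri[t, ], ]
        cv <- state@conc[tri[t, ]]
        ## P1 gradient of conc on the triangle
        M <- cbind(P[2, ] - P[1, ], P[3, ] - P[1, ])
        g <- tryCatch(solve(t(M), cv[2:3] - cv[1]), error = function(e) c(0, 1))
        th <- if (sum(g^2) > 1e-18) atan2(-g[2], -g[1]) else pi / 2
        theta[t] <- th
        ratePar[t] <- config@midribRatePar
        ratePerp[t] <- config@midribRatePerp
      }
    }
    if (config@patterningEnabled) {
      marg <- which(state@tissue == "margin")
      mx <- state@margin$vertex[state@margin$isMax]
      ## CUC2 growth inhibition is sinus-local: it acts at the auxin
      ## minimum between each pair of adjacent maxima (plus immediate
      ## neighbours), where CUC2 stays high, not along the entire margin
      nm <- nrow(state@margin)
      mxPos <- which(state@margin$isMax)
      sinusIdx <- integer(0)
      if (length(mxPos) >= 2) {
        ends <- c(mxPos[-1], mxPos[1] + nm)
        for (g in seq_along(mxPos)) {
          between <- seq(mxPos[g] + 1, ends[g] - 1)
          if (!length(between)) next
          idx <- ((between - 1) %% nm) + 1
          s0 <- idx[which.min(state@margin$auxin[idx])]
          sinusIdx <- c(sinusIdx, ((s0 - 2):s0) %% nm + 1)
        }
      }
      hicuc <- state@margin$vertex[intersect(
        unique(sinusIdx),
        which(state@margin$cuc > 0.5 & !state@margin$differentiated))]
      ## boosted outgrowth acts on the maximum plus its immediate chain
      ## neighbours, spreading the protrusion deformation over several
      ## elements instead of shearing a single one
      mxPosAll <- which(state@margin$isMax)
      nbh <- unique(as.vector(vapply(mxPosAll, function(p0)
        as.integer(((p0 - 2):p0) %% nm + 1), integer(3))))
      mxWide <- state@margin$vertex[nbh]
      cenAll <- (v[tri[, 1], ] + v[tri[, 2], ] + v[tri[, 3], ]) / 3
      cen0 <- colMeans(v)
      inhib <- logical(m)
      for (t in marg) {
        vv <- tri[t, ]
        if (any(vv %in% mxWide)) {
          ## boosted anisotropic growth oriented outward
          dir <- cenAll[t, ] - cen0
          theta[t] <- atan2(dir[2], dir[1])
          ratePar[t] <- config@bladeRate * config@auxinBoost
          ratePerp[t] <- config@bladeRate * 0.5
        } else if (any(vv %in% hicuc)) {
          inhib[t] <- TRUE
        }
      }
      if (config@cucRadius > 0 && any(inhib)) {
        ## spread inhibition cucRadius triangles deep by shared vertices
        cur <- inhib
        for (r in seq_len(as.integer(config@cucRadius))) {
          vv <- unique(as.vector(tri[cur, , drop = FALSE]))
          cur <- rowSums(matrix(tri %in% vv, m, 3)) > 0
        }
        inhib <- cur & !vapply(seq_len(m), function(t)
          any(tri[t, ] %in% mx), TRUE)
      }
      ratePar[inhib] <- ratePar[inhib] * config@cucInhibition
      ratePerp[inhib] <- ratePerp[inhib] * config@cucInhibition
    }
    out <- data.frame(ratePar = ratePar, ratePerp = ratePerp, theta = theta)
  }
  d <- state@differentiated
  out$ratePar[d] <- out$ratePar[d] * config@diffGrowthFactor
  out$ratePerp[d] <- out$ratePerp[d] * config@diffGrowthFactor
  out
}

#' Grow rest shapes and relax the tissue
#'
#' Applies each triangle's specified growth tensor to its rest shape over
#' \code{dt} (multiplicative exponential update), then relaxes vertex
#' positions to elastic equilibrium.  Resultant growth can differ from
#' specified growth where neighbouring specifications conflict.
#'
#' @inheritParams updateDiffFactor
#' @param spec data.frame from \code{\link{specifiedGrowth}}.
#' @return the updated \linkS4class{TissueState}.
#' @export
growAndRelax <- function(state, spec, config, dt) {
  m <- nrow(state@triangles)
  rest <- state@rest
  for (t in seq_len(m)) {
    th <- spec$theta[t]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    G <- R %*% diag(c(exp(spec$ratePar[t] * dt),
                      exp(spec$ratePerp[t] * dt))) %*% t(R)
    rest[, , t] <- G %*% rest[, , t]
  }
  rx <- elasticRelax(state@vertices, state@triangles, rest,
                     poisson = config@poisson, onInverted = "return")
  ## untangle rare local fold-overs: move the vertices of inverted
  ## elements to their one-ring average, remodel those rest shapes to the
  ## untangled geometry, and re-relax
  tries <- 0
  while (length(rx$inverted) && tries < 4) {
    tries <- tries + 1
    v <- rx$vertices
    tri <- state@triangles
    badV <- unique(as.vector(tri[rx$inverted, , drop = FALSE]))
    ring <- lapply(badV, function(b) {
      inc <- tri[rowSums(tri == b) > 0, , drop = FALSE]
      setdiff(unique(as.vector(inc)), b)
    })
    for (k in seq_along(badV))
      v[badV[k], ] <- colMeans(v[ring[[k]], , drop = FALSE])
    for (t in rx$inverted) {
      D <- cbind(v[tri[t, 2], ] - v[tri[t, 1], ],
                 v[tri[t, 3], ] - v[tri[t, 1], ])
      if (D[1, 1] * D[2, 2] - D[1, 2] * D[2, 1] > 0) rest[, , t] <- D
    }
    rx <- elasticRelax(v, state@triangles, rest,
                       poisson = config@poisson, onInverted = "return")
  }
  if (length(rx$inverted))
    stop("inverted element ", rx$inverted[1], " after relaxation")
  state@vertices <- rx$vertices
  ## plastic yielding: elements whose elastic area mismatch exceeds a
  ## threshold remodel their rest shape to the realized one (walls yield
  ## under sustained stress); keeps incompatible growth from accumulating
  ## unbounded elastic strain
  v <- rx$vertices; tri <- state@triangles
  aCur <- abs((v[tri[, 2], 1] - v[tri[, 1], 1]) *
                (v[tri[, 3], 2] - v[tri[, 1], 2]) -
                (v[tri[, 3], 1] - v[tri[, 1], 1]) *
                (v[tri[, 2], 2] - v[tri[, 1], 2]))
  aRest <- vapply(seq_len(nrow(tri)), function(t)
    abs(rest[1, 1, t] * rest[2, 2, t] - rest[1, 2, t] * rest[2, 1, t]), 0)
  yield <- which(aCur / aRest < 0.45 | aCur / aRest > 2.2)
  medA <- stats::median(aCur)
  for (t in yield) {
    D <- cbind(v[tri[t, 2], ] - v[tri[t, 1], ],
               v[tri[t, 3], ] - v[tri[t, 1], ])
    ## only remodel to well-conditioned realized shapes; a crushed sliver
    ## must keep its healthy rest shape (its stress is what recovers it)
    eln <- c(sum(D[, 1]^2), sum(D[, 2]^2), sum((D[, 2] - D[, 1])^2))
    if (aCur[t] > 0.05 * medA && max(eln) / aCur[t] < 25)
      rest[, , t] <- D
  }
  state@rest <- rest
  state
}

## rest-configuration coordinates of a triangle's three stored vertices
restCoords <- function(rest, t) cbind(c(0, 0), rest[, , t])

## children of splitting triangle `t0` (vertex ids vv) along edge (a, b)
## at new vertex `newId`: returns triangles (2 x 3) and rest array, with
## orientation matched to current positions
splitTriangleAt <- function(v, tri, rest, t0, a, b, newId) {
  vv <- tri[t0, ]
  cI <- setdiff(vv, c(a, b))
  rp <- restCoords(rest, t0)
  pos <- list()
  pos[[as.character(vv[1])]] <- rp[, 1]
  pos[[as.character(vv[2])]] <- rp[, 2]
  pos[[as.character(vv[3])]] <- rp[, 3]
  pos[[as.character(newId)]] <- (pos[[as.character(a)]] +
                                   pos[[as.character(b)]]) / 2
  mk <- function(t3) {
    p1 <- pos[[as.character(t3[1])]]
    p2 <- pos[[as.character(t3[2])]]
    p3 <- pos[[as.character(t3[3])]]
    cbind(p2 - p1, p3 - p1)
  }
  ## orient children by the rest configuration (well-conditioned even when
  ## the current element is a crushed sliver); rest and current
  ## orientations agree for any valid parent
  orient <- function(t3) {
    r <- mk(t3)
    if (r[1, 1] * r[2, 2] - r[1, 2] * r[2, 1] < 0) t3[c(1, 3, 2)] else t3
  }
  t1 <- orient(c(a, newId, cI)); t2 <- orient(c(newId, b, cI))
  rst <- array(0, c(2, 2, 2))
  rst[, , 1] <- mk(t1); rst[, , 2] <- mk(t2)
  list(tris = rbind(t1, t2), rest = rst)
}

## split every edge longer than `thr` (boundary and interior); updates
## mesh, rest shapes, conc, tissue, differentiated flags and the margin
## chain.  Interior splits keep sliver formation under anisotropic growth
## in check; boundary splits refine the margin as it extends.
remeshEdges <- function(state, thr) {
  repeat {
    v <- state@vertices; tri <- state@triangles
    em <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    first <- !duplicated(key)
    el <- sqrt(rowSums((v[em[first, 2], , drop = FALSE] -
                          v[em[first, 1], , drop = FALSE])^2))
    long <- which(el > thr)
    if (!length(long)) break
    eidx <- which(first)[long[which.max(el[long])]]
    a <- em[eidx, 1]; b <- em[eidx, 2]
    own <- which(vapply(seq_len(nrow(tri)), function(t)
      all(c(a, b) %in% tri[t, ]), TRUE))
    newId <- nrow(v) + 1L
    v <- rbind(v, (v[a, ] + v[b, ]) / 2)
    newTris <- list(); newRest <- list()
    for (t0 in own) {
      sp <- splitTriangleAt(v, tri, state@rest, t0, a, b, newId)
      newTris[[length(newTris) + 1]] <- sp$tris
      newRest[[length(newRest) + 1]] <- sp$rest
    }
    keep <- setdiff(seq_len(nrow(tri)), own)
    addT <- do.call(rbind, newTris)
    tri2 <- rbind(tri[keep, , drop = FALSE], addT)
    rest2 <- array(0, c(2, 2, nrow(tri2)))
    rest2[, , seq_along(keep)] <- state@rest[, , keep]
    for (k in seq_along(own))
      rest2[, , length(keep) + (2 * k - 1):(2 * k)] <- newRest[[k]]
    tissue2 <- c(state@tissue[keep],
                 rep(state@tissue[own], each = 2))
    diff2 <- c(state@differentiated[keep],
               rep(state@differentiated[own], each = 2))
    conc2 <- c(state@conc, (state@conc[a] + state@conc[b]) / 2)
    marg <- state@margin
    if (length(own) == 1) {
      ## boundary edge: insert a margin cell between a and b
      ia <- match(a, marg$vertex); ib <- match(b, marg$vertex)
      if (!is.na(ia) && !is.na(ib)) {
        newRow <- data.frame(vertex = newId,
                             auxin = mean(marg$auxin[c(ia, ib)]),
                             cuc = mean(marg$cuc[c(ia, ib)]),
                             isMax = FALSE,
                             differentiated = marg$differentiated[ia] &&
                               marg$differentiated[ib])
        pos <- min(ia, ib)
        if (abs(ia - ib) == nrow(marg) - 1) pos <- nrow(marg)  # wrap edge
        marg <- rbind(marg[seq_len(pos), ], newRow,
                      if (pos < nrow(marg)) marg[seq(pos + 1, nrow(marg)), ])
        rownames(marg) <- NULL
      }
    }
    state <- new("TissueState", vertices = v, triangles = tri2, rest = rest2,
                 tissue = tissue2, differentiated = diff2, conc = conc2,
                 margin = marg, baseVertices = state@baseVertices,
                 time = state@time)
  }
  state
}

#' Simulate tissue development
#'
#' Full loop of the tissue model (margin reaction, differentiation factor,
#' specified growth, growth and elastic relaxation, boundary remeshing)
#' from the initiation start to \code{tEnd}.  Deterministic given the
#' configuration seed.
#'
#' @param config a \linkS4class{TissueConfig}.
#' @param saveEvery interval between recorded snapshots (day).
#' @return list with \code{states} (named list of \linkS4class{TissueState}
#'   snapshots), \code{growth} (per-snapshot-interval data.frame of
#'   per-triangle resultant growth: \code{area_ext_pct}, \code{ratio},
#'   \code{pct}, \code{orientation_deg}, \code{tissue},
#'   \code{differentiated}, centroid position) and \code{config}.
#' @export
simulateTissue <- function(config, saveEvery = 1) {
  state <- initPrimordium(config)
  baseThr <- config@remeshFactor * {
    bnd <- meshBoundary(state@vertices, state@triangles)
    mean(sqrt(rowSums((state@vertices[c(bnd[-1], bnd[1]), ] -
                         state@vertices[bnd, ])^2)))
  }
  L0 <- diff(range(state@vertices[, 2]))
  states <- list(); growth <- list()
  states[[sprintf("%g", state@time)]] <- state
  lastSave <- state
  nstep <- round((config@tEnd - config@initiationStart) / config@dtGrowth)
  for (i in seq_len(nstep)) {
    tNew <- config@initiationStart + i * config@dtGrowth
    if (config@patterningEnabled && state@time >= config@initiationEnd) {
      for (s in seq_len(as.integer(config@reactionSubsteps)))
        state@margin <- marginReactionStep(
          state@margin, config, config@dtGrowth / config@reactionSubsteps)
    }
    state@time <- tNew
    state <- updateDiffFactor(state, config, config@dtGrowth)
    spec <- specifiedGrowth(state, config)
    state <- growAndRelax(state, spec, config, config@dtGrowth)
    ## element size tracks organ scale so the mesh stays tractable
    thr <- baseThr * sqrt(max(1, diff(range(state@vertices[, 2])) / L0))
    state <- remeshEdges(state, thr)
    if (abs(tNew / saveEvery - round(tNew / saveEvery)) < 1e-9 ||
        i == nstep) {
      states[[sprintf("%g", tNew)]] <- state
      growth[[length(growth) + 1]] <-
        resultantGrowth(lastSave, state)
      lastSave <- state
    }
  }
  list(states = states, growth = growth, config = config)
}

## resultant growth of each triangle of the earlier snapshot over the
## interval to the later snapshot, matching triangles of s0 to the
## positions of their (possibly split) material in s1 via shared vertices
resultantGrowth <- function(s0, s1) {
  tri0 <- s0@triangles
  n0 <- nrow(s0@vertices)
  v1 <- s1@vertices
  rows <- lapply(seq_len(nrow(tri0)), function(t) {
    vv <- tri0[t, ]
    if (any(vv > nrow(v1))) return(NULL)
    p0 <- s0@vertices[vv, ]
    p1 <- v1[vv, ]
    Fm <- tryCatch({
      D0 <- cbind(p0[2, ] - p0[1, ], p0[3, ] - p0[1, ])
      D1 <- cbind(p1[2, ] - p1[1, ], p1[3, ] - p1[1, ])
      D1 %*% solve(D0)
    }, error = function(e) NULL)
    if (is.null(Fm)) return(NULL)
    ps <- principalStretches(Fm)
    cen <- colMeans(p0)
    data.frame(tri = t, t_from = s0@time, t_to = s1@time,
               area_ext_pct = 100 * (abs(det(Fm)) - 1),
               ratio = ps$kmax / ps$kmin,
               pct = 100 * (1 - ps$kmin / ps$kmax),
               orientation_deg = ps$orientation,
               tissue = s0@tissue[t], differentiated = s0@differentiated[t],
               x = cen[1], y = cen[2])
  })
  do.call(rbind, rows)
}
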