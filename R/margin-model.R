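## Geometric model of leaf-margin development.
##
## The margin is a 1D sequence of material sample points along the leaf edge.
## Patterning is growth-driven: competent (CUC2-expressing) intervals that
## exceed a threshold arc length are broken by an auxin convergence point,
## which then drives lateral outgrowth; the margin extends with a basipetal
## growth gradient while a differentiation line recedes from the tip toward
## the base; localized (RCO-type) repression at protrusion bases narrows
## them, up to a petiolate (stalked) form when the repression zone is
## extended into the protrusion base.

## internal constant: extension factor of the repression zone in
## "extend_into_base" mode, relative to rcoExtent
.rcoBaseFactor <- 3

#' Margin model parameters
#'
#' Constructor with the wild-type reference defaults used throughout the
#' package (see the methods vignette for the rationale behind each value).
#'
#' @param initLength initial margin length (um).
#' @param nPoints initial number of sample points.
#' @param gLong baseline longitudinal relative growth rate (1/day).
#' @param gradientFloor growth multiplier beyond the growth zone.
#' @param growthZone proximal elevated-growth region length (um).
#' @param competenceZone normalized arc interval competent for convergence
#'   points.
#' @param LThresh interval break length (um).
#' @param tPatternEnd end of patterning (DAI).
#' @param vOut outgrowth rate at convergence points (um/day).
#' @param wOut outgrowth kernel half-width (um).
#' @param rcoStrength repression depth in [0,1].
#' @param rcoExtent repression zone half-width (um).
#' @param rcoMode \code{"flank_only"} or \code{"extend_into_base"}.
#' @param cpGap non-competent gap width around a new convergence point (um).
#' @param diffSpeed differentiation-line speed (normalized arc/day).
#' @param diffStart time the differentiation line starts moving (DAI).
#' @param diffFactor post-differentiation growth multiplier.
#' @param dt time step (day).
#' @param tStart,tEnd simulation window (DAI).
#' @param seed integer, recorded for provenance (the model is deterministic).
#' @return a validated \linkS4class{MarginParams}.
#' @examples
#' p <- marginParams()
#' s <- initMargin(p)
#' marginLength(s)
#' @export
marginParams <- function(initLength = 100, nPoints = 60,
                         gLong = 0.45, gradientFloor = 0.08,
                         growthZone = 160, competenceZone = c(0.02, 0.98),
                         LThresh = 45, tPatternEnd = 6,
                         vOut = 18, wOut = 12,
                         rcoStrength = 0, rcoExtent = 8,
                         rcoMode = "flank_only", cpGap = 10,
                         diffSpeed = 0.13, diffStart = 2.5, diffFactor = 0.12,
                         dt = 0.02, tStart = 2, tEnd = 7, seed = 1L) {
  obj <- new("MarginParams", initLength = initLength, nPoints = nPoints,
             gLong = gLong, gradientFloor = gradientFloor,
             growthZone = growthZone, competenceZone = competenceZone,
             LThresh = LThresh, tPatternEnd = tPatternEnd,
             vOut = vOut, wOut = wOut, rcoStrength = rcoStrength,
             rcoExtent = rcoExtent, rcoMode = rcoMode, cpGap = cpGap,
             diffSpeed = diffSpeed, diffStart = diffStart,
             diffFactor = diffFactor, dt = dt, tStart = tStart, tEnd = tEnd,
             seed = seed)
  msg <- validObject(obj, test = TRUE)
  if (is.character(msg)) stop("invalid margin parameters: ",
                              paste(msg, collapse = "; "))
  obj
}

## basipetal growth gradient: 1 at the base declining linearly to
## gradientFloor at the growth-zone boundary, floor beyond
marginGradient <- function(arc, params) {
  gz <- params@growthZone
  if (gz <= 0) return(rep(params@gradientFloor, length(arc)))
  f <- 1 - (1 - params@gradientFloor) * pmin(arc, gz) / gz
  f
}

#' Initialize the margin
#'
#' Straight margin of the configured initial length with one competent
#' (CUC2) interval spanning the competence zone, no convergence points, and
#' the differentiation line at the distal end.
#'
#' @param params a \linkS4class{MarginParams}.
#' @return a \linkS4class{MarginState} at \code{tStart}.
#' @export
initMargin <- function(params) {
  msg <- validObject(params, test = TRUE)
  if (is.character(msg)) stop("invalid margin parameters: ",
                              paste(msg, collapse = "; "))
  n <- as.integer(params@nPoints)
  arc <- seq(0, params@initLength, length.out = n)
  s <- arc / params@initLength
  comp <- s >= params@competenceZone[1] & s <= params@competenceZone[2] &
    params@competenceZone[2] > params@competenceZone[1]
  pts <- data.frame(arc = arc, offset = 0, competent = comp,
                    isCP = FALSE, differentiated = FALSE, repression = 1,
                    outgrowth = 0)
  new("MarginState", points = pts, time = params@tStart, diffFront = 1)
}

#' One growth step of the margin
#'
#' Multiplicative exponential update of each inter-point segment with the
#' basipetal gradient, local repression and the post-differentiation factor;
#' basipetal advance of the differentiation line; Gaussian-kernel lateral
#' outgrowth at convergence points; resampling where point spacing exceeds
#' twice the initial spacing.
#'
#' @param state a \linkS4class{MarginState}.
#' @param params a \linkS4class{MarginParams}.
#' @return the updated \linkS4class{MarginState} (time advanced by
#'   \code{dt}).
#' @export
growMarginStep <- function(state, params) {
  p <- state@points
  n <- nrow(p)
  t1 <- state@time + params@dt
  L <- p$arc[n]

  ## differentiation line recedes basipetally at its configured speed
  front <- if (t1 <= params@diffStart) 1 else
    max(0, 1 - params@diffSpeed * (t1 - params@diffStart))
  sNorm <- p$arc / L
  p$differentiated <- p$differentiated | (sNorm > front)

  ## segment-wise exponential growth
  seg <- diff(p$arc)
  mid <- (p$arc[-1] + p$arc[-n]) / 2
  grad <- marginGradient(mid, params)
  rep_ <- (p$repression[-1] + p$repression[-n]) / 2
  dfac <- ifelse(p$differentiated[-1] & p$differentiated[-n],
                 params@diffFactor, 1)
  seg <- seg * exp(params@gLong * grad * rep_ * dfac * params@dt)
  p$arc <- c(0, cumsum(seg))

  ## lateral outgrowth: each point carries a material outgrowth competence
  ## (a Gaussian kernel assigned when its convergence point was inserted,
  ## advected with the tissue), modulated by the basipetal growth gradient
  ## (outgrowth is growth) and reduced after differentiation
  if (params@vOut > 0 && any(p$outgrowth > 0)) {
    dOut <- params@vOut * p$outgrowth * marginGradient(p$arc, params) *
      ifelse(p$differentiated, params@diffFactor, 1)
    p$offset <- p$offset + dOut * params@dt
  }

  ## resample where spacing exceeds 2x the initial spacing
  thr <- 2 * params@initLength / (params@nPoints - 1)
  wide <- which(diff(p$arc) > thr)
  if (length(wide)) {
    add <- lapply(wide, function(i) {
      data.frame(arc = (p$arc[i] + p$arc[i + 1]) / 2,
                 offset = (p$offset[i] + p$offset[i + 1]) / 2,
                 competent = p$competent[i] & p$competent[i + 1],
                 isCP = FALSE,
                 differentiated = p$differentiated[i] & p$differentiated[i + 1],
                 repression = (p$repression[i] + p$repression[i + 1]) / 2,
                 outgrowth = (p$outgrowth[i] + p$outgrowth[i + 1]) / 2)
    })
    p <- rbind(p, do.call(rbind, add))
    p <- p[order(p$arc), ]
    rownames(p) <- NULL
  }

  new("MarginState", points = p, time = t1, diffFront = front)
}

#' Break over-threshold CUC2 intervals with convergence points
#'
#' Every maximal competent, non-differentiated interval whose arc length
#' exceeds \code{LThresh} receives a convergence point at its midpoint
#' (intervals processed proximal to distal).  A non-competent gap of width
#' \code{cpGap} opens around the new point and the configured repression
#' profile is attached.  No-op once \code{time >= tPatternEnd}.
#'
#' @inheritParams growMarginStep
#' @return the updated \linkS4class{MarginState}.
#' @export
breakIntervals <- function(state, params) {
  if (state@time >= params@tPatternEnd) return(state)
  p <- state@points
  ok <- p$competent & !p$differentiated
  if (!any(ok)) return(state)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  newCP <- numeric(0)
  for (k in runs) {  # proximal -> distal
    i0 <- starts[k]; i1 <- ends[k]
    if (i1 - i0 < 1) next
    len <- p$arc[i1] - p$arc[i0]
    if (len > params@LThresh)
      newCP <- c(newCP, (p$arc[i0] + p$arc[i1]) / 2)
  }
  if (!length(newCP)) return(state)
  for (a in newCP) {
    off <- stats::approx(p$arc, p$offset, xout = a)$y
    p <- rbind(p, data.frame(arc = a, offset = off, competent = TRUE,
                             isCP = TRUE, differentiated = FALSE,
                             repression = 1, outgrowth = 1))
    p <- p[order(p$arc), ]
    d <- abs(p$arc - a)
    ## material outgrowth competence assigned at insertion time
    p$outgrowth <- pmax(p$outgrowth, exp(-d^2 / (2 * params@wOut^2)))
    ## competence gap (the new point itself loses competence for future
    ## patterning; its isCP flag records that it was competent at insertion)
    p$competent[d <= params@cpGap / 2] <- FALSE
    ## repression profile
    if (params@rcoStrength > 0) {
      zone <- if (params@rcoMode == "flank_only")
        d > params@cpGap / 2 & d <= params@cpGap / 2 + params@rcoExtent
      else
        d > params@cpGap / 2 &
          d <= params@cpGap / 2 + .rcoBaseFactor * params@rcoExtent
      p$repression[zone] <- pmin(p$repression[zone], 1 - params@rcoStrength)
    }
  }
  rownames(p) <- NULL
  new("MarginState", points = p, time = state@time, diffFront = state@diffFront)
}

#' Simulate margin development
#'
#' Iterates \code{\link{growMarginStep}} and \code{\link{breakIntervals}}
#' from \code{tStart} to \code{tEnd}.  Fully deterministic given the
#' parameters.
#'
#' @param params a \linkS4class{MarginParams}.
#' @param outputTimes times (DAI) at which to record states; defaults to
#'   whole days plus the final time.
#' @return named list of \linkS4class{MarginState} objects (names = times).
#' @export
simulateMargin <- function(params, outputTimes = NULL) {
  if (is.null(outputTimes)) {
    outputTimes <- unique(c(seq(ceiling(params@tStart), params@tEnd),
                            params@tEnd))
  }
  state <- initMargin(params)
  state <- breakIntervals(state, params)
  out <- list()
  record <- function(st) out[[sprintf("%g", st@time)]] <<- st
  if (any(abs(outputTimes - state@time) < params@dt / 2)) record(state)
  nstep <- round((params@tEnd - params@tStart) / params@dt)
  for (i in seq_len(nstep)) {
    state <- growMarginStep(state, params)
    state <- breakIntervals(state, params)
    if (any(abs(outputTimes - state@time) < params@dt / 2)) record(state)
  }
  out
}

#' Extract the margin silhouette
#'
#' The (arc, offset) curve resampled at uniform arc spacing, together with
#' the arc-length preserving planar lift: x advances by
#' \code{sqrt(dL^2 - d offset^2)} per segment, so that protrusions whose
#' base stops extending while outgrowth continues appear as narrow stalks.
#'
#' @param state a \linkS4class{MarginState}.
#' @param ds output spacing (um).
#' @return data.frame with columns \code{time_dai}, \code{arc_um},
#'   \code{offset_um}, \code{x_um}.
#' @export
extractSilhouette <- function(state, ds = 1) {
  p <- state@points
  curve <- resamplePolyline(cbind(p$arc, p$offset), ds)
  dL <- diff(curve[, 1])
  dO <- diff(curve[, 2])
  dx <- sqrt(pmax(dL^2 - dO^2, (0.02 * dL)^2))
  x <- c(0, cumsum(dx))
  data.frame(time_dai = state@time, arc_um = curve[, 1],
             offset_um = curve[, 2], x_um = x)
}

#' Detect protrusions on a silhouette
#'
#' Finds protrusion tips as offset peaks above a prominence threshold and
#' the flanking sinuses as the lowest intervening points, then computes the
#' triangle metrics (base width, length, asymmetry) on the planar lift, and
#' flags petiolate (stalked) protrusions: a contiguous height band of at
#' least 15% of the protrusion length, in the lower half, where the local
#' width falls below half of the maximal width above it.
#'
#' @param sil silhouette data.frame from \code{\link{extractSilhouette}}.
#' @param prominence minimum peak prominence (um).
#' @return data.frame with one row per protrusion: \code{tip_arc},
#'   \code{tip_x}, \code{height}, \code{base_width}, \code{length},
#'   \code{asymmetry}, \code{ratio}, \code{stalked}.
#' @export
detectProtrusions <- function(sil, prominence = 2) {
  y <- sil$offset_um
  pk <- findPeaks(y, prominence = prominence)
  if (!length(pk))
    return(data.frame(tip_arc = numeric(0), tip_x = numeric(0),
                      height = numeric(0), base_width = numeric(0),
                      length = numeric(0), asymmetry = numeric(0),
                      ratio = numeric(0), stalked = logical(0)))
  n <- length(y)
  bounds <- c(1L, findPeaks(-y, prominence = 0), n)
  res <- lapply(pk, function(i) {
    lo <- max(bounds[bounds < i])
    hi <- min(bounds[bounds > i])
    ## sinus = lowest point on each flank between neighbouring protrusions
    s1 <- lo + which.min(y[lo:i]) - 1L
    s2 <- i + which.min(y[i:hi]) - 1L
    tri <- protrusionTriangle(cbind(sil$x_um, sil$offset_um),
                              landmarks = c(s1, i, s2))
    ## stalk test on the width profile of the lifted outline: a petiolate
    ## protrusion shows a long near-constant-width (vertical-sided) band
    ## well below its basal width; a cone-shaped (flank-repressed or
    ## unrepressed) protrusion narrows steadily instead
    h <- y[i] - max(y[s1], y[s2])
    stalked <- FALSE
    if (h > 0) {
      nb <- 25
      hs <- seq(max(y[s1], y[s2]) + 0.02 * h, y[i] - 0.02 * h,
                length.out = nb)
      wd <- vapply(hs, function(hh) {
        li <- s1:i; ri <- i:s2
        xl <- stats::approx(y[li], sil$x_um[li], xout = hh, ties = "ordered")$y
        xr <- stats::approx(rev(y[ri]), rev(sil$x_um[ri]), xout = hh,
                            ties = "ordered")$y
        abs(xr - xl)
      }, 0)
      if (all(is.finite(wd))) {
        bestLen <- 0; bestMed <- Inf
        for (k0 in seq_len(nb - 1)) {
          for (k1 in seq(k0 + 1, nb)) {
            w <- wd[k0:k1]
            if (max(w) - min(w) <= 0.1 * stats::median(w)) {
              if (k1 - k0 + 1 > bestLen) {
                bestLen <- k1 - k0 + 1
                bestMed <- stats::median(w)
              }
            }
          }
        }
        stalked <- bestLen >= 0.4 * nb && bestMed <= 0.5 * wd[1]
      }
    }
    data.frame(tip_arc = sil$arc_um[i], tip_x = sil$x_um[i], height = y[i],
               base_width = tri["base_width"], length = tri["length"],
               asymmetry = tri["asymmetry"],
               ratio = tri["length"] / max(tri["base_width"], 1e-9),
               stalked = stalked)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Parameter sweep of the margin model
#'
#' Runs the margin simulation over a sweep of parameter values and records
#' protrusion morphospace metrics for each run.
#'
#' @param base a \linkS4class{MarginParams} reference parameter set.
#' @param axes named list: names are \code{MarginParams} fields, values the
#'   vectors to sweep.
#' @param mode \code{"one_at_a_time"} (each axis varied alone around
#'   \code{base}) or \code{"grid"} (Cartesian product).
#' @param prominence protrusion detection prominence (um).
#' @return data.frame with one row per run: the swept parameter values plus
#'   \code{n_protrusions}, \code{mean_length}, \code{mean_base_width},
#'   \code{mean_ratio}, \code{mean_asymmetry}, \code{any_stalked}.
#' @export
sweepParameters <- function(base, axes, mode = c("one_at_a_time", "grid"),
                            prominence = 2) {
  mode <- match.arg(mode)
  stopifnot(is.list(axes), length(names(axes)) == length(axes))
  for (f in names(axes)) {
    if (!f %in% slotNames("MarginParams"))
      stop("unknown MarginParams field: ", f)
    if (!is.numeric(slot(base, f)))
      stop("cannot sweep non-numeric field: ", f)
  }
  combos <- if (mode == "grid") {
    expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  } else {
    do.call(rbind, lapply(names(axes), function(f) {
      d <- as.data.frame(lapply(axes, function(v) NA_real_))
      d <- d[rep(1, length(axes[[f]])), , drop = FALSE]
      d[[f]] <- axes[[f]]
      d
    }))
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    p <- base
    for (f in names(axes)) {
      v <- combos[i, f]
      if (!is.na(v)) slot(p, f) <- v
    }
    states <- simulateMargin(p, outputTimes = p@tEnd)
    st <- states[[length(states)]]
    pr <- detectProtrusions(extractSilhouette(st), prominence = prominence)
    ## the dominant (tallest) protrusion gives count-robust form metrics
    dom <- if (nrow(pr)) pr[which.max(pr$height), ] else NULL
    data.frame(combos[i, , drop = FALSE],
               n_protrusions = nrow(pr),
               dom_length = if (!is.null(dom)) dom$length else NA_real_,
               dom_base_width = if (!is.null(dom)) dom$base_width else NA_real_,
               dom_ratio = if (!is.null(dom)) dom$ratio else NA_real_,
               dom_asymmetry = if (!is.null(dom)) dom$asymmetry else NA_real_,
               mean_length = if (nrow(pr)) mean(pr$length) else NA_real_,
               mean_base_width = if (nrow(pr)) mean(pr$base_width) else NA_real_,
               mean_ratio = if (nrow(pr)) mean(pr$ratio) else NA_real_,
               any_stalked = any(pr$stalked))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
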