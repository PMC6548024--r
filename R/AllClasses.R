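#' @import methods
NULL

## ---------------------------------------------------------------------------
## margin model classes
## ---------------------------------------------------------------------------

#' Parameters of the geometric margin model
#'
#' Container for the 1D margin simulator settings: the basipetal growth
#' gradient, the CUC2 interval-breaking rule that inserts auxin convergence
#' points, the receding differentiation line, convergence-point outgrowth,
#' and localized basal (RCO-type) growth repression.  Construct with
#' \code{\link{marginParams}}.
#'
#' @slot initLength initial margin length (um).
#' @slot nPoints number of sample points at initialization.
#' @slot gLong baseline longitudinal relative growth rate (1/day).
#' @slot gradientFloor growth multiplier at and beyond the growth-zone
#'   boundary (the basipetal gradient declines linearly from 1 at the base).
#' @slot growthZone length of the proximal elevated-growth region (um).
#' @slot competenceZone normalized arc interval (length 2, in [0,1])
#'   competent to form convergence points.
#' @slot LThresh CUC2-interval break length (um).
#' @slot tPatternEnd time after which no new convergence points form (DAI).
#' @slot vOut outgrowth rate at convergence points (um/day).
#' @slot wOut lateral half-width of the Gaussian outgrowth kernel (um).
#' @slot rcoStrength repression depth in [0,1] (0 = none).
#' @slot rcoExtent arc half-width of the repression zone flanking each
#'   convergence point (um).
#' @slot rcoMode \code{"flank_only"} or \code{"extend_into_base"}.
#' @slot cpGap arc width of the non-competent gap opened around a new
#'   convergence point (um).
#' @slot diffSpeed speed of the differentiation line in normalized arc
#'   coordinates (fraction/day, moving distal to proximal).
#' @slot diffStart time at which the differentiation line starts moving (DAI).
#' @slot diffFactor growth multiplier applied distal to the differentiation
#'   line (< 1).
#' @slot dt time step (day).
#' @slot tStart,tEnd simulation start and end times (DAI).
#' @slot seed integer seed (the model is deterministic; the seed is recorded
#'   for provenance).
#' @export
setClass("MarginParams", representation(
  initLength = "numeric", nPoints = "numeric",
  gLong = "numeric", gradientFloor = "numeric", growthZone = "numeric",
  competenceZone = "numeric", LThresh = "numeric", tPatternEnd = "numeric",
  vOut = "numeric", wOut = "numeric",
  rcoStrength = "numeric", rcoExtent = "numeric", rcoMode = "character",
  cpGap = "numeric",
  diffSpeed = "numeric", diffStart = "numeric", diffFactor = "numeric",
  dt = "numeric", tStart = "numeric", tEnd = "numeric", seed = "numeric"))

setValidity("MarginParams", function(object) {
  msgs <- character(0)
  num1 <- function(x) length(x) == 1 && is.finite(x)
  chk <- function(ok, msg) if (!ok) msgs <<- c(msgs, msg)
  chk(num1(object@initLength) && object@initLength > 0, "initLength must be > 0")
  chk(num1(object@nPoints) && object@nPoints >= 4, "nPoints must be >= 4")
  chk(num1(object@gLong) && object@gLong >= 0, "gLong must be >= 0")
  chk(num1(object@gradientFloor) && object@gradientFloor >= 0,
      "gradientFloor must be >= 0")
  chk(num1(object@growthZone) && object@growthZone >= 0, "growthZone must be >= 0")
  chk(length(object@competenceZone) == 2 &&
        all(object@competenceZone >= 0 & object@competenceZone <= 1) &&
        object@competenceZone[1] <= object@competenceZone[2],
      "competenceZone must be an ordered interval inside [0,1]")
  chk(num1(object@LThresh) && object@LThresh > 0, "LThresh must be > 0")
  chk(num1(object@vOut) && object@vOut >= 0, "vOut must be >= 0")
  chk(num1(object@wOut) && object@wOut > 0, "wOut must be > 0")
  chk(num1(object@rcoStrength) && object@rcoStrength >= 0 &&
        object@rcoStrength <= 1, "rcoStrength must lie in [0,1]")
  chk(num1(object@rcoExtent) && object@rcoExtent >= 0, "rcoExtent must be >= 0")
  chk(object@rcoMode %in% c("flank_only", "extend_into_base"),
      "rcoMode must be 'flank_only' or 'extend_into_base'")
  chk(num1(object@cpGap) && object@cpGap >= 0, "cpGap must be >= 0")
  chk(num1(object@diffSpeed) && object@diffSpeed >= 0, "diffSpeed must be >= 0")
  chk(num1(object@diffFactor) && object@diffFactor >= 0 &&
        object@diffFactor <= 1, "diffFactor must lie in [0,1]")
  chk(num1(object@dt) && object@dt > 0 && object@dt <= 0.1,
      "dt must lie in (0, 0.1] day")
  chk(object@tEnd >= object@tStart, "tEnd must be >= tStart")
  if (length(msgs)) msgs else TRUE
})

#' State of the 1D margin at one time
#'
#' Ordered sample points of the leaf margin carrying competence,
#' convergence-point, differentiation and repression attributes.
#'
#' @slot points data.frame with columns \code{arc} (um from the leaf base,
#'   strictly increasing), \code{offset} (lateral outgrowth displacement, um,
#'   >= 0), \code{competent}, \code{isCP}, \code{differentiated} (logicals)
#'   and \code{repression} (factor in [0,1] multiplying local longitudinal
#'   growth; 1 = no repression).
#' @slot time days after initiation.
#' @slot diffFront position of the differentiation line in normalized arc
#'   coordinates (1 = distal end; points with normalized arc above the front
#'   are differentiated).
#' @export
setClass("MarginState", representation(
  points = "data.frame", time = "numeric", diffFront = "numeric"))

setValidity("MarginState", function(object) {
  p <- object@points
  need <- c("arc", "offset", "competent", "isCP", "differentiated", "repression")
  if (!all(need %in% names(p)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (nrow(p) >= 2 && any(diff(p$arc) <= 0))
    return("arc positions must be strictly increasing")
  if (any(p$offset < -1e-9)) return("offset must be >= 0")
  if (any(p$repression < -1e-9 | p$repression > 1 + 1e-9))
    return("repression must lie in [0,1]")
  TRUE
})

## ---------------------------------------------------------------------------
## tissue model classes
## ---------------------------------------------------------------------------

#' Configuration of the 2D growing-tissue model
#'
#' All tunable parameters of the tissue simulator: geometry of the initial
#' primordium, per-tissue specified growth rates, the diffusing
#' differentiation factor, the auxin-PIN1-CUC2 margin reaction, the elastic
#' relaxation, and time stepping.  Construct with \code{\link{tissueConfig}},
#' whose defaults are the wild-type calibration documented in the package
#' vignette.
#'
#' @slot initLength,initWidth initial primordium length and width (um).
#' @slot meshRings radial resolution of the structured initial mesh.
#' @slot initiationStart,initiationEnd initiation window (DAI) during which
#'   specified growth is homogeneous and anisotropic.
#' @slot initRatePar,initRatePerp specified growth rates (1/day) along and
#'   across the organ axis during the initiation window.
#' @slot bladeRate isotropic blade rate (1/day) after initiation.
#' @slot midribRatePar,midribRatePerp midrib/petiole rates (1/day) along and
#'   across the local proximodistal axis.
#' @slot diffGrowthFactor multiplier on specified rates after differentiation
#'   (< 1).
#' @slot auxinBoost growth-rate boost factor at margin auxin maxima.
#' @slot cucInhibition growth multiplier (< 1) on margin elements adjacent
#'   to high-CUC2 margin cells.
#' @slot cucRadius number of margin-cell neighbours over which CUC2
#'   inhibition reaches into the tissue (inhibition radius).
#' @slot auxinDiffAccel local fractional reduction of the effective
#'   differentiation-factor level at auxin maxima (auxin accelerates
#'   differentiation).
#' @slot D,kDecay diffusivity (um^2/day) and first-order decay (1/day) of the
#'   basally produced differentiation-repressing factor.
#' @slot cSource fixed factor level on the base boundary.
#' @slot cStar differentiation threshold on the factor level.
#' @slot transportCoef,hExp,auxinDiffusion,auxinProd,auxinDecay,cucRepress,cucRecover,auxinThr,promThr
#'   margin reaction parameters: PIN1 transport coefficient, up-the-gradient
#'   exponent, passive cell-to-cell auxin exchange, auxin production and
#'   decay, CUC2 repression by auxin and recovery rates, the auxin level
#'   above which CUC2 is repressed, and the prominence threshold for
#'   flagging auxin maxima.
#' @slot poisson Poisson ratio of the elastic relaxation (the modulus scales
#'   out of the free-boundary equilibrium).
#' @slot dtGrowth growth time step (day).
#' @slot reactionSubsteps reaction substeps per growth step.
#' @slot tEnd end time (DAI).
#' @slot patterningEnabled logical; FALSE ablates the margin reaction
#'   (the no-patterning convergent form).
#' @slot seed integer seed for the initial reaction perturbation.
#' @export
setClass("TissueConfig", representation(
  initLength = "numeric", initWidth = "numeric", meshRings = "numeric",
  initiationStart = "numeric", initiationEnd = "numeric",
  initRatePar = "numeric", initRatePerp = "numeric",
  bladeRate = "numeric", midribRatePar = "numeric", midribRatePerp = "numeric",
  diffGrowthFactor = "numeric",
  auxinBoost = "numeric", cucInhibition = "numeric", cucRadius = "numeric",
  auxinDiffAccel = "numeric",
  D = "numeric", kDecay = "numeric", cSource = "numeric", cStar = "numeric",
  transportCoef = "numeric", hExp = "numeric",
  auxinDiffusion = "numeric",
  auxinProd = "numeric", auxinDecay = "numeric",
  cucRepress = "numeric", cucRecover = "numeric",
  auxinThr = "numeric", promThr = "numeric",
  poisson = "numeric",
  dtGrowth = "numeric", reactionSubsteps = "numeric", tEnd = "numeric",
  patterningEnabled = "logical", seed = "numeric",
  midribFrac = "numeric", midribTopFrac = "numeric", remeshFactor = "numeric"))

setValidity("TissueConfig", function(object) {
  msgs <- character(0)
  chk <- function(ok, msg) if (!ok) msgs <<- c(msgs, msg)
  chk(object@initLength > 0 && object@initWidth > 0,
      "initLength and initWidth must be > 0")
  chk(object@initiationEnd > object@initiationStart,
      "initiation window must have positive duration")
  chk(all(is.finite(c(object@bladeRate, object@midribRatePar,
                      object@midribRatePerp, object@initRatePar,
                      object@initRatePerp))), "growth rates must be finite")
  chk(object@diffGrowthFactor >= 0 && object@diffGrowthFactor <= 1,
      "diffGrowthFactor must lie in [0,1]")
  chk(object@cucInhibition >= 0 && object@cucInhibition <= 1,
      "cucInhibition must lie in [0,1]")
  chk(object@poisson > -1 && object@poisson < 0.5,
      "poisson must lie in (-1, 0.5)")
  chk(object@dtGrowth > 0, "dtGrowth must be > 0")
  chk(object@D >= 0 && object@kDecay >= 0, "D and kDecay must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' State of the growing tissue
#'
#' Triangulated 2D primordium with tissue-type labels, per-triangle rest
#' configurations (the specified-growth memory), a diffusible differentiation
#' factor on vertices, and the chain of margin cells carrying the
#' auxin-PIN1-CUC2 reaction state.
#'
#' @slot vertices numeric matrix (n x 2) of current positions (um).
#' @slot triangles integer matrix (m x 3) of vertex indices (1-based,
#'   counter-clockwise).
#' @slot rest numeric array (2 x 2 x m): per-triangle rest edge matrix.
#' @slot tissue character per triangle: \code{"blade"},
#'   \code{"midrib_petiole"} or \code{"margin"}.
#' @slot differentiated logical per triangle (monotone in time).
#' @slot conc per-vertex level of the differentiation factor.
#' @slot margin data.frame of margin cells in base-to-base boundary order:
#'   \code{vertex} (index), \code{auxin}, \code{cuc}, \code{isMax},
#'   \code{differentiated}.
#' @slot baseVertices integer indices of base (petiole end) boundary
#'   vertices, the Dirichlet source of the differentiation factor.
#' @slot time DAI.
#' @export
setClass("TissueState", representation(
  vertices = "matrix", triangles = "matrix", rest = "array",
  tissue = "character", differentiated = "logical", conc = "numeric",
  margin = "data.frame", baseVertices = "integer", time = "numeric"))

setValidity("TissueState", function(object) {
  m <- nrow(object@triangles)
  if (length(object@tissue) != m) return("tissue must have one label per triangle")
  if (length(object@differentiated) != m)
    return("differentiated must have one flag per triangle")
  if (!all(dim(object@rest) == c(2, 2, m)))
    return("rest must be a 2 x 2 x nTriangles array")
  if (length(object@conc) != nrow(object@vertices))
    return("conc must have one value per vertex")
  if (!all(object@tissue %in% c("blade", "midrib_petiole", "margin")))
    return("unknown tissue label")
  TRUE
})

## ---------------------------------------------------------------------------
## quantification / data classes
## ---------------------------------------------------------------------------

#' A segmented tissue at one observation time
#'
#' Labeled polygonal cell tessellation: a shared junction (vertex) table and
#' per-cell ordered vertex references, so that junction identity across
#' adjacent cells is explicit.  Construct with
#' \code{\link{segmentedTimepoint}} or read from file with
#' \code{\link{readTessellation}}.
#'
#' @slot time observation time (DAI).
#' @slot vertices data.frame with columns \code{id} (integer, unique),
#'   \code{x}, \code{y} (um).
#' @slot cells named list (names = cell ids) of integer vertex-id vectors in
#'   polygon order.
#' @slot attrs data.frame of optional per-cell attributes with a
#'   \code{cell_id} column (e.g. \code{tissue}, \code{differentiated}).
#' @slot sample sample identifier string.
#' @export
setClass("SegmentedTimepoint", representation(
  time = "numeric", vertices = "data.frame", cells = "list",
  attrs = "data.frame", sample = "character"))

setValidity("SegmentedTimepoint", function(object) {
  v <- object@vertices
  if (!all(c("id", "x", "y") %in% names(v)))
    return("vertices must have columns id, x, y")
  if (anyDuplicated(v$id)) return("duplicate vertex ids")
  if (is.null(names(object@cells)) || anyDuplicated(names(object@cells)))
    return("cells must be uniquely named by cell id")
  allv <- unique(unlist(object@cells, use.names = FALSE))
  if (length(allv) && !all(allv %in% v$id))
    return("cell refers to a missing vertex id")
  if (any(vapply(object@cells, length, 1L) < 3))
    return("every cell needs at least 3 vertices")
  TRUE
})

#' Child-to-parent lineage map between two observation times
#'
#' Total map on the later time point's cells; composable across intervals
#' with \code{\link{composeLineages}}.
#'
#' @slot tFrom,tTo interval endpoints (DAI).
#' @slot parentOf named character vector: names are child cell ids at
#'   \code{tTo}, values the parent cell ids at \code{tFrom}.
#' @export
setClass("LineageMap", representation(
  tFrom = "numeric", tTo = "numeric", parentOf = "character"))

setValidity("LineageMap", function(object) {
  if (object@tTo <= object@tFrom) return("tTo must be > tFrom")
  if (length(object@parentOf) && is.null(names(object@parentOf)))
    return("parentOf must be named by child cell id")
  if (anyDuplicated(names(object@parentOf)))
    return("every child must have exactly one parent")
  TRUE
})

#' Configuration of the synthetic time-lapse generator
#'
#' Defines the leaf-shaped domain, the programmed growth field, the division
#' rule and the observation schedule of a synthetic segmented time-lapse with
#' fully known ground truth.  Construct with \code{\link{synthConfig}}.
#'
#' @slot nCellsInit initial number of cells.
#' @slot domainLength,bladeWidth,petioleFraction,petioleWidth leaf-outline
#'   descriptor (um; petiole sizes relative to blade).
#' @slot growthField list descriptor: \code{type} in \code{"uniform"},
#'   \code{"basipetal"}, \code{"tissue"}, plus type-specific rates (1/day).
#' @slot divisionArea cell-area division threshold (um^2).
#' @slot divisionJitterSD orientation jitter (radians) of the division wall.
#' @slot nTimepoints number of observation times (>= 2).
#' @slot dtDays interval between observations (day).
#' @slot junctionNoiseSD segmentation-jitter noise on junction coordinates
#'   (um), applied after ground truth is recorded.
#' @slot lloydIters Lloyd relaxation iterations of the initial centroidal
#'   Voronoi tessellation.
#' @slot seed integer seed.
#' @export
setClass("SynthConfig", representation(
  nCellsInit = "numeric", domainLength = "numeric", bladeWidth = "numeric",
  petioleFraction = "numeric", petioleWidth = "numeric",
  growthField = "list", divisionArea = "numeric", divisionJitterSD = "numeric",
  nTimepoints = "numeric", dtDays = "numeric", junctionNoiseSD = "numeric",
  lloydIters = "numeric", seed = "numeric"))

setValidity("SynthConfig", function(object) {
  msgs <- character(0)
  chk <- function(ok, msg) if (!ok) msgs <<- c(msgs, msg)
  chk(object@nCellsInit >= 1, "nCellsInit must be >= 1")
  chk(object@nTimepoints >= 2, "nTimepoints must be >= 2")
  chk(object@divisionArea > 0, "divisionArea must be > 0")
  chk(object@domainLength > 0 && object@bladeWidth > 0,
      "domain dimensions must be > 0")
  chk(is.character(object@growthField$type) &&
        object@growthField$type %in% c("uniform", "basipetal", "tissue", "custom"),
      "growthField$type must be uniform, basipetal, tissue or custom")
  if (length(msgs)) msgs else TRUE
})
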