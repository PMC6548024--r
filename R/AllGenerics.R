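#' Observation time accessor
#'
#' @param x an object with a time coordinate (days after initiation).
#' @return numeric time in DAI.
#' @export
setGeneric("timeDai", function(x) standardGeneric("timeDai"))

#' Cell identifiers of a tessellation
#' @param x a \linkS4class{SegmentedTimepoint}.
#' @return character vector of cell ids.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Number of cells
#' @param x a \linkS4class{SegmentedTimepoint}.
#' @return integer.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Cell polygons of a tessellation
#'
#' @param x a \linkS4class{SegmentedTimepoint}.
#' @param ids optional character vector restricting to these cell ids.
#' @return named list of n x 2 coordinate matrices (um), one per cell.
#' @export
setGeneric("cellPolygons", function(x, ids = NULL) standardGeneric("cellPolygons"))

#' Cell adjacency of a tessellation
#'
#' Two cells are adjacent when they share a wall (at least two junctions).
#'
#' @param x a \linkS4class{SegmentedTimepoint}.
#' @return two-column character matrix of adjacent cell-id pairs.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Child-to-parent map of a lineage
#' @param x a \linkS4class{LineageMap}.
#' @return named character vector (names = child ids, values = parent ids).
#' @export
setGeneric("parentMap", function(x) standardGeneric("parentMap"))

#' Interval spanned by a lineage map
#' @param x a \linkS4class{LineageMap}.
#' @return numeric length-2 vector (tFrom, tTo) in DAI.
#' @export
setGeneric("lineageInterval", function(x) standardGeneric("lineageInterval"))

#' Margin sample points of a margin state
#' @param x a \linkS4class{MarginState}.
#' @return data.frame of ordered margin points (see
#'   \linkS4class{MarginState}).
#' @export
setGeneric("marginPoints", function(x) standardGeneric("marginPoints"))

#' Total margin length
#' @param x a \linkS4class{MarginState}.
#' @return arc length of the margin (um).
#' @export
setGeneric("marginLength", function(x) standardGeneric("marginLength"))

#' Outline of a tissue mesh
#'
#' Boundary polygon of the triangulated primordium, traversed
#' counter-clockwise from the base.
#'
#' @param x a \linkS4class{TissueState}.
#' @return n x 2 matrix of boundary vertex positions (um).
#' @export
setGeneric("meshOutline", function(x) standardGeneric("meshOutline"))
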