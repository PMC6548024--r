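## File schemas: labeled tessellation files (versioned plain text), lineage
## and results CSVs, silhouettes as CSV/SVG, YAML configuration, run
## manifests.  All coordinates are planar um, y increasing distally (base
## at y = 0); orientations in degrees in [0, 180).

#' Write a tessellation file
#'
#' Versioned plain-text schema: header lines (\code{version}, \code{units},
#' \code{time_dai}, \code{sample}), vertex records \code{V id x y}, cell
#' records \code{C cell_id v1 v2 ...}, optional attribute records
#' \code{A cell_id key=value ...}.
#'
#' @param tp a \linkS4class{SegmentedTimepoint}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTessellation <- function(tp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# leafmorph tessellation",
               "version 1", "units um",
               sprintf("time_dai %.10g", tp@time),
               sprintf("sample %s", tp@sample)), con)
  v <- tp@vertices
  writeLines(sprintf("V %d %.17g %.17g", v$id, v$x, v$y), con)
  for (cid in names(tp@cells))
    writeLines(paste("C", cid, paste(tp@cells[[cid]], collapse = " ")), con)
  if (nrow(tp@attrs)) {
    for (i in seq_len(nrow(tp@attrs))) {
      kv <- vapply(setdiff(names(tp@attrs), "cell_id"), function(k)
        sprintf("%s=%s", k, tp@attrs[i, k]), "")
      writeLines(paste("A", tp@attrs$cell_id[i], paste(kv, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a tessellation file
#'
#' Strict parser for the schema written by \code{\link{writeTessellation}};
#' schema violations raise errors naming the offending field and line.
#'
#' @param path input file.
#' @return a \linkS4class{SegmentedTimepoint}.
#' @export
readTessellation <- function(path) {
  if (!file.exists(path)) stop("no such tessellation file: ", path)
  lines <- readLines(path)
  perr <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg))
  hdr <- list(version = NA, units = NA, time_dai = NA, sample = "unknown")
  vid <- integer(0); vx <- numeric(0); vy <- numeric(0)
  cells <- list(); attrs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key %in% names(hdr)) {
      hdr[[key]] <- tok[2]
    } else if (key == "V") {
      if (length(tok) != 4) perr(i, "vertex record needs 'V id x y'")
      id <- suppressWarnings(as.integer(tok[2]))
      xy <- suppressWarnings(as.numeric(tok[3:4]))
      if (is.na(id) || anyNA(xy)) perr(i, "malformed vertex record")
      if (id %in% vid) perr(i, paste("duplicate vertex id", id))
      vid <- c(vid, id); vx <- c(vx, xy[1]); vy <- c(vy, xy[2])
    } else if (key == "C") {
      if (length(tok) < 5) perr(i, "cell record needs 'C cell_id v1 v2 v3 ...'")
      cid <- tok[2]
      if (cid %in% names(cells)) perr(i, paste("duplicate cell_id", cid))
      vv <- suppressWarnings(as.integer(tok[-(1:2)]))
      if (anyNA(vv)) perr(i, "malformed vertex reference in cell record")
      miss <- setdiff(vv, vid)
      if (length(miss))
        perr(i, paste("cell", cid, "references missing vertex id",
                      paste(miss, collapse = ", ")))
      cells[[cid]] <- vv
    } else if (key == "A") {
      cid <- tok[2]
      kv <- strsplit(tok[-(1:2)], "=", fixed = TRUE)
      row <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      attrs[[cid]] <- row
    } else perr(i, paste("unknown record type", key))
  }
  if (is.na(hdr$version)) stop(path, ": missing 'version' header")
  if (!identical(hdr$units, "um")) stop(path, ": units must be um")
  tm <- suppressWarnings(as.numeric(hdr$time_dai))
  if (is.na(tm)) stop(path, ": missing or malformed 'time_dai' header")
  bad <- setdiff(unique(names(attrs)), names(cells))
  if (length(bad)) stop(path, ": attribute for unknown cell ",
                        paste(bad, collapse = ", "))
  attrDf <- if (length(attrs)) {
    keys <- unique(unlist(lapply(attrs, names)))
    df <- data.frame(cell_id = names(attrs), stringsAsFactors = FALSE)
    for (k in keys) df[[k]] <- vapply(attrs, function(r)
      if (k %in% names(r)) r[[k]] else NA_character_, "")
    df
  } else data.frame(cell_id = character(0))
  segmentedTimepoint(tm, data.frame(id = vid, x = vx, y = vy), cells,
                     attrs = attrDf, sample = hdr$sample)
}

#' Write / read lineage CSVs
#'
#' Columns \code{t_from}, \code{t_to}, \code{child_id}, \code{parent_id};
#' one row per child.  An empty table (header only) reads back as an empty
#' map.
#'
#' @param lin a \linkS4class{LineageMap}.
#' @param path file path.
#' @return \code{writeLineage}: \code{path} invisibly;
#'   \code{readLineage}: a \linkS4class{LineageMap}.
#' @export
writeLineage <- function(lin, path) {
  df <- if (length(lin@parentOf)) {
    data.frame(t_from = lin@tFrom, t_to = lin@tTo,
               child_id = names(lin@parentOf),
               parent_id = unname(lin@parentOf))
  } else {
    data.frame(t_from = numeric(0), t_to = numeric(0),
               child_id = character(0), parent_id = character(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLineage
#' @param tFrom,tTo interval endpoints used when the file holds no rows.
#' @export
readLineage <- function(path, tFrom = 0, tTo = 1) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read lineage CSV ", path,
                                          ": ", e$message))
  need <- c("t_from", "t_to", "child_id", "parent_id")
  if (!all(need %in% names(df)))
    stop(path, ": lineage CSV must have columns ",
         paste(need, collapse = ", "))
  if (!nrow(df))
    return(lineageMap(tFrom, tTo, stats::setNames(character(0), character(0))))
  bad <- which(is.na(df$child_id) | is.na(df$parent_id))
  if (length(bad)) stop(path, ": malformed lineage row(s) ",
                        paste(bad + 1, collapse = ", "))
  lineageMap(df$t_from[1], df$t_to[1],
             stats::setNames(as.character(df$parent_id),
                             as.character(df$child_id)))
}

#' Write / read growth-record CSVs
#'
#' Deterministic column order; undefined anisotropy (too few matched
#' junctions, or isotropic orientation) stays NA through the round trip.
#'
#' @param df growth-record data.frame (see \code{\link{quantifyGrowth}}).
#' @param path file path.
#' @export
writeGrowthRecords <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeGrowthRecords
#' @export
readGrowthRecords <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read alignment-graph CSVs
#'
#' The measure and distance mode are stored as columns; on read,
#' contribution-mode bins are checked to sum to 100.
#'
#' @param ag alignment-graph data.frame from \code{\link{alignmentGraph}}.
#' @param path file path.
#' @export
writeAlignmentGraph <- function(ag, path) {
  out <- ag
  out$measure <- attr(ag, "measure")
  out$distance_mode <- attr(ag, "distance_mode")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAlignmentGraph
#' @export
readAlignmentGraph <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("measure" %in% names(df) && any(df$measure == "contribution")) {
    s <- sum(df$value)
    if (abs(s - 100) > 0.01)
      stop(path, ": contribution bins sum to ", s, ", expected 100")
  }
  measure <- if ("measure" %in% names(df)) df$measure[1] else NA
  dm <- if ("distance_mode" %in% names(df)) df$distance_mode[1] else NA
  df$measure <- NULL; df$distance_mode <- NULL
  attr(df, "measure") <- measure
  attr(df, "distance_mode") <- dm
  df
}

#' Write / read silhouette CSVs
#'
#' Columns \code{time_dai}, \code{arc_um}, \code{offset_um}, \code{x_um}.
#'
#' @param sil silhouette data.frame from \code{\link{extractSilhouette}}.
#' @param path file path.
#' @export
writeSilhouetteCSV <- function(sil, path) {
  utils::write.table(sil, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeSilhouetteCSV
#' @export
readSilhouetteCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## minimal SVG polyline writer (text-parseable graphics contract)
svgDocument <- function(paths, width, height) {
  body <- vapply(paths, function(p)
    sprintf('<polyline fill="none" stroke="black" stroke-width="0.5" points="%s"/>',
            paste(sprintf("%.3f,%.3f", p[, 1], height - p[, 2]),
                  collapse = " ")), "")
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
            width, height, width, height),
    body, "</svg>")
}

#' Write a silhouette (or outline) as SVG
#'
#' @param xy silhouette data.frame (columns \code{x_um}, \code{offset_um})
#'   or an n x 2 outline matrix.
#' @param path output file.
#' @export
writeSilhouetteSVG <- function(xy, path) {
  p <- if (is.data.frame(xy) && all(c("x_um", "offset_um") %in% names(xy)))
    cbind(xy$x_um, xy$offset_um) else as.matrix(xy)
  p <- sweep(p, 2, apply(p, 2, min))
  writeLines(svgDocument(list(p), max(p[, 1]) + 2, max(p[, 2]) + 2), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## configuration files and manifests
## ---------------------------------------------------------------------------

snakeToCamel <- function(x) {
  gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
}

## build a parameter object from a named list, tolerating snake_case keys
fromConfigList <- function(lst, constructor) {
  if (is.null(lst)) lst <- list()
  names(lst) <- snakeToCamel(names(lst))
  known <- names(formals(constructor))
  ## tolerate case differences left by the snake_case mapping (e.g. *_sd)
  idx <- match(tolower(names(lst)), tolower(known))
  if (anyNA(idx))
    stop("unknown configuration field(s): ",
         paste(names(lst)[is.na(idx)], collapse = ", "))
  names(lst) <- known[idx]
  do.call(constructor, lst)
}

#' Read a configuration file
#'
#' YAML with optional top-level sections \code{margin}, \code{tissue} and
#' \code{synth}; keys may be snake_case or camelCase and map to the
#' arguments of \code{\link{marginParams}}, \code{\link{tissueConfig}} and
#' \code{\link{synthConfig}}.
#'
#' @param path YAML file.
#' @return list with any of the elements \code{margin}, \code{tissue},
#'   \code{synth} (parameter objects) that the file defines.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$margin)) out$margin <- fromConfigList(y$margin, marginParams)
  if (!is.null(y$tissue)) out$tissue <- fromConfigList(y$tissue, tissueConfig)
  if (!is.null(y$synth)) out$synth <- fromConfigList(y$synth, synthConfig)
  if (!length(out))
    stop(path, ": config defines none of the sections margin/tissue/synth")
  out
}

## serialize a parameter object to a plain list (for manifests)
paramsToList <- function(obj) {
  sn <- slotNames(class(obj))
  stats::setNames(lapply(sn, function(s) slot(obj, s)), sn)
}

#' Write a run manifest
#'
#' JSON record of a CLI run: tool version, the fully resolved
#' configuration, seed, input file hashes, outputs and wall-clock time —
#' every output is reconstructible from the manifest plus inputs.
#'
#' @param path output JSON file.
#' @param command CLI subcommand name.
#' @param config parameter object or list of them.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths (hashed if present).
#' @param outputs character vector of output paths.
#' @param elapsed wall-clock seconds.
#' @export
writeManifest <- function(path, command, config, seed = NA,
                          inputs = character(0), outputs = character(0),
                          elapsed = NA) {
  cfg <- if (isVirtualClass(class(config)) || is.list(config))
    lapply(config, paramsToList) else paramsToList(config)
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_, "")
  obj <- list(tool = "leafmorph",
              version = as.character(utils::packageVersion("leafmorph")),
              command = command, config = cfg, seed = seed,
              inputs = as.list(hashes), outputs = as.list(outputs),
              elapsed_sec = elapsed,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
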