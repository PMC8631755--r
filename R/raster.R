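# In-package raster containers. Grids are plain numeric matrices with row 1
# at the northern edge (the ESRI ASCII convention); NA marks nodata, and all
# layers of a stack share one NA mask. Cells are square, in degrees.

#' RasterStack: co-registered named climate grids
#'
#' A minimal multi-layer raster: a named list of equally sized numeric
#' matrices sharing one geotransform (lower-left corner plus square cell
#' size, in degrees) and one nodata mask (`NA` cells, identical across
#' layers). Row 1 is the northernmost row.
#'
#' @slot layers named list of numeric matrices (rows x cols).
#' @slot xmin,ymin numeric, coordinates of the lower-left corner of the grid.
#' @slot cellsize numeric, cell edge length in degrees.
#' @exportClass RasterStack
setClass("RasterStack",
  representation(layers = "list", xmin = "numeric", ymin = "numeric",
                 cellsize = "numeric"))

setValidity("RasterStack", function(object) {
  if (length(object@layers) == 0L) return("stack must hold at least one layer")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    return("layers must have unique names")
  dims <- vapply(object@layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all layers must share the same dimensions")
  msk <- is.na(object@layers[[1]])
  for (l in object@layers)
    if (!identical(is.na(l), msk)) return("all layers must share one nodata mask")
  if (object@cellsize <= 0) return("cellsize must be positive")
  TRUE
})

#' Single-layer grid tagged with a scenario label
#'
#' A suitability surface in \[0, 1\] produced by [ensemblePredict()], plus an
#' optional binary presence grid filled in by [binarize()] and the lowest
#' presence threshold used to produce it.
#'
#' @slot grid numeric matrix of suitabilities; `NA` = nodata.
#' @slot scenario character scenario label ("current" or a future name).
#' @slot binary binary presence matrix (0/1/NA) or a 0 x 0 matrix if unset.
#' @slot lpt numeric threshold used for `binary` (`NA_real_` if unset).
#' @slot xmin,ymin,cellsize geotransform as in [RasterStack-class].
#' @exportClass SuitabilityMap
setClass("SuitabilityMap",
  representation(grid = "matrix", scenario = "character", binary = "matrix",
                 lpt = "numeric", xmin = "numeric", ymin = "numeric",
                 cellsize = "numeric"))

setValidity("SuitabilityMap", function(object) {
  v <- object@grid[!is.na(object@grid)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("suitability values must lie in [0, 1] on unmasked cells")
  if (length(object@binary) &&
      !identical(dim(object@binary), dim(object@grid)))
    return("binary grid must match the suitability grid")
  TRUE
})

#' Dispersal-cost (friction) surface
#'
#' Per-cell dispersal cost derived from a continuous suitability map by
#' [frictionFromSuitability()]. All unmasked costs are at least the
#' `epsilon` floor so that even perfectly suitable terrain accumulates cost.
#'
#' @slot grid numeric matrix of positive costs; `NA` = impassable nodata.
#' @slot source character, scenario label of the suitability map inverted.
#' @slot xmin,ymin,cellsize geotransform as in [RasterStack-class].
#' @exportClass FrictionSurface
setClass("FrictionSurface",
  representation(grid = "matrix", source = "character", xmin = "numeric",
                 ymin = "numeric", cellsize = "numeric"))

setValidity("FrictionSurface", function(object) {
  v <- object@grid[!is.na(object@grid)]
  if (length(v) && min(v) <= 0) return("all unmasked costs must be positive")
  TRUE
})

#' Construct a RasterStack
#'
#' @param layers named list of numeric matrices (row 1 = north).
#' @param xmin,ymin lower-left corner, degrees.
#' @param cellsize cell edge, degrees.
#' @return a [RasterStack-class].
#' @examples
#' r <- rasterStack(list(tmean = matrix(1:12, 3)), 100, 30, 0.5)
#' nLayers(r)
#' @export
rasterStack <- function(layers, xmin = 0, ymin = 0, cellsize = 1) {
  new("RasterStack", layers = layers, xmin = xmin, ymin = ymin,
      cellsize = cellsize)
}

suitabilityMap <- function(grid, scenario, xmin, ymin, cellsize,
                           binary = matrix(numeric(0), 0, 0),
                           lpt = NA_real_) {
  new("SuitabilityMap", grid = grid, scenario = scenario, binary = binary,
      lpt = lpt, xmin = xmin, ymin = ymin, cellsize = cellsize)
}

## ---- generics -------------------------------------------------------------

#' @rdname rasterStack
#' @param x a raster object.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname rasterStack
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' Extract one layer as a matrix
#' @param x a [RasterStack-class].
#' @param name layer name or index.
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' Grid dimensions (rows, cols)
#' @param x a raster object.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' Suitability / cost values as a matrix
#' @param x a single-layer raster object.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' Scenario label of a raster product
#' @param x object carrying a scenario tag.
#' @export
setGeneric("scenarioLabel", function(x) standardGeneric("scenarioLabel"))
#' Binary presence grid of a thresholded suitability map
#' @param x a [SuitabilityMap-class].
#' @export
setGeneric("binaryGrid", function(x) standardGeneric("binaryGrid"))

setMethod("nLayers", "RasterStack", function(x) length(x@layers))
setMethod("layerNames", "RasterStack", function(x) names(x@layers))
setMethod("getLayer", "RasterStack", function(x, name) x@layers[[name]])
setMethod("gridDim", "RasterStack", function(x) dim(x@layers[[1]]))
setMethod("gridDim", "SuitabilityMap", function(x) dim(x@grid))
setMethod("gridDim", "FrictionSurface", function(x) dim(x@grid))
setMethod("gridValues", "SuitabilityMap", function(x) x@grid)
setMethod("gridValues", "FrictionSurface", function(x) x@grid)
setMethod("scenarioLabel", "SuitabilityMap", function(x) x@scenario)
setMethod("scenarioLabel", "FrictionSurface", function(x) x@source)
setMethod("binaryGrid", "SuitabilityMap", function(x) {
  if (!length(x@binary)) NULL else x@binary
})

setMethod("show", "RasterStack", function(object) {
  d <- gridDim(object)
  cat(sprintf("RasterStack: %d layer(s), %d x %d cells, cellsize %g deg\n",
              nLayers(object), d[1], d[2], object@cellsize))
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n", object@xmin,
              object@xmin + d[2] * object@cellsize, object@ymin,
              object@ymin + d[1] * object@cellsize))
})

setMethod("show", "SuitabilityMap", function(object) {
  d <- gridDim(object)
  cat(sprintf("SuitabilityMap [%s]: %d x %d cells", object@scenario,
              d[1], d[2]))
  if (!is.na(object@lpt)) cat(sprintf(", binarized at %.4g", object@lpt))
  cat("\n")
})

setMethod("show", "FrictionSurface", function(object) {
  d <- gridDim(object)
  cat(sprintf("FrictionSurface from '%s': %d x %d cells, cost range [%g, %g]\n",
              object@source, d[1], d[2],
              min(object@grid, na.rm = TRUE), max(object@grid, na.rm = TRUE)))
})

## ---- coordinate helpers ---------------------------------------------------

rasterYmax <- function(x) x@ymin + nrow(if (is(x, "RasterStack")) x@layers[[1]] else x@grid) * x@cellsize

#' Map lon/lat coordinates to grid cells
#'
#' @param x a raster object.
#' @param lon,lat numeric vectors of coordinates.
#' @return integer matrix with columns `row`, `col`; coordinates outside the
#'   grid give `NA`.
#' @export
cellFromXY <- function(x, lon, lat) {
  d <- gridDim(x)
  col <- floor((lon - x@xmin) / x@cellsize) + 1L
  row <- floor((rasterYmax(x) - lat) / x@cellsize) + 1L
  ## points exactly on the top/right edge belong to the edge cell
  col[lon == x@xmin + d[2] * x@cellsize] <- d[2]
  row[lat == x@ymin] <- d[1]
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @param x a raster object.
#' @param cells optional integer matrix (`row`, `col`); default all cells in
#'   column-major order.
#' @return matrix with columns `lon`, `lat`.
#' @export
xyFromCell <- function(x, cells = NULL) {
  d <- gridDim(x)
  if (is.null(cells))
    cells <- cbind(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]))
  lon <- x@xmin + (cells[, 2] - 0.5) * x@cellsize
  lat <- rasterYmax(x) - (cells[, 1] - 0.5) * x@cellsize
  cbind(lon = lon, lat = lat)
}

#' Stack values as a cells-by-layers matrix
#'
#' Unmasked cells only, in column-major cell order; the attribute `cells`
#' holds their (row, col) indices.
#' @param x a [RasterStack-class].
#' @export
stackValues <- function(x) {
  msk <- !is.na(x@layers[[1]])
  keep <- which(as.vector(msk))
  m <- vapply(x@layers, function(l) as.vector(l)[keep],
              numeric(length(keep)))
  m <- matrix(m, nrow = length(keep),
              dimnames = list(NULL, names(x@layers)))
  d <- gridDim(x)
  attr(m, "cells") <- cbind(row = ((keep - 1L) %% d[1]) + 1L,
                            col = ((keep - 1L) %/% d[1]) + 1L)
  m
}

#' Extract layer values at coordinates
#' @param x a [RasterStack-class].
#' @param lon,lat coordinates.
#' @return matrix (points x layers); `NA` rows for masked or outside points.
#' @export
extractValues <- function(x, lon, lat) {
  rc <- cellFromXY(x, lon, lat)
  out <- matrix(NA_real_, length(lon), nLayers(x),
                dimnames = list(NULL, layerNames(x)))
  ok <- !is.na(rc[, 1])
  for (j in seq_len(nLayers(x)))
    out[ok, j] <- x@layers[[j]][rc[ok, , drop = FALSE]]
  out
}

#' Spherically weighted cell areas
#'
#' Cell area in km^2 under the spherical approximation: the area of a
#' `cellsize` x `cellsize` graticule cell scales with cos(latitude).
#'
#' @param x a raster object.
#' @return numeric matrix of per-cell areas (km^2), same shape as the grid.
#' @export
cellAreaKm2 <- function(x) {
  d <- gridDim(x)
  km_per_deg <- pi * 6371.0088 / 180
  lat <- rasterYmax(x) - (seq_len(d[1]) - 0.5) * x@cellsize
  area_row <- (x@cellsize * km_per_deg)^2 * cos(lat * pi / 180)
  matrix(rep(area_row, d[2]), nrow = d[1])
}

## ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-layer raster exchange. `writeAsciiGrid` writes one
#' matrix; `writeStackAscii`/`readStackAscii` handle a whole stack as one
#' `.asc` file per layer in a directory.
#'
#' @param path file path (`.asc`).
#' @return `readAsciiGrid`: a list with `grid`, `xmin`, `ymin`, `cellsize`.
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  dat <- scan(path, skip = 6L, quiet = TRUE)
  g <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == nodata] <- NA_real_
  xmin <- if ("xllcorner" %in% keys) vals[["xllcorner"]] else
    vals[["xllcenter"]] - vals[["cellsize"]] / 2
  ymin <- if ("yllcorner" %in% keys) vals[["yllcorner"]] else
    vals[["yllcenter"]] - vals[["cellsize"]] / 2
  list(grid = g, xmin = xmin, ymin = ymin, cellsize = vals[["cellsize"]])
}

#' @rdname readAsciiGrid
#' @param grid numeric matrix (row 1 = north).
#' @param xmin,ymin,cellsize geotransform.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
writeAsciiGrid <- function(grid, path, xmin = 0, ymin = 0, cellsize = 1,
                           nodata = -9999) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(grid)),
               sprintf("nrows %d", nrow(grid)),
               sprintf("xllcorner %.10g", xmin),
               sprintf("yllcorner %.10g", ymin),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  g <- grid; g[is.na(g)] <- nodata
  writeLines(apply(g, 1L, function(r) paste(format(r, trim = TRUE,
                                                   digits = 15),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname readAsciiGrid
#' @param x a [RasterStack-class].
#' @param dir directory receiving one `<layer>.asc` per layer.
#' @export
writeStackAscii <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in layerNames(x))
    writeAsciiGrid(getLayer(x, nm), file.path(dir, paste0(nm, ".asc")),
                   x@xmin, x@ymin, x@cellsize)
  invisible(dir)
}

#' @rdname readAsciiGrid
#' @export
readStackAscii <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files in ", dir)
  gs <- lapply(files, readAsciiGrid)
  layers <- lapply(gs, `[[`, "grid")
  names(layers) <- sub("\\.asc$", "", basename(files))
  rasterStack(layers, gs[[1]]$xmin, gs[[1]]$ymin, gs[[1]]$cellsize)
}
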