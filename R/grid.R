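#' Construct a GridLayer
#'
#' @param name layer name.
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xmin,ymin western/southern grid edges (degrees, WGS84).
#' @param cellsize cell size in degrees.
#' @return A [GridLayer-class].
#' @export
gridLayer <- function(name, values, xmin, ymin, cellsize) {
  new("GridLayer", name = name, values = values,
      xmin = xmin, ymin = ymin, cellsize = cellsize)
}

#' Construct a GridStack from GridLayer objects
#'
#' @param ... [GridLayer-class] objects (or a single list of them).
#' @return A [GridStack-class]; layer names come from the layers.
#' @export
gridStack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !is(layers[[1]], "GridLayer"))
    layers <- layers[[1]]
  names(layers) <- vapply(layers, function(l) l@name, "")
  new("GridStack", layers = layers)
}

#' @rdname gridAccessors
#' @export
setGeneric("gridValues", function(x, ...) standardGeneric("gridValues"))

#' Grid accessors
#'
#' `gridValues()` returns the value matrix of a layer (or a named list for a
#' stack); `cellSize()` the cell size in degrees; `gridExtent()` the
#' `c(xmin, xmax, ymin, ymax)` extent; `layerNames()` the layer names of a
#' stack; `cellCentres()` a data.frame of cell-centre lon/lat (row-major,
#' north to south).
#'
#' @param x a [GridLayer-class] or [GridStack-class].
#' @param ... unused.
#' @name gridAccessors
#' @aliases gridValues cellSize gridExtent layerNames cellCentres
NULL

#' @rdname gridAccessors
#' @export
setMethod("gridValues", "GridLayer", function(x, ...) x@values)
#' @rdname gridAccessors
#' @export
setMethod("gridValues", "GridStack", function(x, ...)
  lapply(x@layers, function(l) l@values))

#' @rdname gridAccessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname gridAccessors
#' @export
setMethod("cellSize", "GridLayer", function(x) x@cellsize)
#' @rdname gridAccessors
#' @export
setMethod("cellSize", "GridStack", function(x) x@layers[[1]]@cellsize)

#' @rdname gridAccessors
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))
#' @rdname gridAccessors
#' @export
setMethod("gridExtent", "GridLayer", function(x) {
  d <- dim(x@values)
  c(xmin = x@xmin, xmax = x@xmin + d[2] * x@cellsize,
    ymin = x@ymin, ymax = x@ymin + d[1] * x@cellsize)
})
#' @rdname gridAccessors
#' @export
setMethod("gridExtent", "GridStack", function(x) gridExtent(x@layers[[1]]))

#' @rdname gridAccessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname gridAccessors
#' @export
setMethod("layerNames", "GridStack", function(x) names(x@layers))

#' @rdname gridAccessors
#' @export
setGeneric("cellCentres", function(x) standardGeneric("cellCentres"))
#' @rdname gridAccessors
#' @export
setMethod("cellCentres", "GridLayer", function(x) {
  d <- dim(x@values)
  ymax <- x@ymin + d[1] * x@cellsize
  lon <- x@xmin + (seq_len(d[2]) - 0.5) * x@cellsize
  lat <- ymax - (seq_len(d[1]) - 0.5) * x@cellsize
  # row-major ordering: cell (i, j) at index (i-1)*ncol + j
  data.frame(lon = rep(lon, times = d[1]), lat = rep(lat, each = d[2]))
})
#' @rdname gridAccessors
#' @export
setMethod("cellCentres", "GridStack", function(x) cellCentres(x@layers[[1]]))

setMethod("show", "GridLayer", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridLayer '%s': %d x %d cells, cellsize %.4g deg, origin (%.4g, %.4g)\n",
              object@name, d[1], d[2], object@cellsize, object@xmin, object@ymin))
})

setMethod("show", "GridStack", function(object) {
  d <- dim(object@layers[[1]]@values)
  cat(sprintf("GridStack: %d layer(s) [%s], %d x %d cells, cellsize %.4g deg\n",
              length(object@layers), paste(names(object@layers), collapse = ", "),
              d[1], d[2], object@layers[[1]]@cellsize))
})

# matrix of values in cell-centre (row-major) order, as used by cellCentres()
gridVector <- function(layer) as.vector(t(layer@values))

gridFromVector <- function(template, v, name = template@name) {
  m <- matrix(v, nrow = nrow(template@values), byrow = TRUE)
  gridLayer(name, m, template@xmin, template@ymin, template@cellsize)
}

#' Resample a raster stack to a coarser resolution by block means
#'
#' Aggregates every layer of a stack to a common target resolution using the
#' mean of the contributing fine cells (the analysis resolution of the
#' mapping procedure is 5 arc minutes, about 10 x 10 km near the equator).
#' Nodata cells are excluded from block means; a block that is entirely
#' nodata stays nodata.
#'
#' @param stack a [GridStack-class] (all layers already on one grid).
#' @param targetResolution target cell size in degrees; must be an integer
#'   multiple of the input cell size. Default `5/60` (5 arc minutes).
#' @return A [GridStack-class] at the target resolution.
#' @export
resampleStack <- function(stack, targetResolution = 5 / 60) {
  cs <- cellSize(stack)
  f <- targetResolution / cs
  stopIfNot(abs(f - round(f)) < 1e-8 && f >= 1,
            "targetResolution must be an integer multiple of the cell size")
  f <- as.integer(round(f))
  if (f == 1L) return(stack)
  layers <- lapply(stack@layers, function(l) {
    v <- l@values
    nr <- nrow(v) %/% f
    nc <- ncol(v) %/% f
    stopIfNot(nr >= 1 && nc >= 1, "grid smaller than one target cell")
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      rows <- ((i - 1) * f + 1):(i * f)
      for (j in seq_len(nc)) {
        block <- v[rows, ((j - 1) * f + 1):(j * f)]
        if (any(is.finite(block))) out[i, j] <- mean(block, na.rm = TRUE)
      }
    }
    # northern edge is preserved; ymin moves up if rows don't divide evenly
    ymax <- l@ymin + nrow(v) * cs
    gridLayer(l@name, out, l@xmin, ymax - nr * f * cs, f * cs)
  })
  gridStack(layers)
}

#' Sample raster values at point locations
#'
#' Looks up, for every point and layer, the value of the grid cell containing
#' the point. Cells are half-open `[x, x + dx) x (y - dy, y]`, so points on
#' shared edges fall in exactly one cell. Points outside the grid or in
#' nodata cells are flagged.
#'
#' @param stack a [GridStack-class].
#' @param points data.frame or matrix with `lon`, `lat` columns.
#' @return data.frame with one column per layer plus a logical `valid`
#'   column (FALSE where the point is outside the extent or any layer is
#'   nodata there).
#' @export
sampleAtPoints <- function(stack, points) {
  pts <- as.data.frame(points)
  g <- stack@layers[[1]]
  d <- dim(g@values)
  ymax <- g@ymin + d[1] * g@cellsize
  col <- floor((pts$lon - g@xmin) / g@cellsize) + 1
  # row 1 is the northern band (ymax - dy, ymax]
  row <- ceiling((ymax - pts$lat) / g@cellsize)
  row[pts$lat == ymax] <- 1
  inside <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1] &
    !is.na(col) & !is.na(row)
  out <- data.frame(row.names = seq_len(nrow(pts)))
  for (nm in names(stack@layers)) {
    v <- rep(NA_real_, nrow(pts))
    idx <- cbind(row[inside], col[inside])
    v[inside] <- stack@layers[[nm]]@values[idx]
    out[[nm]] <- v
  }
  out$valid <- inside & stats::complete.cases(out)
  out
}

#' Read / write a grid layer as ESRI ASCII grid
#'
#' Plain-text raster interchange used for all gridded outputs (final maps,
#' prediction-interval bounds, covariate layers).
#'
#' @param layer a [GridLayer-class].
#' @param path output file path.
#' @param nodata nodata marker written to the file.
#' @return `readAsciiGrid` returns a [GridLayer-class].
#' @export
writeAsciiGrid <- function(layer, path, nodata = -9999) {
  v <- layer@values
  v[!is.finite(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", layer@xmin),
           sprintf("yllcorner %.10g", layer@ymin),
           sprintf("cellsize %.10g", layer@cellsize),
           sprintf("NODATA_value %g", nodata))
  writeLines(c(hdr, apply(v, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @param name layer name given to the grid read back in.
#' @export
readAsciiGrid <- function(path, name = basename(path)) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- function(key) {
    i <- which(vapply(hdr, `[`, "", 1) == key)
    as.numeric(hdr[[i]][2])
  }
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v[v == val("nodata_value")] <- NA
  gridLayer(name, v, val("xllcorner"), val("yllcorner"), val("cellsize"))
}
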