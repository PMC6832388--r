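#' Read a raster layer from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII grid format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by
#' north-to-south rows). Cells equal to the nodata sentinel are masked and
#' the raster is stored south-to-north.
#'
#' @param path path to an `.asc` file.
#' @param layerName label attached to the returned raster.
#' @return A [GridRaster-class].
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path, layerName = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("unreadable file: ", path))
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing georeferencing metadata in ", path,
         " (need ncols, nrows, cellsize and a lower-left anchor)")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows); cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - cs / 2
  else stop("missing georeferencing metadata in ", path, " (x anchor)")
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - cs / 2
  else stop("missing georeferencing metadata in ", path, " (y anchor)")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (length(vals) != nr * nc || anyNA(vals) && any(is.na(vals) &
      !is.na(strsplit(trimws(body), "\\s+")[[1]])))
    stop("format error: expected ", nr * nc, " values in ", path,
         ", found ", length(vals))
  # file rows run north -> south; flip to the internal south -> north order
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  GridRaster(m,
             latEdges = yll + cs * (0:nr),
             lonEdges = xll + cs * (0:nc),
             nodata = nodata, name = layerName)
}

#' Write a raster layer to an ESRI ASCII grid file
#'
#' Only uniformly spaced grids can be written (the format has a single
#' `cellsize`). Values are written with 17 significant digits so that float
#' round-trips are exact to double precision; whole-number layers are
#' written as integers and round-trip bit-exactly.
#'
#' @param raster a [GridRaster-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(raster, path) {
  stopifnot(is(raster, "GridRaster"))
  dlat <- diff(raster@latEdges); dlon <- diff(raster@lonEdges)
  cs <- dlat[1]
  if (max(abs(c(dlat, dlon) - cs)) > 1e-9 * max(abs(cs), 1))
    stop("only uniformly spaced grids can be written as ASCII grids")
  v <- raster@values
  nodata <- if (is.na(raster@nodata)) -9999 else raster@nodata
  v[is.na(v)] <- nodata
  intLike <- all(v == round(v)) && max(abs(v)) < 2^53
  fmt <- function(x) {
    if (intLike) sprintf("%.0f", x) else formatC(x, digits = 17, format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.12g", raster@lonEdges[1]),
    sprintf("yllcorner %.12g", raster@latEdges[1]),
    sprintf("cellsize %.12g", cs),
    sprintf("NODATA_value %s", fmt(nodata))
  ), con)
  for (r in nrow(v):1)  # north first
    writeLines(paste(fmt(v[r, ]), collapse = " "), con)
  invisible(path)
}

#' Read or write an annual raster series
#'
#' A [TimeRaster-class] is stored as one ASCII grid per year,
#' `<stem>_<year>.asc`, plus no index file: the years are parsed from the
#' file names.
#'
#' @param dir directory holding the per-year files.
#' @param stem file-name stem.
#' @param layerName label for the returned series.
#' @return `readTimeRaster()` a [TimeRaster-class]; `writeTimeRaster()` the
#'   vector of paths written, invisibly.
#' @name timeraster-io
NULL

#' @rdname timeraster-io
#' @export
readTimeRaster <- function(dir, stem, layerName = stem) {
  files <- list.files(dir, pattern = paste0("^", stem, "_\\d+\\.asc$"),
                      full.names = TRUE)
  if (!length(files)) stop("no ", stem, "_<year>.asc files in ", dir)
  years <- as.integer(sub(".*_(\\d+)\\.asc$", "\\1", files))
  o <- order(years)
  files <- files[o]; years <- years[o]
  layers <- lapply(files, readRaster)
  ref <- layers[[1]]
  for (l in layers[-1])
    if (!isTRUE(all.equal(l@latEdges, ref@latEdges)) ||
        !isTRUE(all.equal(l@lonEdges, ref@lonEdges)))
      stop("per-year files are not on a shared grid")
  arr <- array(NA_real_, c(dim(ref@values), length(years)))
  for (k in seq_along(layers)) arr[, , k] <- layers[[k]]@values
  TimeRaster(arr, ref@latEdges, ref@lonEdges, years, name = layerName)
}

#' @rdname timeraster-io
#' @param series a [TimeRaster-class] to write.
#' @export
writeTimeRaster <- function(series, dir, stem = layerName(series)) {
  stopifnot(is(series, "TimeRaster"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(series@years))
  for (k in seq_along(series@years)) {
    r <- GridRaster(series@values[, , k], series@latEdges, series@lonEdges,
                    nodata = -9999, name = series@name)
    paths[k] <- file.path(dir, sprintf("%s_%d.asc", stem, series@years[k]))
    writeRaster(r, paths[k])
  }
  invisible(paths)
}

#' Cell-center coordinates of a raster grid
#'
#' @param x a GridRaster or TimeRaster.
#' @return list with numeric vectors `lat` and `lon` of cell centers
#'   (degrees).
#' @export
cellCenters <- function(x) {
  list(lat = (x@latEdges[-1] + x@latEdges[-length(x@latEdges)]) / 2,
       lon = (x@lonEdges[-1] + x@lonEdges[-length(x@lonEdges)]) / 2)
}
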